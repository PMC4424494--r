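# The directed typed graph and its topology metrics.

new_signalling_network <- function(graph, sources = character(),
                                   targets = character(),
                                   weakly_connected = NA) {
  structure(
    list(graph = graph, sources = sources, targets = targets,
         weakly_connected = weakly_connected),
    class = "signalling_network"
  )
}

#' Build a directed typed signalling network
#'
#' Assembles the graph from parsed interaction records. Duplicate rows for
#' the same ordered (source, target) pair merge into one edge whose type set
#' is the union of their canonical types; self-loops are retained but
#' flagged with a warning; descriptors without any incident record become
#' isolated nodes.
#'
#' @param records data frame with columns `node_a`, `node_b`,
#'   `interaction_type` (raw names are normalised on the way in).
#' @param nodes optional descriptor data frame from [classify_node()];
#'   endpoints missing from it are classified on the fly.
#' @param annotations optional node-category annotation table.
#' @return a `signalling_network`: an igraph directed graph whose vertices
#'   carry `base_name`, `compartment` and `category` attributes and whose
#'   edges carry a `types` attribute (`|`-joined sorted type set), plus
#'   (initially empty) source/target designations.
#' @export
#' @examples
#' tab <- parse_interaction_table(pigmentnet_extdata("table1_interactions.tsv"))
#' net <- build_network(tab$records, tab$nodes)
#' network_node_count(net)
build_network <- function(records, nodes = NULL, annotations = NULL) {
  node_a <- normalise_node_name(records$node_a)
  node_b <- normalise_node_name(records$node_b)
  itype <- canonicalise_interaction_type(records$interaction_type)

  ids <- character()
  if (!is.null(nodes) && nrow(nodes)) ids <- normalise_node_name(nodes$id)
  appearing <- unique(as.vector(t(cbind(node_a, node_b))))
  ids <- unique(c(ids, appearing))
  descriptors <- classify_node(ids, annotations = annotations)

  if (any(node_a == node_b)) {
    warning(sprintf("self-loop(s) retained: %s",
                    paste(unique(node_a[node_a == node_b]), collapse = ", ")))
  }
  key <- paste(node_a, node_b, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate (source, target) rows merged into single typed edges")
  }
  first <- !duplicated(key)
  types <- vapply(split(itype, factor(key, levels = key[first])),
                  function(tt) paste(sort(unique(tt)), collapse = "|"),
                  character(1))
  edges <- data.frame(
    from = node_a[first], to = node_b[first],
    types = as.vector(types), stringsAsFactors = FALSE
  )
  vertices <- data.frame(
    name = descriptors$id, base_name = descriptors$base_name,
    compartment = descriptors$compartment, category = descriptors$category,
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = vertices)
  new_signalling_network(g)
}

#' Designate source and target nodes
#'
#' @param network a `signalling_network`.
#' @param sources,targets character vectors of node ids.
#' @return the network with designations attached.
#' @export
set_designations <- function(network, sources, targets) {
  stopifnot(inherits(network, "signalling_network"))
  ids <- igraph::V(network$graph)$name
  missing <- setdiff(c(sources, targets), ids)
  if (length(missing)) {
    pn_lookup_error(sprintf("unknown node id(s): %s",
                            paste(missing, collapse = ", ")))
  }
  network$sources <- unique(normalise_node_name(sources))
  network$targets <- unique(normalise_node_name(targets))
  network
}

#' @rdname network_node_count
#' @export
network_edge_count <- function(network) igraph::ecount(network$graph)

#' Network size accessors
#'
#' Node count is the number of descriptors; edge count the number of unique
#' ordered (source, target) pairs.
#'
#' @param network a `signalling_network`.
#' @return an integer count.
#' @export
network_node_count <- function(network) igraph::vcount(network$graph)

#' Node and edge tables of a network
#'
#' @param network a `signalling_network`.
#' @return `network_nodes()`: the descriptor data frame (with `members`
#'   list column re-derived from base names); `network_edges()`: a data
#'   frame `source`, `target`, `types`.
#' @export
network_nodes <- function(network) {
  classify_node(igraph::V(network$graph)$name)
}

#' @rdname network_nodes
#' @export
network_edges <- function(network) {
  g <- network$graph
  if (igraph::ecount(g) == 0L) {
    return(data.frame(source = character(), target = character(),
                      types = character(), stringsAsFactors = FALSE))
  }
  ends <- igraph::ends(g, igraph::E(g), names = TRUE)
  data.frame(source = ends[, 1], target = ends[, 2],
             types = igraph::E(g)$types, stringsAsFactors = FALSE)
}

#' @export
print.signalling_network <- function(x, ...) {
  comp <- table(factor(igraph::V(x$graph)$compartment,
                       levels = c("keratinocyte", "melanocyte", "none")))
  cat(sprintf(
    "<signalling_network> %d nodes (%d kerat / %d melan / %d shared), %d edges\n",
    network_node_count(x), comp[["keratinocyte"]], comp[["melanocyte"]],
    comp[["none"]], network_edge_count(x)
  ))
  if (length(x$sources) || length(x$targets)) {
    cat(sprintf("  designations: %d sources, %d targets\n",
                length(x$sources), length(x$targets)))
  }
  if (!is.na(x$weakly_connected)) {
    cat(sprintf("  weakly connected: %s\n", x$weakly_connected))
  }
  invisible(x)
}

#' Per-node degree profile
#'
#' In/out degrees over unique ordered pairs; a self-loop contributes one to
#' each direction.
#'
#' @param network a `signalling_network`.
#' @return data frame `node`, `in_degree`, `out_degree` in vertex order.
#' @export
degree_profile <- function(network) {
  g <- network$graph
  data.frame(
    node = igraph::V(g)$name,
    in_degree = as.integer(igraph::degree(g, mode = "in", loops = TRUE)),
    out_degree = as.integer(igraph::degree(g, mode = "out", loops = TRUE)),
    stringsAsFactors = FALSE
  )
}

#' Topology report: centrality, radiality and global metrics
#'
#' Computes, over unit edge weights: directed shortest-path betweenness for
#' nodes and edges (tied shortest paths split a pair's contribution
#' equally); a reachable-set closeness, `(r/(n-1)) * (r / sum of distances
#' to the r reachable nodes)`, 0 for nodes reaching nothing; and radiality,
#' `sum over reachable w of (diameter + 1 - d(v, w)) / (n - 1)` with the
#' diameter the longest finite directed shortest-path length. Unreachable
#' pairs contribute nothing (the network is not strongly connected, so a
#' reachable-set convention is required).
#'
#' @param network a `signalling_network`.
#' @param hub_rule rule passed to [identify_hubs()] for the report's hub
#'   list; default: top tenth of nodes by total degree.
#' @return a `topology_report`: list with data frames `nodes` (degrees,
#'   betweenness, closeness, radiality, reachable_count) and `edges`
#'   (edge_betweenness), and `network` (node/edge counts, diameter, hubs).
#' @export
network_centrality <- function(network, hub_rule = list(top_fraction = 0.1)) {
  g <- network$graph
  n <- igraph::vcount(g)
  ids <- igraph::V(g)$name

  if (n == 0L) {
    return(structure(list(
      nodes = data.frame(node = character(), in_degree = integer(),
                         out_degree = integer(), betweenness = numeric(),
                         closeness = numeric(), radiality = numeric(),
                         reachable_count = integer()),
      edges = data.frame(source = character(), target = character(),
                         edge_betweenness = numeric()),
      network = list(node_count = 0L, edge_count = 0L,
                     diameter = NA_real_, hubs = character())
    ), class = "topology_report"))
  }

  dm <- igraph::distances(g, mode = "out", weights = NA)
  off <- dm; diag(off) <- Inf
  finite <- is.finite(off)
  diameter <- if (any(finite)) max(off[finite]) else NA_real_

  reach <- rowSums(finite)
  sumd <- rowSums(ifelse(finite, off, 0))
  closeness <- ifelse(reach > 0 & n > 1,
                      (reach / (n - 1)) * (reach / pmax(sumd, 1)), 0)
  # sumd == 0 with reach > 0 cannot happen at unit weights (d >= 1)
  radiality <- if (is.na(diameter) || n == 1L) rep(0, n) else
    rowSums(ifelse(finite, diameter + 1 - off, 0)) / (n - 1)

  btw <- igraph::betweenness(g, directed = TRUE, weights = NA)
  ebtw <- if (igraph::ecount(g)) {
    igraph::edge_betweenness(g, directed = TRUE, weights = NA)
  } else numeric()

  deg <- degree_profile(network)
  edges <- network_edges(network)
  edges$edge_betweenness <- as.numeric(ebtw)

  structure(list(
    nodes = data.frame(
      node = ids, in_degree = deg$in_degree, out_degree = deg$out_degree,
      betweenness = as.numeric(btw), closeness = as.numeric(closeness),
      radiality = as.numeric(radiality),
      reachable_count = as.integer(reach), stringsAsFactors = FALSE
    ),
    edges = edges[, c("source", "target", "edge_betweenness")],
    network = list(
      node_count = n, edge_count = igraph::ecount(g),
      diameter = diameter,
      hubs = do.call(identify_hubs, c(list(network), hub_rule))
    )
  ), class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf("<topology_report> %d nodes, %d edges, diameter %s; %d hub(s)\n",
              x$network$node_count, x$network$edge_count,
              format(x$network$diameter), length(x$network$hubs)))
  invisible(x)
}

#' Identify hub nodes
#'
#' Ranks nodes by total degree (in + out), ties broken lexicographically by
#' id, and keeps either the top fraction of nodes or every node with at
#' least a minimum total degree. Exactly one rule must be given.
#'
#' @param network a `signalling_network`.
#' @param top_fraction fraction in (0, 1] of nodes to keep (count rounded
#'   up).
#' @param min_total_degree minimum total degree (>= 1).
#' @return ordered character vector of hub ids (rank order).
#' @export
identify_hubs <- function(network, top_fraction = NULL,
                          min_total_degree = NULL) {
  if (is.null(top_fraction) == is.null(min_total_degree)) {
    pn_value_error("give exactly one of top_fraction or min_total_degree")
  }
  deg <- degree_profile(network)
  if (nrow(deg) == 0L) return(character())
  total <- deg$in_degree + deg$out_degree
  ord <- order(-total, deg$node, method = "radix")
  if (!is.null(top_fraction)) {
    if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction > 1) {
      pn_value_error("top_fraction must lie in (0, 1]")
    }
    k <- ceiling(top_fraction * nrow(deg))
    deg$node[ord][seq_len(k)]
  } else {
    if (!is.numeric(min_total_degree) || min_total_degree < 1) {
      pn_value_error("min_total_degree must be >= 1")
    }
    keep <- ord[total[ord] >= min_total_degree]
    deg$node[keep]
  }
}

#' Serialise a topology report
#'
#' @param report a `topology_report`.
#' @param path output path (TSV: one node per row; JSON: full report).
#' @param format `"tsv"` or `"json"`.
#' @return invisibly, `path`.
#' @export
write_topology_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    con <- file(path, open = "wb"); on.exit(close(con))
    write.table(report$nodes, con, sep = "\t", quote = FALSE,
                row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(
      list(nodes = report$nodes, edges = report$edges,
           network = report$network),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
    )
  }
  invisible(path)
}
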