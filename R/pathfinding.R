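# Shortest signalling routes: single pairs, all-vs-all connectivity,
# source-to-target (S2T) enumeration and sub-network extraction.
#
# All path computations use unit edge weights (breadth-first distances) and
# traverse inhibitory edges exactly like activating ones: interaction sign
# is metadata, not a traversal rule. Among tied minimal-length routes the
# canonical path is the lexicographically smallest node sequence, which
# makes every reported route reproducible.

new_path_result <- function(network, nodes) {
  edge_types <- if (length(nodes) > 1L) {
    eids <- igraph::get_edge_ids(network$graph,
                                 rbind(nodes[-length(nodes)], nodes[-1]))
    igraph::E(network$graph)$types[eids]
  } else character()
  structure(
    list(source = nodes[[1]], target = nodes[[length(nodes)]],
         nodes = nodes, length = length(nodes) - 1L,
         edge_types = edge_types),
    class = "path_result"
  )
}

#' @export
print.path_result <- function(x, ...) {
  cat(sprintf("<path> length %d: %s\n", x$length, as_path_string(x)))
  invisible(x)
}

#' @rdname format_path_string
#' @param path a `path_result`.
#' @export
as_path_string <- function(path) format_path_string(path$nodes)

check_node_ids <- function(network, ids) {
  missing <- setdiff(ids, igraph::V(network$graph)$name)
  if (length(missing)) {
    pn_lookup_error(sprintf("unknown node id(s): %s",
                            paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

tied_geodesics <- function(network, source, target) {
  if (source == target) return(list(source))
  res <- suppressWarnings(
    igraph::all_shortest_paths(network$graph, from = source, to = target,
                               mode = "out", weights = NA)
  )$vpaths
  seqs <- lapply(res, function(p) igraph::as_ids(p))
  seqs[lexicographic_order(seqs)]
}

#' Canonical shortest signalling route between two nodes
#'
#' Breadth-first shortest directed path; among tied minimal routes the
#' lexicographically smallest node sequence is returned. The trivial
#' source-equals-target query yields the zero-length path (self-loops never
#' participate in shortest routes).
#'
#' @param network a `signalling_network`.
#' @param source,target node ids.
#' @return a `path_result` (`source`, `target`, `nodes`, `length`,
#'   `edge_types`), or `NULL` when no directed route exists.
#' @export
#' @examples
#' net <- table1_fixture()
#' shortest_path(net, "PGE2_kerat", "Eumelanin_melan")
shortest_path <- function(network, source, target) {
  check_node_ids(network, c(source, target))
  seqs <- tied_geodesics(network, source, target)
  if (length(seqs) == 0L) return(NULL)
  new_path_result(network, seqs[[1]])
}

#' All tied shortest routes between two nodes
#'
#' Exhaustive set of minimal-length directed paths, lexicographically
#' ordered by node sequence.
#'
#' @inheritParams shortest_path
#' @return list of `path_result` (possibly empty).
#' @export
all_shortest_paths <- function(network, source, target) {
  check_node_ids(network, c(source, target))
  lapply(tied_geodesics(network, source, target),
         function(s) new_path_result(network, s))
}

#' All-vs-all directed connectivity
#'
#' Breadth-first distances between every ordered pair of distinct nodes and
#' the count of pairs with a finite distance.
#'
#' @param network a `signalling_network`.
#' @return list with `distances` (node-by-node matrix, `Inf` when
#'   unreachable) and `connected_pairs` (ordered pairs, excluding
#'   self-pairs).
#' @export
all_pairs_connectivity <- function(network) {
  dm <- igraph::distances(network$graph, mode = "out", weights = NA)
  off <- dm
  if (nrow(off)) diag(off) <- Inf
  list(distances = dm,
       connected_pairs = sum(is.finite(off)))
}

#' Enumerate source-to-target shortest routes
#'
#' For every ordered (source, target) pair with the two distinct, computes
#' either the canonical shortest route (`canonical_per_pair`) or the full
#' tied set (`all_tied`). Node frequencies count, for each node, the number
#' of returned routes it lies on.
#'
#' @param network a `signalling_network`.
#' @param sources,targets node id sets; default: the network's
#'   designations.
#' @param mode `"canonical_per_pair"` or `"all_tied"`.
#' @return a `path_set`: list with `sources`, `targets`, `mode`, `paths`
#'   (list of `path_result`), `connected_pairs` (ordered pairs at finite
#'   distance), `path_count`, and `frequency` (named integer vector over
#'   nodes appearing in returned paths).
#' @export
source_target_paths <- function(network, sources = NULL, targets = NULL,
                                mode = c("canonical_per_pair", "all_tied")) {
  mode <- match.arg(mode)
  if (is.null(sources)) sources <- network$sources
  if (is.null(targets)) targets <- network$targets
  if (length(sources) == 0L || length(targets) == 0L) {
    pn_value_error("source and target sets must both be non-empty")
  }
  check_node_ids(network, c(sources, targets))

  paths <- list()
  connected <- 0L
  for (s in sources) {
    for (t in targets) {
      if (s == t) next
      seqs <- tied_geodesics(network, s, t)
      if (length(seqs) == 0L) next
      connected <- connected + 1L
      if (mode == "canonical_per_pair") seqs <- seqs[1]
      paths <- c(paths, lapply(seqs, function(x) new_path_result(network, x)))
    }
  }
  freq_tab <- table(unlist(lapply(paths, `[[`, "nodes"), use.names = FALSE))
  frequency <- setNames(as.integer(freq_tab), names(freq_tab))
  structure(
    list(sources = sources, targets = targets, mode = mode,
         paths = paths, connected_pairs = connected,
         path_count = length(paths), frequency = frequency),
    class = "path_set"
  )
}

#' @export
print.path_set <- function(x, ...) {
  cat(sprintf(
    "<path_set> %d source(s) x %d target(s): %d connected pair(s), %d path(s) [%s]\n",
    length(x$sources), length(x$targets), x$connected_pairs,
    x$path_count, x$mode
  ))
  invisible(x)
}

#' Extract the source-to-target (S2T) sub-network
#'
#' Union of all nodes and edges lying on the routes of a path set, with
#' edge types and designations carried over from the parent network; the
#' result records whether it is weakly connected.
#'
#' @param network the `signalling_network` the paths were computed on.
#' @param paths a `path_set`.
#' @return a `signalling_network` with a `weakly_connected` flag.
#' @export
extract_s2t_subnetwork <- function(network, paths) {
  stopifnot(inherits(paths, "path_set"))
  node_ids <- unique(unlist(lapply(paths$paths, `[[`, "nodes"),
                            use.names = FALSE))
  pair_from <- unlist(lapply(paths$paths,
                             function(p) p$nodes[-length(p$nodes)]),
                      use.names = FALSE)
  pair_to <- unlist(lapply(paths$paths, function(p) p$nodes[-1]),
                    use.names = FALSE)
  if (length(pair_from)) {
    key <- !duplicated(paste(pair_from, pair_to, sep = "\r"))
    pair_from <- pair_from[key]; pair_to <- pair_to[key]
    eids <- igraph::get_edge_ids(network$graph, rbind(pair_from, pair_to))
    if (any(eids == 0L)) {
      pn_consistency_error("path edge absent from the parent network")
    }
    types <- igraph::E(network$graph)$types[eids]
  } else {
    types <- character()
  }
  desc <- classify_node(node_ids)
  edges <- data.frame(from = pair_from, to = pair_to, types = types,
                      stringsAsFactors = FALSE)
  vertices <- data.frame(
    name = desc$id, base_name = desc$base_name,
    compartment = desc$compartment,
    category = igraph::V(network$graph)$category[
      match(desc$id, igraph::V(network$graph)$name)],
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = vertices)
  new_signalling_network(
    g,
    sources = intersect(paths$sources, node_ids),
    targets = intersect(paths$targets, node_ids),
    weakly_connected = if (igraph::vcount(g)) {
      igraph::is_connected(g, mode = "weak")
    } else NA
  )
}

#' Serialise a path set
#'
#' TSV with one route per row (`source`, `target`, `length`, `path` in the
#' arrow dialect) or JSON carrying nodes, lengths and edge types.
#'
#' @param paths a `path_set`.
#' @param path output file path.
#' @param format `"tsv"` or `"json"`.
#' @return invisibly, `path`.
#' @export
write_path_set <- function(paths, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  rows <- data.frame(
    source = vapply(paths$paths, `[[`, character(1), "source"),
    target = vapply(paths$paths, `[[`, character(1), "target"),
    length = vapply(paths$paths, `[[`, integer(1), "length"),
    path = vapply(paths$paths, as_path_string, character(1)),
    stringsAsFactors = FALSE
  )
  if (format == "tsv") {
    con <- file(path, open = "wb"); on.exit(close(con))
    write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE,
                eol = "\n", fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(
      list(
        mode = paths$mode, connected_pairs = paths$connected_pairs,
        path_count = paths$path_count,
        paths = lapply(paths$paths, function(p) {
          list(source = p$source, target = p$target, nodes = p$nodes,
               length = p$length, edge_types = p$edge_types)
        }),
        frequency = as.list(paths$frequency)
      ),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(path)
}
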