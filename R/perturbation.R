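# Virtual knockouts: remove a node, recompute source-to-target routes,
# classify the effect per pair, and rank nodes by how many pairs their
# removal disconnects ("essential nodes").
#
# Classification is made against the full tied set of baseline shortest
# routes, not only the canonical one: a knockout counts as a rerouting
# whenever the removed node lay on at least one baseline shortest route and
# the pair stays connected. The reported baseline route for an affected
# pair is the lexicographically smallest baseline shortest route passing
# through the removed node (the route the perturbation actually severed),
# falling back to the canonical route when the node lay on none.

#' Virtual knockout of a node
#'
#' Returns a copy of the network lacking the node and every incident edge;
#' the input network is not modified. Designations lose the removed node.
#'
#' @param network a `signalling_network`.
#' @param node node id to remove.
#' @return the perturbed `signalling_network`.
#' @export
knockout <- function(network, node) {
  stopifnot(length(node) == 1L)
  check_node_ids(network, node)
  g <- igraph::delete_vertices(network$graph, node)
  new_signalling_network(
    g,
    sources = setdiff(network$sources, node),
    targets = setdiff(network$targets, node)
  )
}

# Baseline tied routes split into the severed (through `removed`) and
# surviving parts; NULL-safe canonical pick.
split_baseline <- function(baseline_seqs, removed) {
  through <- vapply(baseline_seqs, function(s) removed %in% s, logical(1))
  list(through = baseline_seqs[through], spared = baseline_seqs[!through])
}

classify_one <- function(network, perturbed, source, target, removed,
                         baseline_seqs) {
  if (removed %in% c(source, target)) {
    return(list(status = "not_applicable", baseline_path = NULL,
                perturbed_path = NULL))
  }
  if (length(baseline_seqs) == 0L) {
    return(list(status = "not_applicable", baseline_path = NULL,
                perturbed_path = NULL))
  }
  parts <- split_baseline(baseline_seqs, removed)
  baseline_nodes <- if (length(parts$through)) parts$through[[1]]
                    else baseline_seqs[[1]]
  baseline_path <- new_path_result(network, baseline_nodes)

  if (length(parts$through) == 0L) {
    # every baseline shortest route survives: nothing changes
    return(list(status = "unchanged", baseline_path = baseline_path,
                perturbed_path = baseline_path))
  }
  perturbed_path <- shortest_path(perturbed, source, target)
  if (is.null(perturbed_path)) {
    list(status = "abrogated", baseline_path = baseline_path,
         perturbed_path = NULL)
  } else {
    list(status = "rerouted", baseline_path = baseline_path,
         perturbed_path = perturbed_path)
  }
}

#' Classify the effect of a knockout on one source-target pair
#'
#' Statuses: `abrogated` (pair disconnected by the removal), `rerouted`
#' (still connected but the removed node lay on a baseline shortest route),
#' `unchanged` (removed node on no baseline shortest route), and
#' `not_applicable` (pair disconnected already at baseline, or the removed
#' node is itself the source or target).
#'
#' @param baseline the intact `signalling_network`.
#' @param perturbed the network returned by `knockout(baseline, removed)`.
#' @param source,target the pair's node ids (looked up in `baseline`).
#' @param removed the knocked-out node id.
#' @return list with `status`, `removed`, `source`, `target`,
#'   `baseline_path` (`path_result` or `NULL`), `perturbed_path`, and
#'   `length_increased` (logical; `NA` unless rerouted).
#' @export
classify_pair <- function(baseline, perturbed, source, target, removed) {
  check_node_ids(baseline, c(source, target, removed))
  base_ids <- igraph::V(baseline$graph)$name
  pert_ids <- igraph::V(perturbed$graph)$name
  if (removed %in% pert_ids ||
      !setequal(pert_ids, setdiff(base_ids, removed))) {
    pn_consistency_error(
      "perturbed network is not knockout(baseline, removed)")
  }
  baseline_seqs <- tied_geodesics(baseline, source, target)
  out <- classify_one(baseline, perturbed, source, target, removed,
                      baseline_seqs)
  out$removed <- removed; out$source <- source; out$target <- target
  out$length_increased <- if (out$status == "rerouted") {
    out$perturbed_path$length > length(baseline_seqs[[1]]) - 1L
  } else NA
  out
}

#' Knockout scan over candidate nodes
#'
#' Performs one virtual knockout per candidate, classifies every ordered
#' (source, target) pair, and ranks candidates by their essentiality count:
#' the number of baseline-connected pairs whose signalling the removal
#' abrogates. Rerouted pairs do not count; pairs where the candidate is
#' itself the source or target are excluded (`not_applicable`).
#'
#' @param network a `signalling_network`.
#' @param sources,targets node id sets; default: the network's
#'   designations.
#' @param candidates non-empty node id set to knock out, one at a time.
#' @return an `essentiality_scan`: list with `table` (data frame `node`,
#'   `essential_pairs`, sorted by descending count then id), `outcomes`
#'   (data frame with one row per candidate and applicable pair: `removed`,
#'   `source`, `target`, `status`, `baseline_path`, `perturbed_path`,
#'   `baseline_length`, `perturbed_length`), and `connected_pairs` (the
#'   baseline bound on any count).
#' @export
#' @examples
#' net <- table1_fixture()
#' scan <- essentiality_scan(net, sources = "PGE2_kerat",
#'                           targets = "Eumelanin_melan",
#'                           candidates = c("PLC_melan", "PTGER3_melan"))
#' scan$table
essentiality_scan <- function(network, sources = NULL, targets = NULL,
                              candidates) {
  if (is.null(sources)) sources <- network$sources
  if (is.null(targets)) targets <- network$targets
  if (length(candidates) == 0L) {
    pn_value_error("candidate set must be non-empty")
  }
  if (length(sources) == 0L || length(targets) == 0L) {
    pn_value_error("source and target sets must both be non-empty")
  }
  check_node_ids(network, c(sources, targets, candidates))

  pairs <- expand.grid(source = sources, target = targets,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
  baseline_seqs <- Map(function(s, t) tied_geodesics(network, s, t),
                       pairs$source, pairs$target)
  connected <- vapply(baseline_seqs, length, integer(1)) > 0L

  rows <- list()
  for (cand in candidates) {
    perturbed <- knockout(network, cand)
    for (i in seq_len(nrow(pairs))) {
      if (!connected[[i]]) next
      out <- classify_one(network, perturbed, pairs$source[[i]],
                          pairs$target[[i]], cand, baseline_seqs[[i]])
      if (out$status == "not_applicable") next
      rows[[length(rows) + 1L]] <- data.frame(
        removed = cand, source = pairs$source[[i]],
        target = pairs$target[[i]], status = out$status,
        baseline_path = as_path_string(out$baseline_path),
        perturbed_path = if (is.null(out$perturbed_path)) NA_character_
                         else as_path_string(out$perturbed_path),
        baseline_length = out$baseline_path$length,
        perturbed_length = if (is.null(out$perturbed_path)) NA_integer_
                           else out$perturbed_path$length,
        stringsAsFactors = FALSE
      )
    }
  }
  outcomes <- if (length(rows)) do.call(rbind, rows) else data.frame(
    removed = character(), source = character(), target = character(),
    status = character(), baseline_path = character(),
    perturbed_path = character(), baseline_length = integer(),
    perturbed_length = integer(), stringsAsFactors = FALSE
  )
  counts <- vapply(candidates, function(cand) {
    sum(outcomes$removed == cand & outcomes$status == "abrogated")
  }, integer(1))
  tab <- data.frame(node = candidates, essential_pairs = as.integer(counts),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$essential_pairs, tab$node, method = "radix"), ,
             drop = FALSE]
  rownames(tab) <- NULL
  structure(
    list(table = tab, outcomes = outcomes,
         connected_pairs = sum(connected)),
    class = "essentiality_scan"
  )
}

#' @export
print.essentiality_scan <- function(x, ...) {
  cat(sprintf(
    "<essentiality_scan> %d candidate(s) over %d connected pair(s); top: %s\n",
    nrow(x$table), x$connected_pairs,
    if (nrow(x$table)) sprintf("%s (%d)", x$table$node[[1]],
                               x$table$essential_pairs[[1]]) else "-"
  ))
  invisible(x)
}

#' Shortlist knockout candidates
#'
#' Union of the top `top_by_degree` nodes by total degree and the top
#' `top_by_path_frequency` nodes by shortest-path frequency, excluding the
#' designated sources and targets. Ties break lexicographically; counts
#' larger than the eligible pool are clamped.
#'
#' @param network a `signalling_network`.
#' @param paths a `path_set` supplying per-node route frequencies.
#' @param top_by_degree,top_by_path_frequency non-negative counts.
#' @return lexicographically sorted character vector of candidate ids.
#' @export
shortlist_candidates <- function(network, paths, top_by_degree = 0,
                                 top_by_path_frequency = 0) {
  if (top_by_degree < 0 || top_by_path_frequency < 0) {
    pn_value_error("shortlist sizes must be non-negative")
  }
  excluded <- unique(c(network$sources, network$targets,
                       paths$sources, paths$targets))
  picked <- character()
  if (top_by_degree > 0) {
    deg <- degree_profile(network)
    deg <- deg[!(deg$node %in% excluded), , drop = FALSE]
    ord <- order(-(deg$in_degree + deg$out_degree), deg$node,
                 method = "radix")
    picked <- c(picked, deg$node[ord][seq_len(min(top_by_degree, nrow(deg)))])
  }
  if (top_by_path_frequency > 0) {
    freq <- paths$frequency
    freq <- freq[!(names(freq) %in% excluded)]
    ord <- order(-freq, names(freq), method = "radix")
    picked <- c(picked,
                names(freq)[ord][seq_len(min(top_by_path_frequency,
                                             length(freq)))])
  }
  sort(unique(picked), method = "radix")
}

#' Alternate-path report
#'
#' One row per rerouted or abrogated (candidate, pair) outcome of a scan:
#' the severed baseline (control) route and the alternate route taken post
#' perturbation, `"None"` when the pair is abrogated. Unchanged pairs emit
#' no row.
#'
#' @param scan an `essentiality_scan`.
#' @return data frame `removed`, `source`, `target`, `status`,
#'   `control_path`, `alternate_path`.
#' @export
alternate_path_report <- function(scan) {
  oc <- scan$outcomes
  oc <- oc[oc$status %in% c("rerouted", "abrogated"), , drop = FALSE]
  out <- data.frame(
    removed = oc$removed, source = oc$source, target = oc$target,
    status = oc$status, control_path = oc$baseline_path,
    alternate_path = ifelse(oc$status == "abrogated", "None",
                            oc$perturbed_path),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Serialise scan results
#'
#' @param scan an `essentiality_scan`.
#' @param path output file path.
#' @param format `"tsv"` (ranked node/count table) or `"json"` (table plus
#'   all outcomes).
#' @return invisibly, `path`.
#' @export
write_essentiality <- function(scan, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    con <- file(path, open = "wb"); on.exit(close(con))
    write.table(scan$table, con, sep = "\t", quote = FALSE,
                row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(
      list(table = scan$table, outcomes = scan$outcomes,
           connected_pairs = scan$connected_pairs),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
    )
  }
  invisible(path)
}
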