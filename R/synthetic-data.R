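# Seeded generator of two-compartment layered signalling networks.
#
# The generator emulates the structure the analysis assumes: zero-in-degree
# trigger/receptor sources in the first layer, zero-out-degree biological
# end processes in the last, a feed-forward cascade in between, paracrine
# edges crossing the keratinocyte/melanocyte boundary, and tunable route
# redundancy. Defaults mirror the curated pigmentation model's scale
# (142 keratinocyte and 113 melanocyte nodes, 20 sources, 9 end processes,
# mean in-degree ~1.6). It produces a DAG unless feedback_prob > 0; the
# analysis code never assumes acyclicity.

#' Specification for a synthetic two-compartment network
#'
#' @param n_keratinocyte,n_melanocyte node counts per compartment (sources,
#'   intermediates and end processes are drawn from this total).
#' @param n_sources number of zero-in-degree trigger/receptor sources
#'   (>= 1).
#' @param n_targets number of zero-out-degree biological end processes
#'   (>= 1).
#' @param n_layers depth of the layered cascade (>= 2; layer 1 holds the
#'   sources, the last layer the targets).
#' @param cross_talk_prob probability in [0, 1] that an edge's upstream
#'   node is drawn from the other compartment (paracrine cross-talk).
#' @param redundancy mean number of incoming branches per non-source node
#'   (>= 1); larger values create more parallel routes per source-target
#'   pair.
#' @param inhibition_frac fraction of edges typed `inhibits` (the rest are
#'   `activates`).
#' @param feedback_prob expected fraction of extra backward edges creating
#'   cycles (default 0: pure DAG).
#' @param seed integer seed owned by the generator call.
#' @return a `synthetic_spec`.
#' @export
synthetic_spec <- function(n_keratinocyte = 142, n_melanocyte = 113,
                           n_sources = 20, n_targets = 9, n_layers = 8,
                           cross_talk_prob = 0.2, redundancy = 1.6,
                           inhibition_frac = 0.15, feedback_prob = 0,
                           seed = 1L) {
  spec <- list(
    n_keratinocyte = as.integer(n_keratinocyte),
    n_melanocyte = as.integer(n_melanocyte),
    n_sources = as.integer(n_sources), n_targets = as.integer(n_targets),
    n_layers = as.integer(n_layers),
    cross_talk_prob = as.numeric(cross_talk_prob),
    redundancy = as.numeric(redundancy),
    inhibition_frac = as.numeric(inhibition_frac),
    feedback_prob = as.numeric(feedback_prob),
    seed = as.integer(seed)
  )
  n_total <- spec$n_keratinocyte + spec$n_melanocyte
  n_inter <- n_total - spec$n_sources - spec$n_targets
  ok <- spec$n_sources >= 1L && spec$n_targets >= 1L &&
    spec$n_layers >= 2L && spec$redundancy >= 1 &&
    spec$cross_talk_prob >= 0 && spec$cross_talk_prob <= 1 &&
    spec$inhibition_frac >= 0 && spec$inhibition_frac <= 1 &&
    spec$feedback_prob >= 0 && spec$feedback_prob <= 1 &&
    n_inter >= 0L && n_inter >= spec$n_layers - 2L
  if (!ok) {
    pn_value_error(paste(
      "infeasible synthetic spec: need n_sources >= 1, n_targets >= 1,",
      "n_layers >= 2, redundancy >= 1, probabilities in [0, 1], and enough",
      "nodes to fill every intermediate layer"
    ))
  }
  structure(spec, class = "synthetic_spec")
}

#' Generate a seeded two-compartment signalling network
#'
#' Layered feed-forward construction: every non-source node receives one
#' incoming edge from the previous layer (guaranteeing each node, and hence
#' each designated end process, is reachable from at least one source) plus
#' `rpois(redundancy - 1)` further incoming edges from any earlier layer.
#' Upstream partners switch compartment with probability
#' `cross_talk_prob`. The same spec and seed reproduce a byte-identical
#' edge table; the caller's RNG state is left untouched.
#'
#' @param spec a `synthetic_spec`.
#' @return a `signalling_network` with source/target designations.
#' @export
#' @examples
#' net <- generate_network(synthetic_spec(
#'   n_keratinocyte = 12, n_melanocyte = 10, n_sources = 3, n_targets = 2,
#'   n_layers = 4, seed = 7
#' ))
#' net
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(
    spec$seed,
    .rng_kind = "Mersenne-Twister", .rng_normal_kind = "Inversion",
    .rng_sample_kind = "Rejection",
    generate_network_impl(spec)
  )
}

generate_network_impl <- function(spec) {
  n_total <- spec$n_keratinocyte + spec$n_melanocyte
  n_inter <- n_total - spec$n_sources - spec$n_targets
  comp <- sample(c(rep("kerat", spec$n_keratinocyte),
                   rep("melan", spec$n_melanocyte)))

  role <- c(rep("source", spec$n_sources),
            rep("intermediate", n_inter),
            rep("target", spec$n_targets))
  layer <- integer(n_total)
  layer[role == "source"] <- 1L
  layer[role == "target"] <- spec$n_layers
  if (n_inter > 0L) {
    mids <- if (spec$n_layers > 2L) seq(2L, spec$n_layers - 1L) else integer()
    fill <- c(mids, if (n_inter > length(mids)) {
      sample(mids, n_inter - length(mids), replace = TRUE)
    })
    layer[role == "intermediate"] <- sort(fill)[seq_len(n_inter)]
  }

  idx_by_role <- split(seq_len(n_total), role)
  name <- character(n_total)
  name[role == "source"] <- sprintf(
    "REC%02d_%s", seq_len(spec$n_sources), comp[role == "source"])
  name[role == "intermediate"] <- sprintf(
    "SIG%03d_%s", seq_len(n_inter), comp[role == "intermediate"])
  name[role == "target"] <- sprintf(
    "Process%02d_formation_%s", seq_len(spec$n_targets),
    comp[role == "target"])

  pick_parent <- function(pool, want_comp) {
    cross <- runif(1) < spec$cross_talk_prob
    prefer <- if (cross) setdiff(c("kerat", "melan"), want_comp)
              else want_comp
    cand <- pool[comp[pool] == prefer]
    if (length(cand) == 0L) cand <- pool
    cand[sample.int(length(cand), 1L)]
  }

  from <- integer(); to <- integer()
  for (v in seq_len(n_total)[layer >= 2L & role != "source"]) {
    prev <- which(layer == layer[[v]] - 1L & role != "target")
    if (length(prev) == 0L) {
      prev <- which(layer < layer[[v]] & role != "target")
    }
    earlier <- which(layer < layer[[v]] & role != "target")
    k_extra <- rpois(1L, max(spec$redundancy - 1, 0))
    parents <- pick_parent(prev, comp[[v]])
    if (k_extra > 0L) {
      extra <- unique(vapply(seq_len(k_extra), function(i) {
        pick_parent(earlier, comp[[v]])
      }, integer(1)))
      parents <- unique(c(parents, extra))
    }
    from <- c(from, parents)
    to <- c(to, rep(v, length(parents)))
  }

  if (spec$feedback_prob > 0) {
    inter <- which(role == "intermediate")
    n_fb <- rbinom(1L, length(from), spec$feedback_prob)
    for (i in seq_len(n_fb)) {
      v <- inter[sample.int(length(inter), 1L)]
      pool <- inter[layer[inter] > layer[[v]]]
      if (length(pool) == 0L) next
      u <- pool[sample.int(length(pool), 1L)]
      from <- c(from, u); to <- c(to, v)
    }
  }

  dup <- duplicated(paste(from, to))
  from <- from[!dup]; to <- to[!dup]
  types <- ifelse(runif(length(from)) < spec$inhibition_frac,
                  "inhibits", "activates")
  records <- data.frame(
    node_a = name[from], node_b = name[to], interaction_type = types,
    stringsAsFactors = FALSE
  )
  nodes <- classify_node(name)
  net <- build_network(records, nodes = nodes)
  igraph::V(net$graph)$category <- ifelse(
    igraph::V(net$graph)$name %in% name[idx_by_role$target],
    "biological_process", "protein"
  )
  set_designations(net, sources = name[idx_by_role$source],
                   targets = name[idx_by_role$target])
}
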