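# Independent brute-force oracles: exhaustive simple-path enumeration over
# the edge table, with shortest-path sets, betweenness and cut-node
# checks derived from it. Deliberately naive and igraph-free so they can
# arbitrate the fast implementations.

oracle_adjacency <- function(net) {
  edges <- network_edges(net)
  nodes <- network_nodes(net)$id
  adj <- lapply(setNames(vector("list", length(nodes)), nodes),
                function(x) character())
  for (i in seq_len(nrow(edges))) {
    adj[[edges$source[[i]]]] <- c(adj[[edges$source[[i]]]],
                                  edges$target[[i]])
  }
  adj
}

# All simple directed paths s -> t as a list of node-id vectors.
oracle_simple_paths <- function(adj, s, t) {
  out <- list()
  walk <- function(path) {
    head <- path[[length(path)]]
    if (head == t) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (nxt in adj[[head]]) {
      if (!(nxt %in% path)) walk(c(path, nxt))
    }
  }
  if (s == t) return(list(s))
  walk(s)
  out
}

# Exhaustive tied shortest-path set, lexicographically ordered.
oracle_shortest_set <- function(adj, s, t) {
  paths <- oracle_simple_paths(adj, s, t)
  if (length(paths) == 0L) return(list())
  len <- lengths(paths)
  tied <- paths[len == min(len)]
  tied[pigmentnet:::lexicographic_order(tied)]
}

# Node and edge betweenness by full enumeration: each ordered pair's
# contribution split equally among its tied shortest paths; the pair's own
# endpoints are excluded from node betweenness.
oracle_betweenness <- function(net) {
  adj <- oracle_adjacency(net)
  nodes <- names(adj)
  nb <- setNames(numeric(length(nodes)), nodes)
  edges <- network_edges(net)
  ekey <- paste(edges$source, edges$target)
  eb <- setNames(numeric(length(ekey)), ekey)
  for (s in nodes) {
    for (t in nodes) {
      if (s == t) next
      tied <- oracle_shortest_set(adj, s, t)
      k <- length(tied)
      if (k == 0L) next
      for (p in tied) {
        inner <- setdiff(p, c(s, t))
        nb[inner] <- nb[inner] + 1 / k
        if (length(p) > 1L) {
          ek <- paste(p[-length(p)], p[-1])
          eb[ek] <- eb[ek] + 1 / k
        }
      }
    }
  }
  list(node = nb, edge = eb)
}

# TRUE iff v lies on every simple s -> t path (and at least one exists).
oracle_is_cut_node <- function(adj, s, t, v) {
  paths <- oracle_simple_paths(adj, s, t)
  length(paths) > 0L && all(vapply(paths, function(p) v %in% p, logical(1)))
}

# Small seeded random digraph (no self-loops) for property tests.
random_network <- function(seed, n_min = 4L, n_max = 10L, p = 0.25) {
  set.seed(seed)
  n <- sample(n_min:n_max, 1L)
  ids <- sprintf("N%02d", seq_len(n))
  pairs <- expand.grid(a = ids, b = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
  keep <- runif(nrow(pairs)) < p
  records <- data.frame(
    node_a = pairs$a[keep], node_b = pairs$b[keep],
    interaction_type = sample(c("activates", "inhibits", "induces"),
                              sum(keep), replace = TRUE),
    stringsAsFactors = FALSE
  )
  build_network(records, nodes = classify_node(ids))
}
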