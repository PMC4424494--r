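# Seeded generator of layered two-compartment networks, plus the packaged
# fixtures.

small_spec <- function(seed = 1L, ...) {
  args <- list(n_keratinocyte = 12, n_melanocyte = 10, n_sources = 3,
               n_targets = 2, n_layers = 4, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synthetic_spec, args)
}

test_that("spec validation rejects infeasible parameter combinations", {
  expect_s3_class(small_spec(), "synthetic_spec")
  expect_error(small_spec(n_sources = 0), class = "pigmentnet_value_error")
  expect_error(small_spec(n_targets = 0), class = "pigmentnet_value_error")
  expect_error(small_spec(n_layers = 1), class = "pigmentnet_value_error")
  expect_error(small_spec(redundancy = 0.5),
               class = "pigmentnet_value_error")
  expect_error(small_spec(cross_talk_prob = 1.5),
               class = "pigmentnet_value_error")
  # more layers than nodes to fill them
  expect_error(synthetic_spec(n_keratinocyte = 3, n_melanocyte = 2,
                              n_sources = 2, n_targets = 2, n_layers = 6),
               class = "pigmentnet_value_error")
})

test_that("the generator is seed-deterministic and leaves the RNG alone", {
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_network(generate_network(small_spec(seed = 7)), f1)
  write_network(generate_network(small_spec(seed = 7)), f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed gives a different network
  f3 <- withr::local_tempfile()
  write_network(generate_network(small_spec(seed = 8)), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
  # caller RNG state is restored
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generate_network(small_spec(seed = 7)))
  expect_identical(runif(1), before)
})

test_that("generated networks obey the structural guarantees", {
  for (seed in 1:5) {
    net <- generate_network(small_spec(seed = seed))
    dp <- degree_profile(net)
    expect_equal(network_node_count(net), 22L)
    expect_length(net$sources, 3L)
    expect_length(net$targets, 2L)
    expect_true(all(dp$in_degree[match(net$sources, dp$node)] == 0L))
    expect_true(all(dp$out_degree[match(net$targets, dp$node)] == 0L))
    expect_equal(sum(dp$in_degree), network_edge_count(net))
    expect_equal(sum(dp$out_degree), network_edge_count(net))
    # every designated end process reachable from >= 1 source
    dm <- all_pairs_connectivity(net)$distances
    expect_true(all(apply(dm[net$sources, net$targets, drop = FALSE], 2,
                          function(x) any(is.finite(x)))))
    # targets are biological processes in both compartments' naming scheme
    cats <- network_nodes(net)
    expect_true(all(cats$category[match(net$targets, cats$id)] ==
                      "biological_process"))
    expect_setequal(unique(cats$compartment),
                    c("keratinocyte", "melanocyte"))
  }
})

test_that("a redundancy-1 single route makes every intermediate essential", {
  spec <- synthetic_spec(n_keratinocyte = 4, n_melanocyte = 3, n_sources = 1,
                         n_targets = 1, n_layers = 7, redundancy = 1,
                         cross_talk_prob = 0.3, seed = 11)
  net <- generate_network(spec)
  # one incoming branch per node: the source-target route is unique
  intermediates <- setdiff(network_nodes(net)$id,
                           c(net$sources, net$targets))
  route <- shortest_path(net, net$sources, net$targets)
  on_route <- setdiff(route$nodes, c(net$sources, net$targets))
  scan <- essentiality_scan(net, candidates = intermediates)
  counts <- setNames(scan$table$essential_pairs, scan$table$node)
  expect_true(all(counts[on_route] == 1L))
  expect_true(all(counts[setdiff(intermediates, on_route)] == 0L))
})

test_that("raising redundancy does not increase the abrogation fraction", {
  abrogation_fraction <- function(redundancy) {
    fracs <- vapply(1:4, function(seed) {
      net <- generate_network(synthetic_spec(
        n_keratinocyte = 14, n_melanocyte = 12, n_sources = 3, n_targets = 2,
        n_layers = 5, redundancy = redundancy, seed = seed
      ))
      cand <- setdiff(network_nodes(net)$id, c(net$sources, net$targets))
      scan <- essentiality_scan(net, candidates = cand)
      oc <- scan$outcomes
      sum(oc$status == "abrogated") / nrow(oc)
    }, numeric(1))
    mean(fracs)
  }
  f1 <- abrogation_fraction(1)
  f3 <- abrogation_fraction(3)
  expect_lte(f3, f1)
})

test_that("packaged fixtures are pinned and re-trace their sources", {
  expect_equal(unname(tools::md5sum(
    pigmentnet_extdata("table1_interactions.tsv"))),
    "66267ed05d0eb4b365f90ba5e2afb56a")
  expect_equal(unname(tools::md5sum(
    pigmentnet_extdata("table2_designations.tsv"))),
    "19d33b2d70f70cd5741931f7b2e81a63")
  expect_equal(unname(tools::md5sum(
    pigmentnet_extdata("printed_paths.tsv"))),
    "25cb794af3315a68a1fda453306cf151")

  net <- table1_fixture()
  expect_equal(network_node_count(net), 21L)
  expect_equal(network_edge_count(net), 20L)
  e <- network_edges(net)
  expect_equal(e$types[e$source == "TYR_melan" &
                         e$target == "Eumelanin_melan"],
               "increases level")

  des <- table2_designations()
  expect_length(des$sources, 20L)
  expect_length(des$targets, 9L)
  expect_true(all(c("UVA", "UVB") %in% des$sources))

  pp <- printed_paths_fixture()
  expect_setequal(pp$sources, c("UV", "UVA", "UVB"))
  tab <- printed_paths_table()
  for (s in tab$path[tab$path != "None"]) {
    nodes <- parse_path_string(s)
    eids <- igraph::get_edge_ids(pp$graph,
                                 rbind(nodes[-length(nodes)], nodes[-1]))
    expect_true(all(eids > 0))
  }
})
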