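# Virtual knockouts: removal semantics, per-pair classification,
# essentiality ranking, candidate shortlisting and alternate-path reports.

test_that("knockout removes the node and its incident edges only", {
  net <- table1_fixture()
  ko <- knockout(net, "PLC_melan")
  expect_equal(network_node_count(ko), 20L)
  expect_equal(network_edge_count(ko), 17L)
  expect_false("PLC_melan" %in% network_nodes(ko)$id)
  # value semantics: the input network is untouched
  expect_equal(network_node_count(net), 21L)
  expect_equal(network_edge_count(net), 20L)
  expect_error(knockout(net, "GHOST"), class = "pigmentnet_lookup_error")

  # isolated node: same edges, one fewer node
  rec <- data.frame(node_a = "A", node_b = "B",
                    interaction_type = "activates")
  with_iso <- build_network(rec, nodes = classify_node(c("A", "B", "Z")))
  koi <- knockout(with_iso, "Z")
  expect_equal(network_node_count(koi), 2L)
  expect_equal(network_edge_count(koi), 1L)
})

test_that("pair classification distinguishes the four outcomes", {
  net <- table1_fixture()
  s <- "PGE2_kerat"; t <- "Eumelanin_melan"

  # abrogated: every route needs PLC
  out <- classify_pair(net, knockout(net, "PLC_melan"), s, t, "PLC_melan")
  expect_equal(out$status, "abrogated")
  expect_null(out$perturbed_path)
  expect_true("PLC_melan" %in% out$baseline_path$nodes)

  # rerouted: PTGER3 carries one of the two tied baseline routes; the
  # reported baseline is the severed route, the alternate avoids it
  out <- classify_pair(net, knockout(net, "PTGER3_melan"), s, t,
                       "PTGER3_melan")
  expect_equal(out$status, "rerouted")
  expect_true("PTGER3_melan" %in% out$baseline_path$nodes)
  expect_false("PTGER3_melan" %in% out$perturbed_path$nodes)
  expect_false(out$length_increased)  # the tied twin has equal length

  # unchanged: TP53 lies on no PGE2-to-eumelanin route
  out <- classify_pair(net, knockout(net, "TP53_kerat"), s, t, "TP53_kerat")
  expect_equal(out$status, "unchanged")
  expect_equal(out$baseline_path$nodes, out$perturbed_path$nodes)

  # not_applicable: removed is the source; or baseline-disconnected pair
  out <- classify_pair(net, knockout(net, s), s, t, s)
  expect_equal(out$status, "not_applicable")
  out <- classify_pair(net, knockout(net, "PLC_melan"), "UVA", t,
                       "PLC_melan")
  expect_equal(out$status, "not_applicable")

  # consistency guard
  expect_error(
    classify_pair(net, knockout(net, "DAG_melan"), s, t, "PLC_melan"),
    class = "pigmentnet_consistency_error"
  )
})

test_that("essentiality scan ranks abrogation counts with exclusions", {
  net <- table1_fixture()
  scan <- essentiality_scan(
    net, sources = "PGE2_kerat", targets = "Eumelanin_melan",
    candidates = c("PLC_melan", "DAG_melan", "PRKCB_melan", "TYR_melan",
                   "PTGER1_melan", "PTGER3_melan")
  )
  counts <- setNames(scan$table$essential_pairs, scan$table$node)
  expect_equal(counts[c("DAG_melan", "PLC_melan", "PRKCB_melan",
                        "TYR_melan")],
               c(DAG_melan = 1L, PLC_melan = 1L, PRKCB_melan = 1L,
                 TYR_melan = 1L))
  expect_equal(counts[c("PTGER1_melan", "PTGER3_melan")],
               c(PTGER1_melan = 0L, PTGER3_melan = 0L))
  # sorted by count then id
  expect_equal(scan$table$node[1:4],
               c("DAG_melan", "PLC_melan", "PRKCB_melan", "TYR_melan"))
  expect_true(all(scan$table$essential_pairs <= scan$connected_pairs))

  # a designated source never contributes its own pairs
  scan2 <- essentiality_scan(net, sources = c("PGE2_kerat", "PTGER1_melan"),
                             targets = "Eumelanin_melan",
                             candidates = "PTGER1_melan")
  expect_false(any(scan2$outcomes$source == "PTGER1_melan"))
  expect_equal(scan2$table$essential_pairs, 0L)  # PGE2 pair just reroutes

  expect_error(essentiality_scan(net, sources = "PGE2_kerat",
                                 targets = "Eumelanin_melan",
                                 candidates = character()),
               class = "pigmentnet_value_error")
})

test_that("candidate shortlisting unions degree and frequency rules", {
  net <- table1_fixture()
  net <- set_designations(net, "PGE2_kerat", "Eumelanin_melan")
  ps <- source_target_paths(net, mode = "all_tied")

  expect_equal(shortlist_candidates(net, ps), character())
  expect_equal(
    shortlist_candidates(net, ps, top_by_path_frequency = 3),
    c("DAG_melan", "PLC_melan", "PRKCB_melan")
  )
  # clamping: asking for more than exists returns all eligible nodes
  all_freq <- shortlist_candidates(net, ps, top_by_path_frequency = 100)
  expect_setequal(all_freq, c("DAG_melan", "PLC_melan", "PRKCB_melan",
                              "TYR_melan", "PTGER1_melan", "PTGER3_melan"))
  # degree rule never returns designated sources/targets
  by_deg <- shortlist_candidates(net, ps, top_by_degree = 5)
  expect_false(any(c("PGE2_kerat", "Eumelanin_melan") %in% by_deg))
  expect_length(by_deg, 5L)
})

test_that("alternate-path report prints severed and alternate routes", {
  net <- table1_fixture()
  scan <- essentiality_scan(
    net, sources = "PGE2_kerat", targets = "Eumelanin_melan",
    candidates = c("PTGER3_melan", "TYR_melan", "ADCY4_melan")
  )
  rep_ <- alternate_path_report(scan)
  # unchanged pairs (ADCY4) emit no row
  expect_setequal(rep_$removed, c("PTGER3_melan", "TYR_melan"))
  tyr <- rep_[rep_$removed == "TYR_melan", ]
  expect_equal(tyr$alternate_path, "None")
  pt3 <- rep_[rep_$removed == "PTGER3_melan", ]
  expect_equal(pt3$status, "rerouted")
  # the alternate re-traces in the perturbed network
  alt <- parse_path_string(pt3$alternate_path)
  ko <- knockout(net, "PTGER3_melan")
  expect_equal(shortest_path(ko, alt[[1]], alt[[length(alt)]])$nodes, alt)

  f <- withr::local_tempfile(fileext = ".tsv")
  write_essentiality(scan, f, "tsv")
  tab <- read.delim(f)
  expect_equal(names(tab), c("node", "essential_pairs"))
  j <- withr::local_tempfile(fileext = ".json")
  write_essentiality(scan, j, "json")
  parsed <- jsonlite::read_json(j)
  expect_equal(parsed$connected_pairs, 1L)
})
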