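# Curated-table parsing, node-name classification and format writers.

test_that("the curated sample table parses with canonical names and types", {
  res <- parse_interaction_table(pigmentnet_extdata("table1_interactions.tsv"))
  expect_length(res$warnings, 0L)
  expect_equal(nrow(res$records), 20L)
  expect_equal(nrow(res$nodes), 21L)
  expect_true(all(res$records$type_recognised))
  # canonicalisation folds the mixed-case variants of the same type
  expect_equal(
    res$records$interaction_type[res$records$node_a == "TYR_melan"],
    "increases level"
  )
  first <- res$records[1, ]
  expect_equal(first$node_a, "UVA")
  expect_equal(first$node_b, "Lipid_Peroxidation_kerat")
  expect_equal(first$interaction_type, "induces")
  # descriptor order is stable first-appearance order
  expect_equal(res$nodes$id[1:3],
               c("UVA", "Lipid_Peroxidation_kerat", "4HNE_kerat"))
})

test_that("degenerate and malformed inputs follow the parsing contract", {
  header <- "Node A\tNode B\tInteraction type A->B"
  # header-only stream
  res <- parse_interaction_table(header, text = TRUE)
  expect_equal(nrow(res$records), 0L)
  expect_equal(nrow(res$nodes), 0L)
  expect_length(res$warnings, 0L)
  # blank endpoint: skipped with a warning in lenient mode, error in strict
  lines <- c(header, "A\t  \tactivates", "A\tB\tactivates")
  res <- parse_interaction_table(lines, text = TRUE)
  expect_equal(nrow(res$records), 1L)
  expect_match(res$warnings, "row 1 skipped")
  expect_error(parse_interaction_table(lines, text = TRUE, strict = TRUE),
               class = "pigmentnet_schema_error")
  # unknown interaction type is preserved but flagged
  res <- parse_interaction_table(c(header, "A\tB\tPhosphorylates"),
                                 text = TRUE)
  expect_equal(res$records$interaction_type, "phosphorylates")
  expect_false(res$records$type_recognised)
  expect_match(res$warnings, "unrecognised")
  # missing mandatory column names the column; empty stream is an error
  expect_error(parse_interaction_table("Node A\tInteraction type A->B",
                                       text = TRUE),
               "Node B", class = "pigmentnet_schema_error")
  expect_error(parse_interaction_table(character(), text = TRUE),
               class = "pigmentnet_schema_error")
  # comma delimiter auto-detected; printed header variant accepted
  res <- parse_interaction_table(
    c("Node A,Node B,Interaction type A- > B", "X,Y,inhibits"),
    text = TRUE
  )
  expect_equal(res$records$node_b, "Y")
})

test_that("node classification parses compartments, complexes and categories", {
  d <- classify_node("NFKB1_kerat")
  expect_equal(d$compartment, "keratinocyte")
  expect_equal(d$base_name, "NFKB1")
  d <- classify_node("RAC1:PARD6A:CDC42_melan")
  expect_equal(d$compartment, "melanocyte")
  expect_equal(d$category, "complex")
  expect_equal(d$members[[1]], c("RAC1", "PARD6A", "CDC42"))
  expect_equal(classify_node("UVA")$category, "environmental_factor")
  expect_equal(classify_node("UVA")$compartment, "none")
  expect_equal(classify_node("Dendrite_formation_melan")$category,
               "biological_process")
  expect_equal(classify_node("Melanosome_biogenesis")$category,
               "biological_process")
  expect_equal(classify_node("TP53_kerat")$category, "unknown")
  # suffix only recognised terminally
  d <- classify_node("kerat_binding_factor")
  expect_equal(d$compartment, "none")
  expect_equal(d$base_name, "kerat_binding_factor")
  # annotation override
  ann <- data.frame(node = "TP53_kerat", category = "protein")
  expect_equal(classify_node("TP53_kerat", annotations = ann)$category,
               "protein")
  expect_error(classify_node("   "), class = "pigmentnet_value_error")
})

test_that("classification is idempotent and whitespace-normalising", {
  raw <- c("  Lipid Peroxidation_kerat ", "RAC1:PARD6A:CDC42_melan", "UVB")
  d1 <- classify_node(raw)
  expect_equal(d1$id[[1]], "Lipid_Peroxidation_kerat")
  d2 <- classify_node(d1$id)
  expect_identical(d1, d2)
})

test_that("edge-table output round-trips to the identical network", {
  net <- table1_fixture()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, f, format = "edge-table")
  res <- parse_interaction_table(f)
  back <- build_network(res$records, res$nodes)
  n1 <- network_nodes(net); n2 <- network_nodes(back)
  expect_setequal(n1$id, n2$id)
  expect_equal(n1$compartment[order(n1$id)], n2$compartment[order(n2$id)])
  e1 <- network_edges(net); e2 <- network_edges(back)
  o1 <- order(e1$source, e1$target); o2 <- order(e2$source, e2$target)
  expect_equal(e1[o1, ], e2[o2, ], ignore_attr = TRUE)
  # dialect is bit-stable: LF endings, tab-delimited
  raw <- readBin(f, "raw", file.size(f))
  expect_false(any(raw == as.raw(0x0d)))
})

test_that("SIF and GraphML writers follow their dialects", {
  rec <- data.frame(node_a = c("A", "B"), node_b = c("B", "C"),
                    interaction_type = c("activates", "increases level"))
  net <- build_network(rec)
  f <- withr::local_tempfile(fileext = ".sif")
  write_network(net, f, format = "sif")
  expect_equal(readLines(f), c("A activates B", "B increases_level C"))

  g <- withr::local_tempfile(fileext = ".graphml")
  write_network(table1_fixture(), g, format = "graphml")
  back <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::vcount(back), 21)
  expect_setequal(igraph::vertex_attr_names(back),
                  c("name", "base_name", "compartment", "category", "id"))

  # empty network: edge-table writes header-only, others refuse
  empty <- build_network(rec[0, ])
  f2 <- withr::local_tempfile()
  write_network(empty, f2, format = "edge-table")
  expect_equal(readLines(f2), "Node A\tNode B\tInteraction type A->B")
  expect_error(write_network(empty, f2, format = "sif"),
               class = "pigmentnet_value_error")
})
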