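# Reading/writing curated interaction tables and node-name parsing.
#
# The curated table dialect has a header row with the three mandatory
# columns "Node A", "Node B", "Interaction type A->B" (header matching is
# punctuation- and case-insensitive, so the printed variant
# "Interaction type A- > B" is accepted), an optional provenance column,
# and any further columns passed through untouched.

# Packaged heuristic lists: environmental triggers and phenotypic
# end-process nodes (the curated target set plus suffix patterns).
environmental_factor_nodes <- c("UV", "UVA", "UVB")

biological_process_nodes <- c(
  "Eumelanin_melan", "Pheomelanin_melan", "Dendrite_formation_melan",
  "Melanosome_phagocytosis_kerat", "Apoptosis_melan",
  "Cell_proliferation_melan", "Melanosome_biogenesis",
  "Cell_survival_melan", "Cell_cycle_arrest_melan"
)

biological_process_patterns <- "(_formation|_phagocytosis)$"

#' Parse node names into structured descriptors
#'
#' Splits a node identifier into its compartment (a terminal `_kerat` or
#' `_melan` suffix marks keratinocyte or melanocyte localisation; anything
#' else is compartment-free), its base name, and a category. Colon-separated
#' base names (`RAC1:PARD6A:CDC42_melan`) are molecular complexes with
#' ordered members. UV triggers are environmental factors; names on the
#' packaged end-process list or ending in `_formation`/`_phagocytosis` are
#' biological processes. Everything else defaults to `unknown` unless an
#' annotation table says otherwise.
#'
#' @param name character vector of raw node names.
#' @param annotations optional data frame with columns `node` and `category`
#'   overriding the heuristic category per node.
#' @return a data frame with one row per name: `id`, `base_name`,
#'   `compartment` (`keratinocyte`/`melanocyte`/`none`), `category`, and a
#'   list column `members` (non-empty only for complexes). Normalisation is
#'   idempotent: re-classifying a returned `id` gives an identical row.
#' @export
#' @examples
#' classify_node("NFKB1_kerat")
#' classify_node("RAC1:PARD6A:CDC42_melan")$members[[1]]
classify_node <- function(name, annotations = NULL) {
  if (length(name) == 0L) {
    return(data.frame(
      id = character(), base_name = character(), compartment = character(),
      category = character(), members = I(list())
    ))
  }
  id <- normalise_node_name(name)
  if (any(!nzchar(id))) {
    pn_value_error("node names must be non-empty after whitespace trimming")
  }
  compartment <- rep("none", length(id))
  compartment[grepl("_kerat$", id)] <- "keratinocyte"
  compartment[grepl("_melan$", id)] <- "melanocyte"
  base_name <- sub("_(kerat|melan)$", "", id)
  members <- lapply(base_name, function(b) {
    if (grepl(":", b, fixed = TRUE)) strsplit(b, ":", fixed = TRUE)[[1]]
    else character()
  })

  category <- rep("unknown", length(id))
  category[id %in% biological_process_nodes |
             grepl(biological_process_patterns, base_name)] <- "biological_process"
  category[lengths(members) >= 2L] <- "complex"
  category[id %in% environmental_factor_nodes] <- "environmental_factor"

  if (!is.null(annotations)) {
    if (!all(c("node", "category") %in% names(annotations))) {
      pn_schema_error("annotation table needs columns 'node' and 'category'")
    }
    idx <- match(id, normalise_node_name(annotations$node))
    hit <- !is.na(idx)
    category[hit] <- as.character(annotations$category[idx[hit]])
  }

  out <- data.frame(
    id = id, base_name = base_name, compartment = compartment,
    category = category, stringsAsFactors = FALSE
  )
  out$members <- members
  out
}

# Normalise a header cell to a comparable key: letters only, lower-case.
header_key <- function(x) tolower(gsub("[^A-Za-z]", "", x))

#' Parse a curated interaction table
#'
#' Reads delimiter-separated text (tab or comma, auto-detected from the
#' header unless `delim` is given) with the three mandatory columns of the
#' curated schema. Rows with a blank endpoint or interaction type are
#' skipped with a warning (lenient default) or raise a schema error
#' (`strict = TRUE`). Interaction types outside the controlled vocabulary
#' are preserved in canonical lower-case but flagged.
#'
#' @param source a file path or connection, or a character vector of lines
#'   when `text = TRUE`.
#' @param delim field delimiter; `NULL` auto-detects among tab and comma.
#' @param strict error (rather than warn) on degenerate rows.
#' @param annotations optional node-category annotation table, see
#'   [classify_node()].
#' @param text treat `source` as the literal lines of the table.
#' @return a list with `records` (one row per kept input row: `node_a`,
#'   `node_b`, `interaction_type`, `type_recognised`, `provenance`, plus any
#'   extra columns passed through), `nodes` (deduplicated descriptors over
#'   both name columns, in first-appearance order), and `warnings`
#'   (character vector). Record and descriptor order is the stable input
#'   order.
#' @export
parse_interaction_table <- function(source, delim = NULL, strict = FALSE,
                                    annotations = NULL, text = FALSE) {
  lines <- if (text) source else readLines(source, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    pn_schema_error("empty interaction table: no header row found")
  }
  if (is.null(delim)) {
    delim <- if (grepl("\t", lines[[1]], fixed = TRUE)) "\t" else ","
  }
  tab <- read.delim(text = lines, sep = delim, header = TRUE,
                    check.names = FALSE, colClasses = "character",
                    quote = "\"", blank.lines.skip = TRUE)
  keys <- header_key(names(tab))
  wanted <- c(node_a = "nodea", node_b = "nodeb",
              interaction_type = "interactiontypeab")
  pretty <- c(node_a = "Node A", node_b = "Node B",
              interaction_type = "Interaction type A->B")
  idx <- match(wanted, keys)
  if (anyNA(idx)) {
    pn_schema_error(sprintf(
      "missing mandatory column(s): %s",
      paste(pretty[is.na(idx)], collapse = ", ")
    ))
  }
  extra_cols <- setdiff(seq_along(tab), idx)
  provenance_col <- if (length(extra_cols)) extra_cols[[1]] else NA_integer_

  warnings <- character()
  if (nrow(tab) == 0L) {
    return(list(
      records = data.frame(
        node_a = character(), node_b = character(),
        interaction_type = character(), type_recognised = logical(),
        provenance = character(), stringsAsFactors = FALSE
      ),
      nodes = classify_node(character()),
      warnings = warnings
    ))
  }

  node_a <- normalise_node_name(tab[[idx[[1]]]])
  node_b <- normalise_node_name(tab[[idx[[2]]]])
  itype <- canonicalise_interaction_type(tab[[idx[[3]]]])
  bad <- !nzchar(node_a) | !nzchar(node_b) | !nzchar(itype)
  if (any(bad)) {
    msgs <- sprintf("row %d skipped: missing mandatory field", which(bad))
    if (strict) pn_schema_error(paste(msgs, collapse = "; "))
    warnings <- c(warnings, msgs)
  }

  keep <- which(!bad)
  records <- data.frame(
    node_a = node_a[keep], node_b = node_b[keep],
    interaction_type = itype[keep],
    type_recognised = itype[keep] %in% interaction_vocabulary,
    provenance = if (is.na(provenance_col)) rep(NA_character_, length(keep))
                 else as.character(tab[[provenance_col]][keep]),
    stringsAsFactors = FALSE
  )
  if (any(!records$type_recognised)) {
    warnings <- c(warnings, sprintf(
      "unrecognised interaction type '%s'",
      unique(records$interaction_type[!records$type_recognised])
    ))
  }
  for (j in setdiff(extra_cols, provenance_col)) {
    records[[names(tab)[[j]]]] <- as.character(tab[[j]][keep])
  }

  seen <- unique(as.vector(t(cbind(records$node_a, records$node_b))))
  list(
    records = records,
    nodes = classify_node(seen, annotations = annotations),
    warnings = warnings
  )
}

#' Read a source/target designation table
#'
#' Two-column TSV with header `role` (`source` or `target`) and `node`.
#'
#' @param path file path or connection.
#' @return list with character vectors `sources` and `targets`.
#' @export
read_designations <- function(path) {
  tab <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE)
  if (!all(c("role", "node") %in% names(tab))) {
    pn_schema_error("designation table needs columns 'role' and 'node'")
  }
  node <- normalise_node_name(tab$node)
  list(sources = node[tab$role == "source"],
       targets = node[tab$role == "target"])
}

#' Write a signalling network to standard formats
#'
#' `edge-table` writes the curated tab-delimited dialect (LF line endings,
#' UTF-8, one row per edge and interaction type) and round-trips through
#' [parse_interaction_table()]/[build_network()]. `sif` writes Cytoscape
#' simple-interaction lines `source relation target` with spaces in the
#' relation replaced by underscores. `graphml` stores compartment and
#' category as node attributes (via igraph).
#'
#' @param network a `signalling_network`.
#' @param sink output file path (or writable connection for the text
#'   formats).
#' @param format one of `"edge-table"`, `"sif"`, `"graphml"`.
#' @return invisibly, `sink`.
#' @export
write_network <- function(network, sink,
                          format = c("edge-table", "sif", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "signalling_network"))
  edges <- network_edges(network)
  if (format != "edge-table" && nrow(edges) == 0L) {
    pn_value_error(sprintf("refusing to write an empty network as %s", format))
  }
  # one row per (edge, type)
  expand <- function() {
    types <- strsplit(edges$types, "|", fixed = TRUE)
    data.frame(
      node_a = rep(edges$source, lengths(types)),
      node_b = rep(edges$target, lengths(types)),
      interaction_type = unlist(types, use.names = FALSE),
      stringsAsFactors = FALSE
    )
  }
  if (format == "edge-table") {
    rows <- expand()
    con <- if (is.character(sink)) {
      f <- file(sink, open = "wb"); on.exit(close(f)); f
    } else sink
    body <- c(
      "Node A\tNode B\tInteraction type A->B",
      if (nrow(rows)) paste(rows$node_a, rows$node_b,
                            rows$interaction_type, sep = "\t")
    )
    writeLines(body, con, sep = "\n", useBytes = TRUE)
  } else if (format == "sif") {
    rows <- expand()
    con <- if (is.character(sink)) {
      f <- file(sink, open = "wb"); on.exit(close(f)); f
    } else sink
    writeLines(paste(rows$node_a,
                     gsub(" ", "_", rows$interaction_type, fixed = TRUE),
                     rows$node_b),
               con, sep = "\n", useBytes = TRUE)
  } else {
    if (!is.character(sink)) {
      pn_value_error("graphml output requires a file path")
    }
    igraph::write_graph(network$graph, sink, format = "graphml")
  }
  invisible(sink)
}
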