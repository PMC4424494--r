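# Packaged desk-scale fixtures: the published sample interaction table, the
# curated source/target designations, and the union of all printed pathway
# strings (predicted, control and alternate routes).

#' Path to a packaged data file
#'
#' @param file file name under the package's `extdata` directory; empty to
#'   list the directory.
#' @return absolute path.
#' @export
pigmentnet_extdata <- function(file = "") {
  system.file("extdata", file, package = "pigmentnet", mustWork = nzchar(file))
}

#' The published sample interaction network
#'
#' The 20 curated rows of the sample interaction table, verbatim: a
#' 21-node, 20-edge slice of the pigmentation model covering the UVA →
#' p53 → MSH/ACTH → MC1R cascade and the PGE2 → PLC → PKC → tyrosinase
#' route to eumelanin.
#'
#' @return a `signalling_network`.
#' @export
#' @examples
#' table1_fixture()
table1_fixture <- function() {
  tab <- parse_interaction_table(pigmentnet_extdata("table1_interactions.tsv"))
  build_network(tab$records, tab$nodes)
}

#' The curated source and target designations
#'
#' The 20 trigger/receptor sources (including UVA and UVB) and 9 phenotypic
#' end-process targets selected for source-to-target path analysis,
#' verbatim.
#'
#' @return list with character vectors `sources` and `targets`.
#' @export
table2_designations <- function() {
  read_designations(pigmentnet_extdata("table2_designations.tsv"))
}

#' The printed pathway strings
#'
#' All predicted, control and alternate routes printed in the published
#' pathway tables, one row per route, with the process label, its role and
#' the perturbed gene (alternate routes reading `"None"` mark abrogated
#' pairs and induce no edges). Composite terminals
#' (eumelanin/pheomelanin) are split into one row per terminal; the
#' distinct terminal spellings of the melanogenesis end process are kept
#' exactly as printed.
#'
#' @return data frame `table`, `process`, `role`, `perturbed`, `path`.
#' @export
printed_paths_table <- function() {
  read.delim(pigmentnet_extdata("printed_paths.tsv"), sep = "\t",
             header = TRUE, colClasses = "character", check.names = FALSE,
             na.strings = "NA")
}

#' Network induced by the printed pathway strings
#'
#' Union of every edge induced by consecutive node pairs of the printed
#' routes (interaction type `activates` throughout: the pathway tables
#' print bare node sequences). Sources are the path-initial nodes (the UV,
#' UVA and UVB triggers, kept distinct exactly as printed) and targets the
#' path-terminal nodes; each printed route re-traces in the result with its
#' printed length.
#'
#' @return a `signalling_network` with designations.
#' @export
printed_paths_fixture <- function() {
  tab <- printed_paths_table()
  strings <- tab$path[tab$path != "None"]
  seqs <- lapply(strings, parse_path_string)
  from <- unlist(lapply(seqs, function(s) s[-length(s)]), use.names = FALSE)
  to <- unlist(lapply(seqs, function(s) s[-1]), use.names = FALSE)
  records <- data.frame(node_a = from, node_b = to,
                        interaction_type = "activates",
                        stringsAsFactors = FALSE)
  net <- suppressWarnings(build_network(records))
  set_designations(
    net,
    sources = unique(vapply(seqs, `[[`, character(1), 1L)),
    targets = unique(vapply(seqs, function(s) s[[length(s)]], character(1)))
  )
}
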