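#' @importFrom utils read.delim write.table
#' @importFrom stats setNames rpois rbinom runif
NULL

# Controlled vocabulary of curated interaction types (canonical lower-case).
interaction_vocabulary <- c(
  "activates", "inhibits", "induces",
  "increases level", "increases expression",
  "decreases level", "decreases expression",
  "third molecule regulation"
)

#' Normalise a node name
#'
#' Trims leading/trailing whitespace and collapses internal whitespace runs
#' to single underscores. Case is preserved: node identifiers are
#' case-significant (compartment twins such as `MC1R_kerat` / `MC1R_melan`
#' must not be conflated).
#'
#' @param x character vector of raw node names.
#' @return character vector of canonical node identifiers.
#' @export
#' @examples
#' normalise_node_name("  Lipid Peroxidation_kerat ")
normalise_node_name <- function(x) {
  gsub("\\s+", "_", trimws(x))
}

#' Canonicalise an interaction type
#'
#' Lower-cases and collapses whitespace. Strings outside the controlled
#' vocabulary are preserved in this canonical form but reported as
#' unrecognised by [is_known_interaction_type()].
#'
#' @param x character vector of interaction-type strings.
#' @return canonical lower-case types.
#' @export
canonicalise_interaction_type <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' @rdname canonicalise_interaction_type
#' @export
is_known_interaction_type <- function(x) {
  canonicalise_interaction_type(x) %in% interaction_vocabulary
}

# Classed conditions so callers (and the pipeline driver) can distinguish
# schema, lookup, value and consistency failures.
pn_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "pigmentnet_error")))
}

pn_schema_error      <- function(msg) pn_abort(msg, "pigmentnet_schema_error")
pn_lookup_error      <- function(msg) pn_abort(msg, "pigmentnet_lookup_error")
pn_value_error       <- function(msg) pn_abort(msg, "pigmentnet_value_error")
pn_consistency_error <- function(msg) pn_abort(msg, "pigmentnet_consistency_error")

#' Path-string arrow dialect
#'
#' Signalling routes serialise as `"A- > B- > C"`, the dialect used for the
#' printed pathway tables. `parse_path_string()` accepts flexible whitespace
#' around the arrow and normalises each node name.
#'
#' @param nodes ordered character vector of node ids.
#' @param s a single path string.
#' @return `format_path_string()`: a single string; `parse_path_string()`:
#'   an ordered character vector of node ids.
#' @export
#' @examples
#' format_path_string(c("UVA", "Lipid_Peroxidation_kerat"))
#' parse_path_string("UVA- > Lipid_Peroxidation_kerat- > 4HNE_kerat")
format_path_string <- function(nodes) {
  paste(nodes, collapse = "- > ")
}

#' @rdname format_path_string
#' @export
parse_path_string <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  normalise_node_name(strsplit(s, "\\s*-\\s*>\\s*")[[1]])
}

# Lexicographic order of a list of equal-length character vectors.
# Returns the ordering permutation; used to pick canonical tied paths.
lexicographic_order <- function(seqs) {
  if (length(seqs) <= 1L) return(seq_along(seqs))
  len <- unique(lengths(seqs))
  stopifnot(length(len) == 1L)
  mat <- do.call(rbind, seqs)
  do.call(order, c(lapply(seq_len(ncol(mat)), function(j) mat[, j]),
                   list(method = "radix")))
}
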