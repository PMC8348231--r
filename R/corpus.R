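#' Substitution-type distribution of the curated solubility corpus
#'
#' Loads the bundled 20 x 20 table of substitution counts (original residue
#' in rows, variant residue in columns) describing the curated corpus of
#' 6328 labeled substitutions. Only the cell counts are stored; marginals are
#' computed, so bookkeeping identities (e.g. the leucine row summing to 659,
#' or the grand total of 6328) are derived, not asserted, by this loader.
#'
#' @param path Path to a substitution-count TSV; defaults to the bundled
#'   table.
#' @return A tibble with column `wt` and one integer column per mutant
#'   residue.
#' @export
substitution_counts <- function(path = system.file(
  "extdata", "substitution_counts.tsv", package = "solvar", mustWork = TRUE)) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(identical(df$wt, canonical_residues()),
            identical(sort(setdiff(names(df), "wt")),
                      canonical_residues()))
  tibble::as_tibble(df)
}
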