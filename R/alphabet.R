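#' Canonical amino acid alphabet and residue classifications
#'
#' The package works exclusively over the 20 canonical one-letter amino acid
#' codes; ambiguity and non-standard codes (B, J, O, U, X, Z) are rejected at
#' parse time because every feature table is defined over the 20-letter
#' alphabet.
#'
#' @return `canonical_residues()` returns a character vector of the 20
#'   one-letter codes in alphabetical order.
#' @export
canonical_residues <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' @rdname canonical_residues
#' @details `residue_groups()` returns the six-group partition of the alphabet
#'   used for the 6 x 6 substitution-group indicator features: hydrophobic
#'   (V, I, L, F, M, W, Y, C), negatively charged (D, E), positively charged
#'   (R, K, H), conformational (G, P), polar (N, Q, S), and other (A, T).
#'   The groups are disjoint and cover all 20 residues.
#' @export
residue_groups <- function() {
  list(
    hydrophobic    = c("V", "I", "L", "F", "M", "W", "Y", "C"),
    negative       = c("D", "E"),
    positive       = c("R", "K", "H"),
    conformational = c("G", "P"),
    polar          = c("N", "Q", "S"),
    other          = c("A", "T")
  )
}

#' @rdname canonical_residues
#' @details `neighborhood_classes()` returns the residue classes used for the
#'   five neighborhood-window summary counts (NonPolarAA, PolarAA, ChargedAA,
#'   PosAA, NegAA). Charged is the union of the positive and negative sets, so
#'   PosAA + NegAA = ChargedAA always holds. This partition (nonpolar
#'   A,V,L,I,P,F,M,W,G; polar S,T,C,Y,N,Q; positive K,R,H; negative D,E) is
#'   the standard biochemical polarity/charge classification; it is
#'   deliberately distinct from the six-group substitution partition above.
#' @export
neighborhood_classes <- function() {
  list(
    nonpolar = c("A", "V", "L", "I", "P", "F", "M", "W", "G"),
    polar    = c("S", "T", "C", "Y", "N", "Q"),
    positive = c("K", "R", "H"),
    negative = c("D", "E")
  )
}

#' @rdname canonical_residues
#' @details `solubility_classes()` returns the fixed class order used in every
#'   confusion matrix and report: decrease, no_effect, increase.
#' @export
solubility_classes <- function() {
  c("decrease", "no_effect", "increase")
}

# internal: vectorized residue validation with informative positions
assert_canonical <- function(residues, what = "residue") {
  bad <- which(!residues %in% canonical_residues())
  if (length(bad) > 0) {
    stop(sprintf(
      "non-canonical %s '%s' at entry %d (only the 20 canonical one-letter codes are accepted)",
      what, residues[bad[1]], bad[1]
    ), call. = FALSE)
  }
  invisible(residues)
}
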