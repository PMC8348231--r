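#' Feature sets of the shipped two-layer predictor
#'
#' The default predictor uses 20 features per binary layer, selected by
#' recursive feature elimination; six are shared, so 34 distinct features
#' appear overall. `feature_set_layer1()` names the features of the
#' decreasing / not-decreasing layer, `feature_set_layer2()` those of the
#' increasing / no-effect layer (both in decreasing order of importance), and
#' `feature_set_final()` their union.
#'
#' @return Character vector of feature names.
#' @export
feature_set_layer1 <- function() {
  c("FUKS010101", "JOND920102", "PONP800107", "NonPolarAA", "PolarAA",
    "QIAN880134", "AA20D.T", "PosAA", "AA20D.L", "GEOR030102",
    "OOBM850102", "length", "AA20D.I", "AA20D.P", "KOSJ950115",
    "ARGP820102", "PRAM820103", "AA20D.V", "ZIMJ680104", "CHOP780209")
}

#' @rdname feature_set_layer1
#' @export
feature_set_layer2 <- function() {
  c("VASM830102", "PRAM820103", "DAYM780201", "ChargedAA", "DOSZ010102",
    "NonPolarAA", "PRAM820101", "BROC820102", "PolarAA", "MIRL960101",
    "AA20D.D", "VASM830101", "SUYM030101", "length", "FASG760103",
    "CHOP780213", "AA20D.L", "LIFS790102", "PosAA", "AA20D.G")
}

#' @rdname feature_set_layer1
#' @export
feature_set_final <- function() {
  union(feature_set_layer1(), feature_set_layer2())
}

#' AAindex substitution deltas
#'
#' For every scale in the table, the feature value of a substitution is the
#' mutant value minus the wild-type value. The encoding is antisymmetric:
#' reversing the substitution negates every delta.
#'
#' @param wt,mut Character vectors of wild-type and mutant residues.
#' @param aaindex An AAindex table from [read_aaindex()].
#' @return A tibble with one column per accession, one row per substitution.
#' @export
aaindex_deltas <- function(wt, mut, aaindex) {
  assert_canonical(wt, "wild-type residue")
  assert_canonical(mut, "mutant residue")
  vals <- as.matrix(aaindex[, canonical_residues()])
  rownames(vals) <- NULL
  colnames(vals) <- canonical_residues()
  # rows = substitutions, columns = scales
  d <- t(vals[, mut, drop = FALSE] - vals[, wt, drop = FALSE])
  colnames(d) <- aaindex$accession
  tibble::as_tibble(d)
}

#' Substitution-type indicator features
#'
#' `substitution_onehot()` encodes the ordered (wild-type, mutant) pair over
#' the 20 x 20 substitution matrix: 400 indicators (`SUB.<wt>.<mut>`) with
#' exactly one equal to 1. `group_onehot()` does the same over the 6 x 6
#' residue-group matrix (`GRP.<from>.<to>`, 36 indicators; diagonal cells
#' encode within-group substitutions). Together they form the 436
#' variation-type features.
#'
#' @param wt,mut Character vectors of residues (`wt != mut` required for the
#'   20 x 20 encoding).
#' @return A tibble of 0/1 indicators, one row per substitution.
#' @export
substitution_onehot <- function(wt, mut) {
  assert_canonical(wt, "wild-type residue")
  assert_canonical(mut, "mutant residue")
  if (any(wt == mut)) stop("substitution requires wt != mut", call. = FALSE)
  aa <- canonical_residues()
  cells <- as.vector(t(outer(aa, aa, paste, sep = ".")))  # wt-major order
  m <- matrix(0L, nrow = length(wt), ncol = 400,
              dimnames = list(NULL, paste0("SUB.", cells)))
  m[cbind(seq_along(wt), match(paste0("SUB.", wt, ".", mut), colnames(m)))] <- 1L
  tibble::as_tibble(m)
}

# internal: map residues to their six-group name
residue_group_of <- function(residues, groups = residue_groups()) {
  lut <- stats::setNames(
    rep(names(groups), lengths(groups)), unlist(groups)
  )
  lut[residues]
}

#' @rdname substitution_onehot
#' @param groups Six-group residue partition, see [residue_groups()].
#' @export
group_onehot <- function(wt, mut, groups = residue_groups()) {
  assert_canonical(wt, "wild-type residue")
  assert_canonical(mut, "mutant residue")
  gn <- names(groups)
  cells <- as.vector(t(outer(gn, gn, paste, sep = ".")))
  m <- matrix(0L, nrow = length(wt), ncol = length(cells),
              dimnames = list(NULL, paste0("GRP.", cells)))
  from <- residue_group_of(wt, groups)
  to <- residue_group_of(mut, groups)
  m[cbind(seq_along(wt), match(paste0("GRP.", from, ".", to), colnames(m)))] <- 1L
  tibble::as_tibble(m)
}

#' Neighborhood window composition features
#'
#' Counts residues in the window of 23 sequence positions centered on the
#' substitution site (11 each side plus the site itself, which contributes
#' its wild-type residue). At sequence ends the window is truncated, never
#' padded, so counts sum to at most 23 and to exactly 23 at interior
#' positions. Returns the 20 per-residue counts (`AA20D.A` ... `AA20D.Y`)
#' plus the five class summaries `NonPolarAA`, `PolarAA`, `ChargedAA`,
#' `PosAA`, `NegAA` (with `ChargedAA = PosAA + NegAA` by construction).
#'
#' @param sequence A single protein sequence.
#' @param position Integer vector of 1-based window centers.
#' @param classes Polarity/charge classes, see [neighborhood_classes()].
#' @param halfwidth Window half-width (default 11 for the 23-wide window).
#' @return A tibble with 25 integer columns, one row per position.
#' @export
neighborhood_counts <- function(sequence, position,
                                classes = neighborhood_classes(),
                                halfwidth = 11L) {
  validate_sequence(sequence)
  n <- nchar(sequence)
  if (any(position < 1L | position > n)) {
    stop("window position out of range 1..", n, call. = FALSE)
  }
  chars <- strsplit(sequence, "")[[1]]
  aa <- canonical_residues()
  rows <- purrr::map(position, function(p) {
    win <- chars[max(1L, p - halfwidth):min(n, p + halfwidth)]
    tab <- table(factor(win, levels = aa))
    stats::setNames(as.integer(tab), paste0("AA20D.", aa))
  })
  counts <- tibble::as_tibble(do.call(rbind, rows))
  pick <- function(set) {
    rowSums(counts[, paste0("AA20D.", set), drop = FALSE])
  }
  counts$NonPolarAA <- as.integer(pick(classes$nonpolar))
  counts$PolarAA <- as.integer(pick(classes$polar))
  counts$PosAA <- as.integer(pick(classes$positive))
  counts$NegAA <- as.integer(pick(classes$negative))
  counts$ChargedAA <- counts$PosAA + counts$NegAA
  counts[, c(paste0("AA20D.", aa),
             "NonPolarAA", "PolarAA", "ChargedAA", "PosAA", "NegAA")]
}

#' Assemble the full feature vector for each variant
#'
#' Concatenates, per variant: one AAindex delta per supplied scale, the 436
#' variation-type indicators (20 x 20 substitution cells and 6 x 6
#' residue-group cells), the 25 neighborhood-window features, and the protein
#' length. Column order is deterministic. Conservation features (`SIFT`,
#' `nHits`) require external homology searches and are only available as an
#' all-missing stub, excluded by default.
#'
#' @param dataset A [solvar_dataset] (or anything accepted by it).
#' @param aaindex AAindex table; defaults to the bundled scales.
#' @param features Optional character vector restricting (and ordering) the
#'   returned feature columns, e.g. [feature_set_final()]. Requesting a name
#'   absent from the space is an error.
#' @param conservation If `TRUE`, append the two stub conservation columns
#'   (all `NA`).
#' @return A tibble with identifier columns `protein_id`, `variant` (and
#'   `label` when present), followed by the numeric feature columns.
#' @export
featurize <- function(dataset, aaindex = default_aaindex(), features = NULL,
                      conservation = FALSE) {
  stopifnot(inherits(dataset, "solvar_dataset"))
  v <- dataset$variants
  seqs <- stats::setNames(dataset$proteins$sequence,
                          dataset$proteins$protein_id)
  nb <- dplyr::bind_rows(purrr::map(seq_len(nrow(v)), function(i) {
    neighborhood_counts(seqs[[v$protein_id[i]]], v$position[i])
  }))
  feats <- dplyr::bind_cols(
    aaindex_deltas(v$wt, v$mut, aaindex),
    substitution_onehot(v$wt, v$mut),
    group_onehot(v$wt, v$mut),
    nb,
    tibble::tibble(length = unname(nchar(seqs[v$protein_id])))
  )
  if (conservation) {
    feats$SIFT <- NA_real_
    feats$nHits <- NA_real_
  }
  if (anyDuplicated(names(feats))) {
    stop("feature name collision: ", names(feats)[duplicated(names(feats))][1],
         call. = FALSE)
  }
  if (!is.null(features)) {
    missing <- setdiff(features, names(feats))
    if (length(missing) > 0) {
      stop("requested features absent from the feature space: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    feats <- feats[, features, drop = FALSE]
  }
  id_cols <- v[, intersect(c("protein_id", "variant", "label"), names(v))]
  dplyr::bind_cols(id_cols, feats)
}

# internal: split a featurized tibble into id columns and a numeric matrix
feature_matrix <- function(featurized, feature_names = NULL) {
  ids <- intersect(c("protein_id", "variant", "label"), names(featurized))
  x <- featurized[, setdiff(names(featurized), ids), drop = FALSE]
  if (!is.null(feature_names)) {
    missing <- setdiff(feature_names, names(x))
    if (length(missing) > 0) {
      stop("feature columns missing: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    x <- x[, feature_names, drop = FALSE]
  }
  as.matrix(x)
}

#' Write a feature matrix to TSV
#'
#' @param featurized Output of [featurize()].
#' @param path Output path.
#' @param header Optional comment lines (without `#`).
#' @return Invisibly, `path`.
#' @export
write_features <- function(featurized, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(featurized, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
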