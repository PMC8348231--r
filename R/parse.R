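#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased, whitespace is stripped, and every residue is
#' checked against the 20-letter canonical alphabet; a sequence containing
#' B, J, O, U, X, Z or any other character is rejected with the offending
#' position named.
#'
#' @param path Path to a FASTA file of amino acid sequences.
#' @return A tibble with columns `protein_id` (the word before the first
#'   whitespace of each header) and `sequence`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) {
    stop("FASTA file '", path, "' contains no sequences", call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  for (i in seq_along(seqs)) {
    validate_sequence(seqs[i], ids[i])
  }
  tibble::tibble(protein_id = ids, sequence = unname(seqs))
}

validate_sequence <- function(sequence, id = "<sequence>") {
  if (is.na(sequence) || nchar(sequence) == 0) {
    stop("empty sequence for protein '", id, "'", call. = FALSE)
  }
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% canonical_residues())
  if (length(bad) > 0) {
    stop(sprintf(
      "protein '%s': illegal residue '%s' at position %d",
      id, chars[bad[1]], bad[1]
    ), call. = FALSE)
  }
  invisible(sequence)
}

#' Parse amino acid substitution notation
#'
#' Accepts the compact one-letter notation `<wt><position><mut>` (for example
#' `L123S`: leucine 123 replaced by serine), with positions 1-based. An HGVS
#' protein-level `p.` prefix is tolerated and stripped. Synonymous tokens
#' (`L123L`) are rejected: a substitution must change the residue.
#'
#' @param x Character vector of substitution tokens.
#' @return A tibble with columns `variant` (the normalized token), `wt`,
#'   `position`, `mut`.
#' @examples
#' parse_variants(c("L123S", "p.A1P"))
#' @export
parse_variants <- function(x) {
  x <- sub("^p\\.", "", trimws(x))
  m <- regmatches(x, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", x))
  bad <- which(vapply(m, length, integer(1)) != 4L)
  if (length(bad) > 0) {
    stop("malformed variant token '", x[bad[1]], "' (expected e.g. L123S)",
         call. = FALSE)
  }
  wt <- toupper(vapply(m, `[`, character(1), 2))
  pos <- as.integer(vapply(m, `[`, character(1), 3))
  mut <- toupper(vapply(m, `[`, character(1), 4))
  assert_canonical(wt, "wild-type residue")
  assert_canonical(mut, "mutant residue")
  same <- which(wt == mut)
  if (length(same) > 0) {
    stop("'", x[same[1]], "' is not a substitution (wild-type equals mutant)",
         call. = FALSE)
  }
  if (any(pos < 1L)) stop("variant positions are 1-based", call. = FALSE)
  tibble::tibble(
    variant = paste0(wt, pos, mut),
    wt = wt, position = pos, mut = mut
  )
}

#' Labeled variant datasets
#'
#' A `solvar_dataset` couples a protein table with a variant table. Variants
#' are validated against the sequences: the referenced protein must exist,
#' the position must lie inside the sequence, and the stated wild-type
#' residue must match the sequence at that (1-based) position.
#'
#' @param proteins Tibble with columns `protein_id`, `sequence`.
#' @param variants Tibble with columns `protein_id`, `variant` (or `wt`,
#'   `position`, `mut`), and optionally `label` with values among
#'   `decrease`, `no_effect`, `increase`.
#' @return An object of class `solvar_dataset` with elements `proteins` and
#'   `variants` (tibbles).
#' @export
solvar_dataset <- function(proteins, variants) {
  proteins <- tibble::as_tibble(proteins)
  variants <- tibble::as_tibble(variants)
  stopifnot(all(c("protein_id", "sequence") %in% names(proteins)))
  if (anyDuplicated(proteins$protein_id)) {
    stop("duplicated protein ids in protein table", call. = FALSE)
  }
  purrr::walk2(proteins$sequence, proteins$protein_id, validate_sequence)
  if (!all(c("wt", "position", "mut") %in% names(variants))) {
    stopifnot("variant" %in% names(variants))
    parsed <- parse_variants(variants$variant)
    variants$variant <- parsed$variant
    variants$wt <- parsed$wt
    variants$position <- parsed$position
    variants$mut <- parsed$mut
  }
  if (!"variant" %in% names(variants)) {
    variants$variant <- paste0(variants$wt, variants$position, variants$mut)
  }
  if ("label" %in% names(variants)) {
    known <- is.na(variants$label) | variants$label %in% solubility_classes()
    if (!all(known)) {
      stop("unknown label token '", variants$label[which(!known)[1]],
           "' (expected decrease, no_effect or increase)", call. = FALSE)
    }
  }
  unknown <- !variants$protein_id %in% proteins$protein_id
  if (any(unknown)) {
    stop("row ", which(unknown)[1], ": unknown protein id '",
         variants$protein_id[which(unknown)[1]], "'", call. = FALSE)
  }
  seqs <- stats::setNames(proteins$sequence, proteins$protein_id)
  len <- nchar(seqs[variants$protein_id])
  out_of_range <- variants$position > len
  if (any(out_of_range)) {
    i <- which(out_of_range)[1]
    stop(sprintf("row %d: position %d exceeds length %d of protein '%s'",
                 i, variants$position[i], len[i], variants$protein_id[i]),
         call. = FALSE)
  }
  at_pos <- substr(seqs[variants$protein_id], variants$position, variants$position)
  mismatch <- at_pos != variants$wt
  if (any(mismatch)) {
    i <- which(mismatch)[1]
    stop(sprintf(
      "row %d: wild-type residue of '%s' is stated as %s but the sequence of '%s' has %s at position %d",
      i, variants$variant[i], variants$wt[i], variants$protein_id[i],
      at_pos[i], variants$position[i]), call. = FALSE)
  }
  core <- c("protein_id", "variant", "wt", "position", "mut",
            intersect("label", names(variants)))
  structure(
    list(proteins = proteins, variants = variants[, core]),
    class = "solvar_dataset"
  )
}

#' @export
print.solvar_dataset <- function(x, ...) {
  cat("<solvar_dataset> ", nrow(x$variants), " variants on ",
      nrow(x$proteins), " proteins\n", sep = "")
  if ("label" %in% names(x$variants)) {
    cc <- class_counts(x)
    cat("  class counts: ",
        paste(names(cc), cc, sep = " = ", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @rdname solvar_dataset
#' @param dataset A `solvar_dataset`.
#' @return `class_counts()` returns a named integer vector of label counts in
#'   the fixed class order.
#' @export
class_counts <- function(dataset) {
  stopifnot(inherits(dataset, "solvar_dataset"),
            "label" %in% names(dataset$variants))
  tab <- table(factor(dataset$variants$label, levels = solubility_classes()))
  stats::setNames(as.integer(tab), names(tab))
}

# internal: subset a dataset by variant row index, dropping unused proteins
subset_dataset <- function(dataset, idx) {
  v <- dataset$variants[idx, , drop = FALSE]
  p <- dataset$proteins[dataset$proteins$protein_id %in% v$protein_id, ]
  structure(list(proteins = p, variants = v), class = "solvar_dataset")
}

# permissive column-name mapping for on-disk variant tables
.col_aliases <- list(
  protein_id = c("protein_id", "protein", "id", "accession", "acc"),
  variant    = c("variant", "substitution", "aas", "mutation"),
  label      = c("label", "class", "effect")
)

map_columns <- function(df) {
  for (canon in names(.col_aliases)) {
    if (canon %in% names(df)) next
    hit <- intersect(.col_aliases[[canon]], tolower(names(df)))
    if (length(hit) > 0) {
      names(df)[match(hit[1], tolower(names(df)))] <- canon
    }
  }
  df
}

#' Load a labeled dataset from a variants TSV and a companion FASTA
#'
#' The canonical on-disk form is a tab-separated table with columns
#' `protein_id`, `variant`, `label` plus a FASTA file of the referenced
#' sequences. Obvious column-name variants (protein/accession,
#' substitution/mutation, class/effect) are mapped onto the canonical names.
#' Lines starting with `#` are treated as comments.
#'
#' @param tsv_path Path to the variant table.
#' @param fasta_path Path to the companion FASTA file.
#' @param on_duplicate What to do with duplicated (protein, variant) rows:
#'   `"error"` (default) or `"dedup"` (keep the first).
#' @return A [solvar_dataset].
#' @export
read_dataset <- function(tsv_path, fasta_path,
                         on_duplicate = c("error", "dedup")) {
  on_duplicate <- match.arg(on_duplicate)
  proteins <- read_fasta(fasta_path)
  df <- utils::read.delim(tsv_path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  df <- map_columns(tibble::as_tibble(df))
  need <- c("protein_id", "variant")
  if (!all(need %in% names(df))) {
    stop("variant table must have columns protein_id and variant", call. = FALSE)
  }
  key <- paste(df$protein_id, df$variant)
  if (anyDuplicated(key)) {
    if (on_duplicate == "error") {
      stop("duplicated variant row: ", key[duplicated(key)][1], call. = FALSE)
    }
    df <- df[!duplicated(key), ]
  }
  solvar_dataset(proteins, df)
}

#' Write a dataset back to its canonical TSV + FASTA form
#'
#' Inverse of [read_dataset()]: a round trip reproduces identical records and
#' class counts.
#'
#' @param dataset A [solvar_dataset].
#' @param tsv_path,fasta_path Output paths.
#' @param header Optional comment lines (without `#`) written atop the TSV.
#' @return Invisibly, `dataset`.
#' @export
write_dataset <- function(dataset, tsv_path, fasta_path, header = NULL) {
  stopifnot(inherits(dataset, "solvar_dataset"))
  con <- file(tsv_path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  cols <- intersect(c("protein_id", "variant", "label"),
                    names(dataset$variants))
  utils::write.table(dataset$variants[, cols], con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(paste0(">", dataset$proteins$protein_id, "\n",
                    dataset$proteins$sequence), fasta_path)
  invisible(dataset)
}
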