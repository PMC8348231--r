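#' Read amino acid property scales from an AAindex1 flat file
#'
#' Parses the AAindex1 dialect: records delimited by `//`, with `H` lines
#' giving the accession, `D` lines the description, and an `I` line followed
#' by two rows of ten values in the standard residue order
#' (A R N D C Q E G H I / L K M F P S T W Y V). Entries with any missing
#' (`NA`) value are dropped, since a substitution delta cannot be formed from
#' an incomplete scale; an unparseable record is skipped with a warning.
#'
#' @param path Path to an AAindex1-format file.
#' @return A tibble with columns `accession`, `description`, and one numeric
#'   column per canonical residue (alphabetical order). Errors if no complete
#'   entry is retained.
#' @export
read_aaindex <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty AAindex file: ", path, call. = FALSE)
  rec_end <- which(trimws(lines) == "//")
  if (length(rec_end) == 0) stop("no AAindex records (missing '//') in ", path,
                                 call. = FALSE)
  starts <- c(1L, utils::head(rec_end, -1) + 1L)
  # residue order of the two value rows in AAindex1
  order_i <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  recs <- purrr::map2(starts, rec_end, function(s, e) {
    block <- lines[s:(e - 1)]
    acc <- sub("^H\\s+", "", grep("^H\\s", block, value = TRUE)[1])
    desc <- sub("^D\\s+", "", grep("^D\\s", block, value = TRUE)[1])
    i_at <- grep("^I\\s", block)
    if (is.na(acc) || length(i_at) == 0 || i_at[1] + 2 > length(block)) {
      warning("skipping unparseable AAindex record near line ", s,
              call. = FALSE)
      return(NULL)
    }
    vals <- suppressWarnings(as.numeric(unlist(
      strsplit(trimws(block[i_at[1] + 1:2]), "\\s+")
    )))
    if (length(vals) != 20) {
      warning("skipping AAindex record '", acc, "': expected 20 values",
              call. = FALSE)
      return(NULL)
    }
    if (anyNA(vals)) return(NULL)   # incomplete scale: silently dropped
    row <- stats::setNames(as.list(vals), order_i)[canonical_residues()]
    tibble::tibble(accession = acc,
                   description = ifelse(is.na(desc), "", desc), !!!row)
  })
  out <- dplyr::bind_rows(recs)
  if (nrow(out) == 0) {
    stop("no complete AAindex entries retained from ", path, call. = FALSE)
  }
  if (anyDuplicated(out$accession)) {
    stop("duplicated AAindex accession in ", path, call. = FALSE)
  }
  out
}

#' Write an AAindex table back to the AAindex1 flat-file dialect
#'
#' @param table A tibble as returned by [read_aaindex()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_aaindex <- function(table, path) {
  order_i <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(table))) {
    vals <- as.numeric(table[i, order_i])
    writeLines(c(
      paste("H", table$accession[i]),
      paste("D", table$description[i]),
      paste("I", "   A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V"),
      paste0("  ", paste(formatC(vals[1:10], width = 7, format = "g"), collapse = " ")),
      paste0("  ", paste(formatC(vals[11:20], width = 7, format = "g"), collapse = " ")),
      "//"
    ), con)
  }
  invisible(path)
}

#' The AAindex scales shipped with the package
#'
#' Loads the bundled AAindex1-format files: `aaindex_core.txt` (scales taken
#' verbatim from the public AAindex database) and, when `include_standins` is
#' `TRUE`, `aaindex_synthetic_standins.txt`, which holds synthetic stand-in
#' scales for the few accessions of the default feature set that are absent
#' from the bundled snapshot. Stand-ins carry real accession names so the
#' default feature set resolves, but their values are synthetic; their
#' descriptions say so.
#'
#' @param include_standins Include the synthetic stand-in scales (default
#'   `TRUE`, so the full default feature set is computable).
#' @return A tibble as returned by [read_aaindex()].
#' @export
default_aaindex <- function(include_standins = TRUE) {
  core <- read_aaindex(system.file("extdata", "aaindex_core.txt",
                                   package = "solvar", mustWork = TRUE))
  if (include_standins) {
    st <- read_aaindex(system.file("extdata", "aaindex_synthetic_standins.txt",
                                   package = "solvar", mustWork = TRUE))
    core <- dplyr::bind_rows(core, st)
  }
  core
}
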