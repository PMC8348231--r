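# Shared fixtures, built in code at test time.

tiny_proteins <- function() {
  tibble::tibble(
    protein_id = c("p1", "p2"),
    sequence = c("MKLVANNSTQWERPLKHGDC", "AAAAAAAAAAAAAAAAAAAAAAAAAAAAAA")
  )
}

tiny_dataset <- function() {
  solvar_dataset(
    tiny_proteins(),
    tibble::tibble(
      protein_id = c("p1", "p1", "p2"),
      variant = c("L3S", "K2R", "A15P"),
      label = c("decrease", "increase", "no_effect")
    )
  )
}

# write a dataset to temp TSV + FASTA, returning the two paths
write_tmp_dataset <- function(ds) {
  tsv <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  fa <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  write_dataset(ds, tsv, fa)
  list(tsv = tsv, fasta = fa)
}

# fast hyperparameters for tests that exercise fitting, not accuracy
fast_params <- function(nrounds = 30, max_depth = 3) {
  gbt_params(nrounds = nrounds, eta = 0.3, max_depth = max_depth)
}

# a synthetic AAindex table with n complete scales (for speed / RFE spaces)
synthetic_aaindex <- function(n = 5, seed = 99) {
  set.seed(seed)
  vals <- matrix(round(stats::rnorm(20 * n), 3), nrow = n,
                 dimnames = list(NULL, canonical_residues()))
  dplyr::bind_cols(
    tibble::tibble(accession = sprintf("SYNT%02d0101", seq_len(n)),
                   description = "synthetic test scale"),
    tibble::as_tibble(vals)
  )
}

# linearly separable two-feature binary problem
separable_toy <- function(n = 200, seed = 1) {
  set.seed(seed)
  x <- matrix(stats::rnorm(2 * n), ncol = 2,
              dimnames = list(NULL, c("f1", "f2")))
  y <- factor(ifelse(x[, 1] > 0, "pos", "neg"))
  x[, 1] <- x[, 1] + ifelse(y == "pos", 2, -2)  # wide margin
  list(x = x, y = y)
}

# planted-signal matrix: one informative column among `p_noise` noise columns
planted_signal <- function(n = 500, p_noise = 50, seed = 1, flip = 0.05) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * (p_noise + 1)), nrow = n)
  colnames(x) <- c("signal", sprintf("noise%02d", seq_len(p_noise)))
  y <- x[, "signal"] > 0
  y <- xor(y, stats::runif(n) < flip)
  list(x = x, y = factor(ifelse(y, "a", "b")))
}
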