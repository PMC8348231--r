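#' Specification for a synthetic labeled dataset
#'
#' The generator emulates the shape of a curated solubility-variant corpus:
#' a modest number of proteins, many substitutions, several substitutions per
#' site (so position-grouped splitting is exercised), and a class imbalance
#' matching the curated corpus ratios (decrease : no_effect : increase =
#' 3136 : 2166 : 1026 by default).
#'
#' Labels come from a planted rule with probability `signal`, and are drawn
#' from the class proportions otherwise. The rule is deliberately expressed
#' through features the model can see — the residue-group substitution cell
#' and the nonpolar neighborhood count — so learnability at high signal is
#' guaranteed and feature selection has a known ground truth:
#' \itemize{
#'   \item wild-type hydrophobic, mutant not: increase (a buried hydrophobic
#'     residue is lost);
#'   \item mutant hydrophobic, wild-type not: decrease;
#'   \item otherwise: decrease when the window's nonpolar count is at least
#'     14, no_effect otherwise.
#' }
#'
#' @param n_proteins Number of random proteins.
#' @param length_range Sequence length range (min 23 recommended so interior
#'   windows are full).
#' @param n_variants Total substitutions to generate.
#' @param class_proportions Named proportions over the three classes used for
#'   the noise component; default scaled from 3136/2166/1026.
#' @param signal Probability in [0, 1] that a variant's label follows the
#'   planted rule rather than the noise distribution.
#' @param max_per_position Up to this many distinct substitutions are placed
#'   at each sampled site.
#' @param seed Integer seed; the same spec and seed give a byte-identical
#'   dataset.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_proteins = 8, length_range = c(80, 400),
                         n_variants = 1500,
                         class_proportions = c(decrease = 3136,
                                               no_effect = 2166,
                                               increase = 1026) / 6328,
                         signal = 0.9, max_per_position = 4, seed = 1L) {
  stopifnot(abs(sum(class_proportions) - 1) < 1e-8,
            setequal(names(class_proportions), solubility_classes()),
            signal >= 0, signal <= 1,
            length_range[1] >= 2, length_range[2] >= length_range[1])
  structure(
    list(n_proteins = n_proteins, length_range = length_range,
         n_variants = n_variants, class_proportions = class_proportions,
         signal = signal, max_per_position = max_per_position, seed = seed),
    class = "fixture_spec"
  )
}

# the planted rule: deterministic label from feature-visible quantities
planted_rule <- function(wt, mut, nonpolar_count) {
  hydro <- residue_groups()$hydrophobic
  dplyr::case_when(
    wt %in% hydro & !mut %in% hydro ~ "increase",
    mut %in% hydro & !wt %in% hydro ~ "decrease",
    nonpolar_count >= 14 ~ "decrease",
    TRUE ~ "no_effect"
  )
}

#' Generate a synthetic labeled dataset
#'
#' @param spec A [fixture_spec()].
#' @return A labeled [solvar_dataset] that passes all dataset validators.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  aa <- canonical_residues()
  lens <- sample(spec$length_range[1]:spec$length_range[2],
                 spec$n_proteins, replace = TRUE)
  proteins <- tibble::tibble(
    protein_id = sprintf("SYN%03d", seq_len(spec$n_proteins)),
    sequence = vapply(lens, function(L) {
      paste(sample(aa, L, replace = TRUE), collapse = "")
    }, character(1))
  )
  n_positions <- sum(lens)
  if (spec$n_variants > n_positions * 19) {
    stop("infeasible spec: ", spec$n_variants, " variants requested but only ",
         n_positions * 19, " distinct substitutions exist", call. = FALSE)
  }
  # sample sites, then several distinct substitutions per site
  site_pool <- tibble::tibble(
    protein_id = rep(proteins$protein_id, lens),
    position = unlist(lapply(lens, seq_len))
  )
  rows <- list()
  n_left <- spec$n_variants
  ord <- sample(nrow(site_pool))
  i <- 1
  while (n_left > 0 && i <= length(ord)) {
    site <- site_pool[ord[i], ]
    wt <- substr(proteins$sequence[proteins$protein_id == site$protein_id],
                 site$position, site$position)
    n_here <- min(sample(spec$max_per_position, 1), n_left, 19)
    muts <- sample(setdiff(aa, wt), n_here)
    rows[[length(rows) + 1]] <- tibble::tibble(
      protein_id = site$protein_id, position = site$position,
      wt = wt, mut = muts
    )
    n_left <- n_left - n_here
    i <- i + 1
  }
  v <- dplyr::bind_rows(rows)
  # labels: planted rule with probability `signal`, class-proportion noise
  # otherwise
  seqs <- stats::setNames(proteins$sequence, proteins$protein_id)
  nonpolar <- vapply(seq_len(nrow(v)), function(i) {
    neighborhood_counts(seqs[[v$protein_id[i]]], v$position[i])$NonPolarAA
  }, integer(1))
  rule_label <- planted_rule(v$wt, v$mut, nonpolar)
  noise_label <- sample(names(spec$class_proportions), nrow(v),
                        replace = TRUE, prob = spec$class_proportions)
  use_rule <- stats::runif(nrow(v)) < spec$signal
  v$label <- ifelse(use_rule, rule_label, noise_label)
  v$variant <- paste0(v$wt, v$position, v$mut)
  solvar_dataset(proteins, v)
}
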