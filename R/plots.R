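#' Plot a confusion matrix as a heat map
#'
#' @param object A `solvar_confusion`.
#' @param ... Unused.
#' @return A ggplot object (true class on rows, predicted on columns, cell
#'   counts printed; normalized counts to one decimal).
#' @export
autoplot.solvar_confusion <- function(object, ...) {
  df <- tidy.solvar_confusion(object)
  digits <- if (object$normalized) 1 else 0
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted,
                                   y = factor(.data$true,
                                              levels = rev(object$classes)),
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$n, digits))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted class", y = "true class",
                  fill = if (object$normalized) "weighted n" else "n",
                  title = if (object$normalized) {
                    "Confusion matrix (class-size normalized)"
                  } else "Confusion matrix") +
    ggplot2::theme_minimal()
}

#' Plot per-layer feature importance
#'
#' @param model A `solvar_two_layer` or `solvar_single` model.
#' @param top_n Show at most this many features per layer.
#' @return A ggplot object.
#' @export
plot_importance <- function(model, top_n = 20) {
  df <- tidy(model)
  if (!"layer" %in% names(df)) df$layer <- "three-class"
  df <- df |>
    dplyr::group_by(.data$layer) |>
    dplyr::slice_max(.data$gain, n = top_n, with_ties = FALSE) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gain,
                                   y = stats::reorder(.data$feature,
                                                      .data$gain))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~layer, scales = "free_y") +
    ggplot2::labs(x = "gain importance", y = NULL) +
    ggplot2::theme_minimal()
}

#' All possible substitutions at every position of a protein
#'
#' Builds the 19 x L saturation set used for protein-wide effect maps.
#'
#' @param protein_id,sequence Identifier and sequence of one protein.
#' @return A tibble of `19 * nchar(sequence)` variant rows.
#' @export
saturation_variants <- function(protein_id, sequence) {
  validate_sequence(sequence, protein_id)
  chars <- strsplit(sequence, "")[[1]]
  aa <- canonical_residues()
  purrr::map_dfr(seq_along(chars), function(p) {
    tibble::tibble(protein_id = protein_id, position = p, wt = chars[p],
                   mut = setdiff(aa, chars[p]))
  }) |>
    dplyr::mutate(variant = paste0(.data$wt, .data$position, .data$mut))
}

#' Per-position map of predicted substitution effects
#'
#' Tile map over positions (x) and mutant residues (y), colored by predicted
#' class — the protein-wide view produced by saturation prediction.
#'
#' @param predictions A tibble with columns `position`, `mut` and
#'   `.pred_class` (e.g. saturation predictions joined to their variants).
#' @return A ggplot object.
#' @export
plot_saturation <- function(predictions) {
  stopifnot(all(c("position", "mut", ".pred_class") %in% names(predictions)))
  ggplot2::ggplot(predictions,
                  ggplot2::aes(x = .data$position, y = .data$mut,
                               fill = .data$.pred_class)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(decrease = "#d73027",
                                          no_effect = "#cccccc",
                                          increase = "#4575b4")) +
    ggplot2::labs(x = "sequence position", y = "mutant residue",
                  fill = "predicted effect") +
    ggplot2::theme_minimal()
}
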