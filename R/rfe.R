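#' Recursive feature elimination
#'
#' Fits the gradient-boosted classifier on the current feature set, ranks
#' features by gain importance, drops the least important `step` features,
#' and repeats until `target_k` features remain. The full elimination order
#' is recorded (last eliminated = most important among the eliminated);
#' features still selected at the end rank above all eliminated ones, in
#' final-fit importance order. Ties in importance (typically several features
#' with zero gain) are broken deterministically: among tied features the one
#' latest in column order is dropped first.
#'
#' @param x Feature matrix or featurized tibble.
#' @param y Class labels (binary or multiclass).
#' @param target_k Number of features to retain (>= 1).
#' @param step Features dropped per iteration (the final iteration drops
#'   fewer if needed so exactly `target_k` remain).
#' @param params,seed Passed to [fit_gbt()]; the same seed is used for every
#'   refit so the procedure is reproducible end to end.
#' @return An object of class `solvar_rfe`: list with `selected` (character,
#'   in final importance order), `ranking` (tibble `feature`, `rank`, 1 =
#'   most important) and `eliminated` (in elimination order).
#' @export
rfe_select <- function(x, y, target_k, step = 1L,
                       params = gbt_params(), seed = 1L) {
  if (is.data.frame(x)) x <- feature_matrix(x)
  stopifnot(target_k >= 1, step >= 1)
  if (target_k > ncol(x)) {
    stop("target_k (", target_k, ") exceeds the feature count (", ncol(x), ")",
         call. = FALSE)
  }
  current <- colnames(x)
  eliminated <- character(0)
  model <- NULL
  repeat {
    model <- fit_gbt(x[, current, drop = FALSE], y, params, seed)
    if (length(current) == target_k) break
    imp <- feature_importance(model)
    # ascending importance; among ties, later column order drops first
    ord <- order(imp$gain[match(current, imp$feature)],
                 -seq_along(current))
    n_drop <- min(step, length(current) - target_k)
    drop <- current[ord][seq_len(n_drop)]
    eliminated <- c(eliminated, drop)
    current <- setdiff(current, drop)
  }
  final_imp <- feature_importance(model)
  selected <- final_imp$feature
  ranking <- tibble::tibble(
    feature = c(selected, rev(eliminated)),
    rank = seq_len(ncol(x))
  )
  structure(
    list(selected = selected, ranking = ranking, eliminated = eliminated,
         target_k = target_k, step = step, seed = seed),
    class = "solvar_rfe"
  )
}

#' @export
print.solvar_rfe <- function(x, ...) {
  cat("<solvar_rfe> selected ", length(x$selected), " of ",
      nrow(x$ranking), " features (step ", x$step, ")\n", sep = "")
  cat("  top: ", paste(utils::head(x$selected, 5), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.solvar_rfe <- function(x, ...) {
  dplyr::mutate(x$ranking, selected = .data$feature %in% x$selected)
}
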