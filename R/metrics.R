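#' Confusion matrices with optional class-size normalization
#'
#' `confusion_matrix()` tabulates predictions into a K x K matrix `z` with
#' rows = true class and columns = predicted class, in the fixed class order
#' (decrease, no_effect, increase by default).
#'
#' Because the solubility classes are heavily imbalanced, raw counts are
#' dominated by the majority class. `normalize_confusion()` rescales every
#' row i by the weight w_i = x_ref / x_i (x_i = true size of class i, x_ref =
#' size of the reference class, no_effect by default), so all true classes
#' count as if they had the reference class's size; the reference row itself
#' is unchanged. Ratio measures derived from a normalized matrix are
#' invariant to the choice of reference class, which only sets the overall
#' scale.
#'
#' @param truth,estimate Equal-length vectors of class labels.
#' @param classes Class order; defaults to [solubility_classes()].
#' @return An object of class `solvar_confusion`: list with `z` (K x K
#'   numeric matrix), `classes`, `normalized` flag and per-true-class
#'   `weights`.
#' @export
confusion_matrix <- function(truth, estimate, classes = solubility_classes()) {
  truth <- as.character(truth)
  estimate <- as.character(estimate)
  stopifnot(length(truth) == length(estimate))
  bad <- setdiff(unique(c(truth, estimate)), classes)
  if (length(bad) > 0) {
    stop("unknown class label: ", bad[1], call. = FALSE)
  }
  z <- table(factor(truth, levels = classes),
             factor(estimate, levels = classes))
  new_confusion(unclass(as.matrix(z)), classes)
}

new_confusion <- function(z, classes, normalized = FALSE,
                          weights = rep(1, length(classes))) {
  dimnames(z) <- list(true = classes, predicted = classes)
  structure(
    list(z = z, classes = classes, normalized = normalized,
         weights = stats::setNames(weights, classes)),
    class = "solvar_confusion"
  )
}

#' @export
print.solvar_confusion <- function(x, ...) {
  cat("<solvar_confusion> ", if (x$normalized) "normalized" else "raw",
      ", N = ", round(sum(x$z), 1), "\n", sep = "")
  print(round(x$z, 1))
  invisible(x)
}

#' @rdname confusion_matrix
#' @param cm A raw `solvar_confusion`.
#' @param reference Reference class whose size the other classes are rescaled
#'   to.
#' @export
normalize_confusion <- function(cm, reference = "no_effect") {
  stopifnot(inherits(cm, "solvar_confusion"))
  if (cm$normalized) stop("matrix is already normalized", call. = FALSE)
  x <- rowSums(cm$z)
  if (any(x == 0)) {
    stop("cannot normalize: empty true-class row (",
         paste(names(x)[x == 0], collapse = ", "), ")", call. = FALSE)
  }
  w <- class_weights(x, reference)
  new_confusion(cm$z * w, cm$classes, normalized = TRUE, weights = w)
}

#' @rdname confusion_matrix
#' @param class_sizes Named vector of true class sizes.
#' @return `class_weights()` returns the named per-true-class multipliers
#'   w_i = x_ref / x_i.
#' @export
class_weights <- function(class_sizes, reference = "no_effect") {
  stopifnot(reference %in% names(class_sizes), all(class_sizes > 0))
  class_sizes[[reference]] / class_sizes
}

#' @export
tidy.solvar_confusion <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$z, responseName = "n"))
}

#' Per-class one-vs-rest measures
#'
#' Reduces the K x K matrix to one-vs-rest counts per class j (as predicted
#' class): TP = z_jj, FP = column j minus TP, FN = row j minus TP, TN =
#' remainder, and the four ratios PPV = TP/(TP+FP), NPV = TN/(TN+FN),
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP). A 0/0 ratio is
#' reported as NaN, never silently as 0. On a normalized matrix the counts
#' are weighted; sensitivity and specificity are unchanged by normalization
#' (they are within-row ratios), while PPV and NPV change.
#'
#' @param cm A `solvar_confusion` (raw or normalized).
#' @return A tibble with columns `class`, `tp`, `tn`, `fp`, `fn`, `ppv`,
#'   `npv`, `sensitivity`, `specificity`.
#' @export
per_class_measures <- function(cm) {
  stopifnot(inherits(cm, "solvar_confusion"))
  z <- cm$z
  n <- sum(z)
  ratio <- function(a, b) ifelse(a + b == 0, NaN, a / (a + b))
  purrr::map_dfr(seq_along(cm$classes), function(j) {
    tp <- z[j, j]
    fp <- sum(z[, j]) - tp
    fn <- sum(z[j, ]) - tp
    tn <- n - tp - fp - fn
    tibble::tibble(
      class = cm$classes[j], tp = tp, tn = tn, fp = fp, fn = fn,
      ppv = ratio(tp, fp), npv = ratio(tn, fn),
      sensitivity = ratio(tp, fn), specificity = ratio(tn, fp)
    )
  })
}

#' Overall multi-class measures
#'
#' `cpr()` is the correct prediction ratio, the fraction of (possibly
#' weighted) cases on the diagonal. `gc2()` is the generalized squared
#' correlation: the Pearson chi-square statistic of the matrix against its
#' independence expectation e_ij = x_i * y_j / N, divided by N(K-1); it lies
#' in [0, 1], reaching 1 for a perfect classifier and 0 at independence. A
#' matrix with an empty row or column margin has an undefined GC2, reported
#' as NaN.
#'
#' @param cm A `solvar_confusion`.
#' @return A single number.
#' @export
cpr <- function(cm) {
  stopifnot(inherits(cm, "solvar_confusion"))
  n <- sum(cm$z)
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  sum(diag(cm$z)) / n
}

#' @rdname cpr
#' @export
gc2 <- function(cm) {
  stopifnot(inherits(cm, "solvar_confusion"))
  z <- cm$z
  n <- sum(z)
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  x <- rowSums(z)
  y <- colSums(z)
  if (any(x == 0) || any(y == 0)) return(NaN)
  e <- outer(x, y) / n
  chi2 <- sum((z - e)^2 / e)
  chi2 / (n * (length(cm$classes) - 1))
}

#' Evaluate predictions with raw and normalized reports
#'
#' Convenience wrapper producing both the raw and the class-size-normalized
#' confusion matrices plus all derived measures in one object.
#'
#' @inheritParams confusion_matrix
#' @inheritParams normalize_confusion
#' @return An object of class `solvar_eval`: list with `raw`, `normalized`
#'   (both `solvar_confusion`), `measures` (tibble with a `normalized`
#'   column), `cpr_raw`, `cpr_norm`, `gc2_raw`, `gc2_norm`.
#' @export
evaluate_predictions <- function(truth, estimate,
                                 classes = solubility_classes(),
                                 reference = "no_effect") {
  raw <- confusion_matrix(truth, estimate, classes)
  norm <- normalize_confusion(raw, reference)
  measures <- dplyr::bind_rows(
    dplyr::mutate(per_class_measures(raw), normalized = FALSE),
    dplyr::mutate(per_class_measures(norm), normalized = TRUE)
  )
  structure(
    list(raw = raw, normalized = norm, measures = measures,
         cpr_raw = cpr(raw), cpr_norm = cpr(norm),
         gc2_raw = gc2(raw), gc2_norm = gc2(norm)),
    class = "solvar_eval"
  )
}

#' @export
print.solvar_eval <- function(x, ...) {
  cat("<solvar_eval> N = ", sum(x$raw$z),
      "; CPR ", sprintf("%.3f/%.3f", x$cpr_raw, x$cpr_norm),
      "; GC2 ", sprintf("%.3f/%.3f", x$gc2_raw, x$gc2_norm),
      " (raw/normalized)\n", sep = "")
  invisible(x)
}

#' @export
tidy.solvar_eval <- function(x, ...) {
  x$measures
}

#' @export
glance.solvar_eval <- function(x, ...) {
  tibble::tibble(
    n = sum(x$raw$z),
    cpr_raw = x$cpr_raw, cpr_norm = x$cpr_norm,
    gc2_raw = x$gc2_raw, gc2_norm = x$gc2_norm
  )
}

#' Write a raw/normalized metrics report to TSV
#'
#' Long-format report: one row per (measure, class) with raw and normalized
#' value columns, followed by the overall CPR and GC2 rows. Normalized counts
#' are displayed to one decimal and ratios to three, with full precision
#' retained in the returned object.
#'
#' @param eval A `solvar_eval`.
#' @param path Output path.
#' @param header Optional comment lines (without `#`).
#' @return Invisibly, the report tibble.
#' @export
write_metrics_report <- function(eval, path, header = NULL) {
  m <- eval$measures
  raw <- m[!m$normalized, ]
  nrm <- m[m$normalized, ]
  fmt_count <- function(r, n) paste0(format(r, nsmall = 1), "/",
                                     format(round(n, 1), nsmall = 1))
  fmt_ratio <- function(r, n) sprintf("%.3f/%.3f", r, n)
  rows <- purrr::map_dfr(
    c(tp = "tp", tn = "tn", fp = "fp", fn = "fn",
      ppv = "ppv", npv = "npv",
      sensitivity = "sensitivity", specificity = "specificity"),
    function(col) {
      f <- if (col %in% c("tp", "tn", "fp", "fn")) fmt_count else fmt_ratio
      tibble::tibble(measure = col, class = raw$class,
                     value = f(raw[[col]], nrm[[col]]))
    }
  )
  rows <- dplyr::bind_rows(
    rows,
    tibble::tibble(measure = c("cpr", "gc2"), class = "all",
                   value = c(fmt_ratio(eval$cpr_raw, eval$cpr_norm),
                             fmt_ratio(eval$gc2_raw, eval$gc2_norm)))
  )
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}

#' Reconstruct a 3x3 confusion matrix from one-vs-rest marginals
#'
#' Published reports often print only per-class one-vs-rest counts, in raw
#' and class-size-normalized form. For three classes those jointly determine
#' the six off-diagonal cells: for each predicted class j the two
#' off-diagonal contributions satisfy a 2 x 2 linear system (their raw sum is
#' the raw FP_j; their weighted sum is the normalized FP_j). The solution is
#' rounded to integers and checked: raw FP and FN marginals must be met
#' exactly and the normalized FP reproduced within `tol` (printed normalized
#' counts are rounded to one decimal).
#'
#' @param tp Named vector of raw diagonal counts per class.
#' @param fp_raw,fp_norm Named vectors of raw and normalized false-positive
#'   counts per predicted class.
#' @param class_sizes Named vector of true class sizes (row sums).
#' @param reference Reference class of the normalization.
#' @param tol Tolerance on the reproduced normalized FP (default 0.06,
#'   covering one-decimal printing).
#' @return A raw `solvar_confusion`.
#' @export
reconstruct_confusion <- function(tp, fp_raw, fp_norm, class_sizes,
                                  reference = "no_effect", tol = 0.06) {
  classes <- names(class_sizes)
  stopifnot(length(classes) == 3,
            setequal(names(tp), classes),
            setequal(names(fp_raw), classes),
            setequal(names(fp_norm), classes))
  w <- class_weights(class_sizes, reference)
  z <- diag(tp[classes])
  dimnames(z) <- list(classes, classes)
  for (j in classes) {
    others <- setdiff(classes, j)
    if (abs(w[[others[1]]] - w[[others[2]]]) < 1e-9) {
      stop("cannot disambiguate predicted class '", j,
           "': the two contributing true classes have equal normalization ",
           "weights", call. = FALSE)
    }
    a <- rbind(c(1, 1), w[others])
    sol <- solve(a, c(fp_raw[[j]], fp_norm[[j]]))
    cell <- round(sol)
    if (any(cell < 0) || max(abs(sol - cell)) > 0.45) {
      stop("inconsistent marginals for predicted class '", j,
           "': no non-negative integer solution", call. = FALSE)
    }
    if (sum(cell) != fp_raw[[j]] ||
        abs(sum(w[others] * cell) - fp_norm[[j]]) > tol) {
      stop("inconsistent marginals for predicted class '", j, "'",
           call. = FALSE)
    }
    z[others, j] <- cell
  }
  if (!all(rowSums(z) == class_sizes[classes])) {
    stop("reconstructed row sums disagree with the stated class sizes",
         call. = FALSE)
  }
  new_confusion(z, classes)
}
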