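# Golden values in this file are the printed one-vs-rest counts of the
# published blind-test and cross-validation reports for this method family;
# they exercise the metric layer without any model fitting.

blind_sizes <- c(decrease = 338, no_effect = 237, increase = 87)

blind_34 <- function() {
  reconstruct_confusion(
    tp = c(decrease = 271, no_effect = 159, increase = 14),
    fp_raw = c(decrease = 66, no_effect = 106, increase = 46),
    fp_norm = c(decrease = 105.7, no_effect = 175.5, increase = 42.7),
    class_sizes = blind_sizes
  )
}

test_that("confusion matrices tabulate and conserve cases", {
  cm <- confusion_matrix(c("decrease", "no_effect", "increase"),
                         c("decrease", "no_effect", "increase"))
  expect_equal(unname(diag(cm$z)), c(1, 1, 1))
  expect_equal(sum(cm$z), 3)

  cm2 <- confusion_matrix(rep(solubility_classes(), 2),
                          rep("decrease", 6))
  expect_true(all(cm2$z[, c("no_effect", "increase")] == 0))
  expect_equal(sum(cm2$z), 6)
  expect_error(confusion_matrix("decrease", "bogus"), "unknown class")
})

test_that("normalization rescales rows to the reference class size", {
  cm <- blind_34()
  norm <- normalize_confusion(cm)
  # every raw/normalized TP pair of the printed report reproduces
  expect_equal(round(norm$z["increase", "increase"], 1), 38.1)
  expect_equal(round(norm$z["decrease", "decrease"], 1), 190.0)
  expect_equal(norm$z["no_effect", "no_effect"], 159)   # reference row fixed
  expect_equal(unname(rowSums(norm$z)), rep(237, 3))

  # balanced classes: normalization is the identity
  bal <- confusion_matrix(rep(solubility_classes(), each = 2),
                          rep(solubility_classes(), each = 2))
  expect_equal(normalize_confusion(bal)$z, bal$z)
})

test_that("per-class one-vs-rest measures match the printed blind-test report", {
  m <- per_class_measures(blind_34())
  dec <- m[m$class == "decrease", ]
  expect_equal(dec$tp, 271)
  expect_equal(dec$fp, 66)
  expect_equal(dec$fn, 67)
  expect_equal(dec$tn, 258)
  expect_equal(round(dec$ppv, 3), 0.804)
  expect_equal(round(dec$sensitivity, 3), 0.802)
  expect_equal(round(dec$npv, 3), 0.794)
  expect_equal(round(dec$specificity, 3), 0.796)

  # perfect classifier: all four measures are 1 for every class
  perf <- confusion_matrix(rep(solubility_classes(), each = 3),
                           rep(solubility_classes(), each = 3))
  pm <- per_class_measures(perf)
  expect_true(all(pm$ppv == 1 & pm$npv == 1 &
                  pm$sensitivity == 1 & pm$specificity == 1))
})

test_that("one-vs-rest sensitivity matches an earlier tool's printed report", {
  # a predictor with raw TP 89 of 338 decreasing cases
  expect_equal(round(89 / (89 + 249), 3), 0.263)
  z <- matrix(c(89, 110, 139, 48, 108, 81, 13, 35, 39),
              nrow = 3, byrow = TRUE)
  cm <- solvar:::new_confusion(z, solubility_classes())
  m <- per_class_measures(cm)
  expect_equal(round(m$sensitivity[m$class == "decrease"], 3), 0.263)
})

test_that("undefined ratios surface as NaN, never as zero", {
  # nobody predicted (or was) no_effect in one column/row
  z <- matrix(c(5, 0, 1, 3, 0, 2, 1, 0, 4), nrow = 3, byrow = TRUE)
  cm <- solvar:::new_confusion(z, solubility_classes())
  m <- per_class_measures(cm)
  expect_true(is.nan(m$ppv[m$class == "no_effect"]))
  expect_false(isTRUE(m$ppv[m$class == "no_effect"] == 0))
})

test_that("CPR is the diagonal fraction; random assignment sits near 1/3", {
  cm <- blind_34()
  expect_equal(round(cpr(cm), 3), 0.671)
  expect_equal(round(cpr(normalize_confusion(cm)), 3), 0.545)

  perf <- confusion_matrix(solubility_classes(), solubility_classes())
  expect_equal(cpr(perf), 1.0)

  set.seed(3)
  truth <- sample(solubility_classes(), 30000, replace = TRUE)
  guess <- sample(solubility_classes(), 30000, replace = TRUE)
  expect_equal(cpr(confusion_matrix(truth, guess)), 1 / 3, tolerance = 0.02)
})

test_that("GC2 spans [0, 1] with closed-form endpoints", {
  perf <- confusion_matrix(rep(solubility_classes(), each = 5),
                           rep(solubility_classes(), each = 5))
  expect_equal(gc2(perf), 1.0)

  indep <- solvar:::new_confusion(outer(c(6, 3, 1), c(5, 4, 1)),
                                  solubility_classes())
  expect_equal(gc2(indep), 0.0)

  expect_equal(round(gc2(blind_34()), 3), 0.181)
})

test_that("GC2 equals chi-square over N(K-1) against the stats oracle (property)", {
  set.seed(42)
  for (i in 1:200) {
    z <- matrix(rpois(9, lambda = sample(3:40, 1)) + 1, nrow = 3)
    cm <- solvar:::new_confusion(z, solubility_classes())
    oracle <- suppressWarnings(
      chisq.test(z, correct = FALSE)$statistic) / (sum(z) * 2)
    expect_equal(gc2(cm), unname(oracle), tolerance = 1e-12)
    expect_gte(gc2(cm), 0)
    expect_lte(gc2(cm), 1)
    expect_gte(cpr(cm), 0)
    expect_lte(cpr(cm), 1)
  }
})

test_that("normalized metrics are invariant to the reference class", {
  cm <- blind_34()
  evals <- lapply(solubility_classes(), function(ref) {
    norm <- normalize_confusion(cm, reference = ref)
    list(m = per_class_measures(norm), cpr = cpr(norm), gc2 = gc2(norm))
  })
  for (e in evals[-1]) {
    expect_equal(e$m$ppv, evals[[1]]$m$ppv)
    expect_equal(e$m$npv, evals[[1]]$m$npv)
    expect_equal(e$m$sensitivity, evals[[1]]$m$sensitivity)
    expect_equal(e$m$specificity, evals[[1]]$m$specificity)
    expect_equal(e$cpr, evals[[1]]$cpr)
    expect_equal(e$gc2, evals[[1]]$gc2)
  }
  # sensitivity (a within-row ratio) is unchanged by normalization itself;
  # specificity pools reweighted complement rows and shifts as printed
  raw_m <- per_class_measures(cm)
  expect_equal(evals[[1]]$m$sensitivity, raw_m$sensitivity)
  norm_m <- per_class_measures(normalize_confusion(cm))
  expect_equal(round(norm_m$specificity[norm_m$class == "decrease"], 3), 0.777)
  expect_equal(round(norm_m$tn[norm_m$class == "decrease"], 1), 368.3)
})

test_that("reconstruction inverts its own marginals and rejects corrupt ones", {
  set.seed(5)
  for (i in 1:10) {
    # distinct row sums: equal class sizes give equal weights, under which
    # the off-diagonal system is singular (and errors, by design)
    repeat {
      z <- matrix(rpois(9, 30) + 1, nrow = 3,
                  dimnames = list(solubility_classes(),
                                  solubility_classes()))
      if (!anyDuplicated(rowSums(z))) break
    }
    cm <- solvar:::new_confusion(z, solubility_classes())
    sizes <- rowSums(z)
    w <- class_weights(sizes)
    tp <- diag(z)
    fp_raw <- colSums(z) - tp
    fp_norm <- colSums(z * w) - tp * w
    names(tp) <- names(fp_raw) <- names(fp_norm) <- solubility_classes()
    back <- reconstruct_confusion(tp, fp_raw, fp_norm, sizes)
    expect_equal(back$z, cm$z)
  }

  expect_error(
    reconstruct_confusion(
      tp = c(decrease = 271, no_effect = 159, increase = 14),
      fp_raw = c(decrease = 66, no_effect = 106, increase = 46),
      fp_norm = c(decrease = 130.0, no_effect = 175.5, increase = 42.7),
      class_sizes = blind_sizes),
    "inconsistent")
})

test_that("evaluation wrapper and report writer stay self-consistent", {
  set.seed(8)
  truth <- sample(solubility_classes(), 400, replace = TRUE,
                  prob = c(0.5, 0.34, 0.16))
  est <- ifelse(runif(400) < 0.6, truth,
                sample(solubility_classes(), 400, replace = TRUE))
  ev <- evaluate_predictions(truth, est)
  expect_equal(ev$cpr_raw, cpr(ev$raw))
  expect_equal(ev$cpr_norm, cpr(ev$normalized))
  expect_equal(nrow(ev$measures), 6)

  path <- withr::local_tempfile(fileext = ".tsv")
  rep_tbl <- write_metrics_report(ev, path, header = "test report")
  lines <- readLines(path)
  expect_true(startsWith(lines[1], "# test report"))
  expect_equal(nrow(rep_tbl), 8 * 3 + 2)
  expect_true(file.exists(path))
})
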