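#' Fit the two-layer three-class solubility predictor
#'
#' Layer 1 is a binary decreasing / not-decreasing classifier trained on all
#' cases (increase and no_effect collapsed to not-decreasing). Layer 2 is a
#' binary increasing / no-effect classifier trained only on the non-decreasing
#' cases. At prediction time a case whose layer-1 score reaches the decision
#' threshold is called decrease and layer 2 is never consulted for it;
#' otherwise layer 2 decides between increase and no_effect. The two layers
#' are fitted independently, including any shared features.
#'
#' @param featurized A featurized tibble from [featurize()] including a
#'   `label` column with all three classes present.
#' @param layer1_features,layer2_features Feature names per layer; defaults
#'   are the shipped 20 + 20 sets (6 shared, 34 distinct).
#' @param params,seed Passed to [fit_gbt()].
#' @param threshold Decision threshold on each binary layer's positive-class
#'   score; a score exactly at the threshold goes to the positive class.
#' @return An object of class `solvar_two_layer`.
#' @export
fit_two_layer <- function(featurized,
                          layer1_features = feature_set_layer1(),
                          layer2_features = feature_set_layer2(),
                          params = gbt_params(), seed = 1L,
                          threshold = 0.5) {
  stopifnot("label" %in% names(featurized))
  lab <- featurized$label
  missing_class <- setdiff(solubility_classes(), lab)
  if (length(missing_class) > 0) {
    stop("class absent from training data: ",
         paste(missing_class, collapse = ", "), call. = FALSE)
  }
  x1 <- feature_matrix(featurized, layer1_features)
  y1 <- factor(ifelse(lab == "decrease", "decrease", "not_decrease"),
               levels = c("not_decrease", "decrease"))
  layer1 <- fit_gbt(x1, y1, params, seed)
  keep <- lab != "decrease"
  x2 <- feature_matrix(featurized[keep, , drop = FALSE], layer2_features)
  y2 <- factor(lab[keep], levels = c("no_effect", "increase"))
  layer2 <- fit_gbt(x2, y2, params, seed)
  structure(
    list(layer1 = layer1, layer2 = layer2, threshold = threshold,
         layer1_features = layer1_features,
         layer2_features = layer2_features, seed = seed),
    class = "solvar_two_layer"
  )
}

#' @export
print.solvar_two_layer <- function(x, ...) {
  shared <- intersect(x$layer1_features, x$layer2_features)
  cat("<solvar_two_layer> decreasing/not-decreasing then increasing/no-effect\n",
      "  features: ", length(x$layer1_features), " + ",
      length(x$layer2_features), " (", length(shared), " shared, ",
      length(union(x$layer1_features, x$layer2_features)), " distinct); ",
      "threshold ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Predict solubility effect classes from a fitted model
#'
#' @param object A `solvar_two_layer` model.
#' @param newdata Featurized tibble or feature matrix.
#' @param ... Unused.
#' @return A tibble with `.pred_class` (factor over the three classes),
#'   `.score_decrease` (layer-1 probability of decrease) and
#'   `.score_increase` (layer-2 probability of increase, reported for every
#'   case even when layer 1 decided).
#' @export
predict.solvar_two_layer <- function(object, newdata, ...) {
  s1 <- predict(object$layer1, newdata, type = "prob")[, "decrease"]
  s2 <- predict(object$layer2, newdata, type = "prob")[, "increase"]
  cls <- ifelse(s1 >= object$threshold, "decrease",
                ifelse(s2 >= object$threshold, "increase", "no_effect"))
  tibble::tibble(
    .pred_class = factor(cls, levels = solubility_classes()),
    .score_decrease = unname(s1),
    .score_increase = unname(s2)
  )
}

#' Fit the single-layer three-class predictor
#'
#' One multiclass gradient-boosted model over all three classes; the default
#' feature budget for this architecture is 30 features.
#'
#' @inheritParams fit_two_layer
#' @param features Feature names to use.
#' @return An object of class `solvar_single`.
#' @export
fit_single <- function(featurized, features, params = gbt_params(),
                       seed = 1L) {
  stopifnot("label" %in% names(featurized))
  x <- feature_matrix(featurized, features)
  y <- factor(featurized$label, levels = solubility_classes())
  structure(
    list(model = fit_gbt(x, y, params, seed), features = features,
         seed = seed),
    class = "solvar_single"
  )
}

#' @export
print.solvar_single <- function(x, ...) {
  cat("<solvar_single> three-class classifier, ", length(x$features),
      " features\n", sep = "")
  invisible(x)
}

#' @export
predict.solvar_single <- function(object, newdata, ...) {
  prob <- predict(object$model, newdata, type = "prob")
  cls <- colnames(prob)[max.col(prob, ties.method = "first")]
  tibble::tibble(
    .pred_class = factor(cls, levels = solubility_classes()),
    .score_decrease = unname(prob[, "decrease"]),
    .score_increase = unname(prob[, "increase"])
  )
}

#' @export
tidy.solvar_two_layer <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(feature_importance(x$layer1), layer = "decrease_vs_rest"),
    dplyr::mutate(feature_importance(x$layer2), layer = "increase_vs_no_effect")
  )[, c("layer", "feature", "gain")]
}

#' @export
glance.solvar_two_layer <- function(x, ...) {
  tibble::tibble(
    n_features = length(union(x$layer1_features, x$layer2_features)),
    n_shared = length(intersect(x$layer1_features, x$layer2_features)),
    threshold = x$threshold,
    nrounds = x$layer1$params$nrounds,
    seed = x$seed
  )
}

#' @export
tidy.solvar_single <- function(x, ...) {
  feature_importance(x$model)
}

#' Save or restore a fitted predictor bundle
#'
#' The bundle is a single RDS file holding the serialized boosters together
#' with feature names, threshold, hyperparameters and seed, so a restored
#' model reproduces predictions exactly.
#'
#' @param model A `solvar_two_layer` or `solvar_single` model.
#' @param path File path.
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the model.
#' @export
save_model <- function(model, path) {
  pack <- function(m) {
    m$booster <- xgboost::xgb.save.raw(m$booster)
    m
  }
  obj <- unclass(model)
  if (inherits(model, "solvar_two_layer")) {
    obj$layer1 <- pack(obj$layer1)
    obj$layer2 <- pack(obj$layer2)
  } else {
    obj$model <- pack(obj$model)
  }
  saveRDS(list(class = class(model), payload = obj, version = "1"), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  raw <- readRDS(path)
  unpack <- function(m) {
    m$booster <- xgboost::xgb.load.raw(m$booster)
    class(m) <- "solvar_gbt"
    m
  }
  obj <- raw$payload
  if ("solvar_two_layer" %in% raw$class) {
    obj$layer1 <- unpack(obj$layer1)
    obj$layer2 <- unpack(obj$layer2)
  } else {
    obj$model <- unpack(obj$model)
  }
  structure(obj, class = raw$class)
}
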