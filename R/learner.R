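#' Gradient-boosted tree hyperparameters
#'
#' Defaults follow the stock settings of the gradient-boosting backend
#' (xgboost): 100 boosting rounds, learning rate 0.1, depth-6 trees, no
#' row/column subsampling (which also makes fitting deterministic), and a
#' single thread so results are bit-for-bit reproducible.
#'
#' @param nrounds Number of boosting rounds.
#' @param eta Learning rate.
#' @param max_depth Maximum tree depth.
#' @param nthread Threads (keep 1 for reproducibility).
#' @param ... Further parameters passed to the backend.
#' @return A named list.
#' @export
gbt_params <- function(nrounds = 100, eta = 0.1, max_depth = 6,
                       nthread = 1, ...) {
  c(list(nrounds = nrounds, eta = eta, max_depth = max_depth,
         nthread = nthread), list(...))
}

#' Fit a gradient-boosted decision-tree classifier
#'
#' Binary when `y` has two levels (logistic objective, predicted score =
#' probability of the second level, the "positive" class), multiclass
#' (softprob) otherwise. Feature names are fixed at fit time; prediction
#' rejects data whose columns do not cover them.
#'
#' @param x Numeric matrix or featurized tibble (id columns are dropped).
#' @param y Factor (or character) of class labels; at least two classes, and
#'   at least two examples of each.
#' @param params See [gbt_params()].
#' @param seed Integer seed.
#' @return An object of class `solvar_gbt`.
#' @export
fit_gbt <- function(x, y, params = gbt_params(), seed = 1L) {
  if (is.data.frame(x)) x <- feature_matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("feature matrix contains missing values", call. = FALSE)
  if (anyDuplicated(colnames(x))) {
    stop("feature-name collision in training matrix", call. = FALSE)
  }
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) {
    stop("training labels contain a single class", call. = FALSE)
  }
  if (any(table(y) < 2)) {
    stop("need at least two examples per class", call. = FALSE)
  }
  nclass <- nlevels(y)
  obj <- if (nclass == 2) {
    list(objective = "binary:logistic")
  } else {
    list(objective = "multi:softprob", num_class = nclass)
  }
  xgb_par <- c(
    obj,
    list(eta = params$eta, max_depth = params$max_depth,
         nthread = params$nthread, seed = seed),
    params[setdiff(names(params), c("nrounds", "eta", "max_depth", "nthread"))]
  )
  dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
  set.seed(seed)
  booster <- xgboost::xgb.train(params = xgb_par, data = dtrain,
                                nrounds = params$nrounds, verbose = 0)
  structure(
    list(booster = booster, feature_names = colnames(x), levels = levels(y),
         params = params, seed = seed),
    class = "solvar_gbt"
  )
}

#' @export
print.solvar_gbt <- function(x, ...) {
  cat("<solvar_gbt> ", length(x$levels), "-class gradient-boosted trees, ",
      length(x$feature_names), " features, ", x$params$nrounds,
      " rounds (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

# internal: align prediction columns to the model's feature names
align_features <- function(model, newdata) {
  if (is.data.frame(newdata)) newdata <- feature_matrix(newdata)
  missing <- setdiff(model$feature_names, colnames(newdata))
  if (length(missing) > 0) {
    stop("prediction data lack model features: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  x <- newdata[, model$feature_names, drop = FALSE]
  storage.mode(x) <- "double"
  x
}

#' Predict from a fitted gradient-boosted classifier
#'
#' @param object A `solvar_gbt` model.
#' @param newdata Feature matrix or featurized tibble containing at least the
#'   model's features.
#' @param type `"class"` for hard labels, `"prob"` for a per-class
#'   probability matrix.
#' @param ... Unused.
#' @return Factor of classes, or a numeric matrix of probabilities with one
#'   column per class.
#' @export
predict.solvar_gbt <- function(object, newdata,
                               type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- align_features(object, newdata)
  p <- predict(object$booster, xgboost::xgb.DMatrix(x))
  k <- length(object$levels)
  prob <- if (is.matrix(p)) p else if (k == 2) cbind(1 - p, p) else {
    matrix(p, ncol = k, byrow = TRUE)
  }
  colnames(prob) <- object$levels
  if (type == "prob") return(prob)
  factor(object$levels[max.col(prob, ties.method = "first")],
         levels = object$levels)
}

#' Per-feature importance of a fitted model
#'
#' Gain-based importance. Features that are never used in a split are
#' reported with importance 0 rather than dropped, so the ranking is always a
#' permutation of the model's feature space.
#'
#' @param model A `solvar_gbt` model.
#' @return A tibble (`feature`, `gain`) sorted by decreasing gain; ties keep
#'   the model's column order.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "solvar_gbt"))
  # degenerate boosters (e.g. a single feature or no usable split) can make
  # the backend's importance query fail; treat that as all-zero importance
  imp <- tryCatch(xgboost::xgb.importance(model = model$booster),
                  error = function(e) NULL)
  gain <- stats::setNames(rep(0, length(model$feature_names)),
                          model$feature_names)
  if (!is.null(imp) && nrow(imp) > 0) {
    gain[imp$Feature] <- imp$Gain
  }
  tibble::tibble(feature = names(gain), gain = unname(gain)) |>
    dplyr::arrange(dplyr::desc(gain))
}
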