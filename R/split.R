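#' Model specifications for validation runs
#'
#' A model specification captures architecture, feature sets and
#' hyperparameters so cross-validation and blind tests can refit the model
#' from scratch in every fold.
#'
#' @param layer1_features,layer2_features Feature names per layer (two-layer
#'   architecture).
#' @param params,threshold See [fit_two_layer()].
#' @return An object of class `solvar_spec`.
#' @export
two_layer_spec <- function(layer1_features = feature_set_layer1(),
                           layer2_features = feature_set_layer2(),
                           params = gbt_params(), threshold = 0.5) {
  structure(list(arch = "two_layer", layer1_features = layer1_features,
                 layer2_features = layer2_features, params = params,
                 threshold = threshold),
            class = "solvar_spec")
}

#' @rdname two_layer_spec
#' @param features Feature names (single-layer architecture).
#' @export
single_spec <- function(features, params = gbt_params()) {
  structure(list(arch = "single", features = features, params = params),
            class = "solvar_spec")
}

fit_spec <- function(featurized, spec, seed) {
  if (spec$arch == "two_layer") {
    fit_two_layer(featurized, spec$layer1_features, spec$layer2_features,
                  spec$params, seed, spec$threshold)
  } else {
    fit_single(featurized, spec$features, spec$params, seed)
  }
}

spec_features <- function(spec) {
  if (spec$arch == "two_layer") {
    union(spec$layer1_features, spec$layer2_features)
  } else {
    spec$features
  }
}

# internal: grouping key that must never span a partition boundary
group_key <- function(variants) {
  paste(variants$protein_id, variants$position, sep = "@")
}

#' Position-grouped train/test split
#'
#' All substitutions at one (protein, position) site are kept on the same
#' side of the split, so a model is never tested on a site it has seen in
#' training. Groups are shuffled under the seed and assigned to the test side
#' until the requested fraction is reached.
#'
#' @param dataset A labeled [solvar_dataset].
#' @param test_fraction Target fraction of variants on the test side.
#' @param seed Integer seed.
#' @return A list with elements `train` and `test`, both `solvar_dataset`s.
#' @export
grouped_split <- function(dataset, test_fraction = 0.1, seed = 1L) {
  stopifnot(inherits(dataset, "solvar_dataset"),
            test_fraction > 0, test_fraction < 1)
  v <- dataset$variants
  if (nrow(v) == 0) stop("empty dataset", call. = FALSE)
  key <- group_key(v)
  sizes <- table(key)
  target <- test_fraction * nrow(v)
  if (max(sizes) > max(target, nrow(v) - target)) {
    stop("a single (protein, position) group exceeds both requested ",
         "partition sides", call. = FALSE)
  }
  if (max(sizes) > target) {
    stop("a single (protein, position) group (", max(sizes),
         " variants) exceeds the requested test side (", round(target, 1),
         " variants)", call. = FALSE)
  }
  set.seed(seed)
  ord <- sample(names(sizes))
  cum <- cumsum(as.numeric(sizes[ord]))
  n_test_groups <- which(cum >= target)[1]
  test_keys <- ord[seq_len(n_test_groups)]
  idx_test <- which(key %in% test_keys)
  list(train = subset_dataset(dataset, setdiff(seq_len(nrow(v)), idx_test)),
       test = subset_dataset(dataset, idx_test))
}

#' Assign position-atomic, class-stratified cross-validation folds
#'
#' Groups of substitutions sharing a (protein, position) site are the unit of
#' assignment; within strata defined by each group's majority label, groups
#' are shuffled and dealt round-robin to folds, which balances classes as far
#' as group atomicity permits.
#'
#' @param dataset A labeled [solvar_dataset].
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return An integer vector of fold ids (1..k), one per variant row.
#' @export
make_folds <- function(dataset, k = 10L, seed = 1L) {
  stopifnot(k >= 2)
  v <- dataset$variants
  key <- group_key(v)
  if (k > length(unique(key))) {
    stop("k (", k, ") exceeds the number of (protein, position) groups (",
         length(unique(key)), ")", call. = FALSE)
  }
  set.seed(seed)
  # shuffle groups, block them by stratum, then deal folds in one global
  # cycle: each stratum is spread contiguously across the fold cycle, which
  # balances classes and reduces to leave-one-out at k = number of groups
  groups <- tibble::tibble(key = key, label = v$label) |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(
      stratum = names(sort(table(.data$label), decreasing = TRUE))[1],
      .groups = "drop"
    ) |>
    dplyr::slice_sample(prop = 1) |>
    dplyr::arrange(.data$stratum) |>
    dplyr::mutate(fold = (dplyr::row_number() - 1L) %% k + 1L)
  fold_of <- stats::setNames(groups$fold, groups$key)
  unname(fold_of[key])
}

#' Run position-grouped k-fold cross-validation
#'
#' Features are computed once; in each fold the model is refitted from
#' scratch on the training folds and applied to the held-out fold.
#' Out-of-fold predictions are pooled into a single confusion matrix (N =
#' dataset size) and also summarized as per-fold means of the one-vs-rest
#' counts, in raw and normalized form.
#'
#' @param dataset A labeled [solvar_dataset] with all three classes.
#' @param spec A model specification ([two_layer_spec()] or [single_spec()]).
#' @param aaindex AAindex table used for featurization.
#' @param k Number of folds.
#' @param seed Integer seed (fold assignment and every refit).
#' @param reference Normalization reference class.
#' @return An object of class `solvar_cv`: list with `eval` (a
#'   [evaluate_predictions()] result on the pooled predictions), `fold_means`
#'   (tibble of per-fold mean counts and measures), `folds` (fold id per
#'   variant), `predictions` (tibble).
#' @export
run_cv <- function(dataset, spec, aaindex = default_aaindex(), k = 10L,
                   seed = 1L, reference = "no_effect") {
  stopifnot(inherits(dataset, "solvar_dataset"),
            "label" %in% names(dataset$variants))
  folds <- make_folds(dataset, k, seed)
  featurized <- featurize(dataset, aaindex)
  lab <- dataset$variants$label
  for (f in seq_len(k)) {
    present <- unique(lab[folds != f])
    if (!setequal(present, solubility_classes())) {
      stop("training folds for fold ", f, " are missing a class; ",
           "use fewer folds or more data", call. = FALSE)
    }
  }
  preds <- vector("list", k)
  fold_rows <- vector("list", k)
  for (f in seq_len(k)) {
    model <- fit_spec(featurized[folds != f, , drop = FALSE], spec, seed)
    p <- predict(model, featurized[folds == f, , drop = FALSE])
    preds[[f]] <- dplyr::bind_cols(
      dataset$variants[folds == f, c("protein_id", "variant", "label")],
      p, tibble::tibble(fold = f)
    )
    raw_cm <- confusion_matrix(lab[folds == f], as.character(p$.pred_class))
    rows <- dplyr::mutate(per_class_measures(raw_cm), normalized = FALSE)
    # normalized per-fold counts need every class present in the fold
    if (all(rowSums(raw_cm$z) > 0)) {
      norm_cm <- normalize_confusion(raw_cm, reference)
      rows <- dplyr::bind_rows(
        rows, dplyr::mutate(per_class_measures(norm_cm), normalized = TRUE))
    }
    fold_rows[[f]] <- dplyr::mutate(rows, fold = f)
  }
  predictions <- dplyr::bind_rows(preds)
  eval <- evaluate_predictions(predictions$label, predictions$.pred_class,
                               reference = reference)
  fold_means <- dplyr::bind_rows(fold_rows) |>
    dplyr::group_by(.data$class, .data$normalized) |>
    dplyr::summarise(dplyr::across(
      c("tp", "tn", "fp", "fn", "ppv", "npv", "sensitivity", "specificity"),
      mean), .groups = "drop")
  structure(
    list(eval = eval, fold_means = fold_means, folds = folds,
         predictions = predictions, k = k, seed = seed),
    class = "solvar_cv"
  )
}

#' @export
print.solvar_cv <- function(x, ...) {
  cat("<solvar_cv> ", x$k, "-fold position-grouped cross-validation\n",
      sep = "")
  print(x$eval)
  invisible(x)
}

#' Train once, evaluate once on a held-out blind set
#'
#' Refuses to run if any (protein, position) group appears on both sides
#' (leakage).
#'
#' @param train,test Labeled [solvar_dataset]s forming a group-atomic
#'   partition.
#' @inheritParams run_cv
#' @return A list with `model`, `eval` and `predictions`.
#' @export
run_blind_test <- function(train, test, spec, aaindex = default_aaindex(),
                           seed = 1L, reference = "no_effect") {
  shared <- intersect(group_key(train$variants), group_key(test$variants))
  if (length(shared) > 0) {
    stop("leakage: (protein, position) group(s) shared between train and ",
         "test: ", paste(utils::head(shared, 3), collapse = ", "),
         call. = FALSE)
  }
  model <- fit_spec(featurize(train, aaindex), spec, seed)
  feats_test <- featurize(test, aaindex)
  p <- predict(model, feats_test)
  list(
    model = model,
    eval = evaluate_predictions(test$variants$label, p$.pred_class,
                                reference = reference),
    predictions = dplyr::bind_cols(
      test$variants[, c("protein_id", "variant", "label")], p)
  )
}

#' Randomly downsample one class of a dataset
#'
#' Utility for rebalancing heavily skewed datasets by random exclusion of
#' cases from the majority class. Provided as a documented flag-level
#' utility; not part of the default pipeline.
#'
#' @param dataset A labeled [solvar_dataset].
#' @param label Class to downsample.
#' @param n_keep Number of cases of that class to retain.
#' @param seed Integer seed.
#' @return A [solvar_dataset].
#' @export
downsample_class <- function(dataset, label = "decrease", n_keep, seed = 1L) {
  v <- dataset$variants
  idx <- which(v$label == label)
  stopifnot(n_keep <= length(idx))
  set.seed(seed)
  drop <- sample(idx, length(idx) - n_keep)
  subset_dataset(dataset, setdiff(seq_len(nrow(v)), drop))
}
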