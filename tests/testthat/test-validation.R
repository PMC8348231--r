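test_that("grouped splits never separate substitutions at one position", {
  # 19 substitutions at a single site all land on the same side
  seqn <- strrep("L", 40)
  muts <- setdiff(canonical_residues(), "L")
  ds <- solvar_dataset(
    tibble::tibble(protein_id = "p1", sequence = seqn),
    tibble::tibble(protein_id = "p1",
                   variant = c(paste0("L20", muts),
                               paste0("L", 1:19, "A")),
                   label = rep(solubility_classes(),
                               length.out = 19 + 19))
  )
  sp <- grouped_split(ds, test_fraction = 0.5, seed = 1)
  side_of_20 <- c(
    train = sum(sp$train$variants$position == 20),
    test = sum(sp$test$variants$position == 20)
  )
  expect_true(any(side_of_20 == 19) && any(side_of_20 == 0))

  # partition is exact and disjoint
  expect_equal(nrow(sp$train$variants) + nrow(sp$test$variants), 38)
  expect_length(intersect(
    paste(sp$train$variants$protein_id, sp$train$variants$position),
    paste(sp$test$variants$protein_id, sp$test$variants$position)), 0)
})

test_that("splits are seed-deterministic and seed-sensitive", {
  ds <- generate_fixture(fixture_spec(n_variants = 300, seed = 4))
  a <- grouped_split(ds, 0.3, seed = 1)
  b <- grouped_split(ds, 0.3, seed = 1)
  c <- grouped_split(ds, 0.3, seed = 2)
  expect_identical(a$test$variants, b$test$variants)
  expect_false(identical(a$test$variants, c$test$variants))
})

test_that("degenerate split requests error", {
  p <- tiny_proteins()
  empty <- structure(list(proteins = p, variants = tibble::tibble(
    protein_id = character(), variant = character(), wt = character(),
    position = integer(), mut = character())), class = "solvar_dataset")
  expect_error(grouped_split(empty, 0.3), "empty")

  seqn <- strrep("L", 30)
  big_group <- solvar_dataset(
    tibble::tibble(protein_id = "p1", sequence = seqn),
    tibble::tibble(protein_id = "p1",
                   variant = paste0("L15", setdiff(canonical_residues(), "L")))
  )
  expect_error(grouped_split(big_group, test_fraction = 0.2), "exceeds")
})

test_that("fold assignment is position-atomic across random fixtures (property)", {
  for (seed in 1:3) {
    ds <- generate_fixture(fixture_spec(n_variants = 400, seed = seed))
    folds <- make_folds(ds, k = 5, seed = seed)
    expect_length(folds, nrow(ds$variants))
    key <- paste(ds$variants$protein_id, ds$variants$position)
    expect_true(all(tapply(folds, key, function(f) length(unique(f))) == 1))
    expect_setequal(unique(folds), 1:5)
  }
})

test_that("cross-validation pools out-of-fold predictions over the whole set", {
  ds <- generate_fixture(fixture_spec(n_variants = 450, signal = 1, seed = 6))
  feats_all <- setdiff(names(featurize(ds)),
                       c("protein_id", "variant", "label"))
  spec <- two_layer_spec(feats_all, feats_all, fast_params())
  cv <- run_cv(ds, spec, k = 4, seed = 2)
  expect_equal(sum(cv$eval$raw$z), nrow(ds$variants))
  expect_equal(nrow(cv$predictions), nrow(ds$variants))

  # per-fold mean TP times k equals the pooled diagonal (bookkeeping identity)
  raw_means <- cv$fold_means[!cv$fold_means$normalized, ]
  pooled_diag <- diag(cv$eval$raw$z)
  expect_equal(raw_means$tp[match(solubility_classes(), raw_means$class)] * 4,
               unname(pooled_diag))

  # planted-signal data are learned well above the 1/3 random baseline
  expect_gt(cpr(cv$eval$normalized), 1 / 3)
})

test_that("cross-validation reruns identically under the same seed", {
  ds <- generate_fixture(fixture_spec(n_variants = 240, signal = 1, seed = 7))
  feats_all <- setdiff(names(featurize(ds)),
                       c("protein_id", "variant", "label"))
  spec <- two_layer_spec(feats_all, feats_all, fast_params(15))
  cv1 <- run_cv(ds, spec, k = 3, seed = 5)
  cv2 <- run_cv(ds, spec, k = 3, seed = 5)
  expect_identical(cv1$predictions, cv2$predictions)
})

test_that("singleton groups at k = N reduce to leave-one-out", {
  # one variant per position so every group is a singleton
  set.seed(11)
  seqn <- paste(sample(canonical_residues(), 60, replace = TRUE),
                collapse = "")
  pos <- seq(1, 45, by = 3)
  wt <- substring(seqn, pos, pos)
  mut <- vapply(wt, function(w) sample(setdiff(canonical_residues(), w), 1),
                character(1))
  ds <- solvar_dataset(
    tibble::tibble(protein_id = "p1", sequence = seqn),
    tibble::tibble(protein_id = "p1", variant = paste0(wt, pos, mut),
                   label = rep(solubility_classes(), length.out = length(pos)))
  )
  n <- nrow(ds$variants)
  folds <- make_folds(ds, k = n, seed = 1)
  expect_setequal(folds, 1:n)           # each fold holds exactly one variant
  cv <- run_cv(ds, two_layer_spec(
    setdiff(names(featurize(ds)), c("protein_id", "variant", "label")),
    setdiff(names(featurize(ds)), c("protein_id", "variant", "label")),
    fast_params(5)), k = n, seed = 1)
  expect_equal(nrow(cv$predictions), n)
  expect_equal(sort(unique(cv$predictions$fold)), 1:n)
})

test_that("blind tests refuse leaking (protein, position) groups", {
  ds <- generate_fixture(fixture_spec(n_variants = 300, signal = 1, seed = 9))
  sp <- grouped_split(ds, 0.25, seed = 3)
  leaked <- sp$test
  leaked$variants <- dplyr::bind_rows(leaked$variants,
                                      sp$train$variants[1, ])
  leaked$proteins <- ds$proteins
  expect_error(
    run_blind_test(sp$train, leaked, two_layer_spec(params = fast_params())),
    "leakage")
})

test_that("blind-test evaluation is deterministic and reports both scales", {
  ds <- generate_fixture(fixture_spec(n_variants = 400, signal = 1, seed = 10))
  sp <- grouped_split(ds, 0.25, seed = 3)
  feats_all <- setdiff(names(featurize(ds)),
                       c("protein_id", "variant", "label"))
  spec <- two_layer_spec(feats_all, feats_all, fast_params())
  r1 <- run_blind_test(sp$train, sp$test, spec, seed = 4)
  r2 <- run_blind_test(sp$train, sp$test, spec, seed = 4)
  expect_identical(r1$predictions, r2$predictions)
  expect_false(r1$eval$normalized$normalized == FALSE)
  expect_equal(sum(r1$eval$raw$z), nrow(sp$test$variants))
})

test_that("class downsampling keeps the requested count", {
  ds <- generate_fixture(fixture_spec(n_variants = 300, seed = 12))
  n_dec <- class_counts(ds)["decrease"]
  down <- downsample_class(ds, "decrease", n_keep = 20, seed = 1)
  expect_equal(unname(class_counts(down)["decrease"]), 20L)
  expect_gt(n_dec, 20)
})
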