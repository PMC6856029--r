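test_that("train/test evaluation keeps test rows out of fitting", {
  ds <- generate_dataset(synthetic_spec(n_samples = 80, n_features = 10,
                                        effect_size = 8,
                                        feature_noise_sd = 0.01, seed = 2))
  sp <- stratified_split(ds, seed = 2)
  tt <- evaluate_train_test(model_spec("PLS-DA", list(n_latent = 1)), ds, sp)
  expect_equal(tt$auc_train, 1)            # constructed separability
  expect_s3_class(tt$roc_test, "roc_curve")
  # preprocessing statistics must be identical to a train-only fit
  prep_alone <- fit_preprocessing(feature_matrix(ds, sp$train_ids))
  expect_equal(tt$preprocessing$centre, prep_alone$centre)
  expect_equal(tt$preprocessing$scale, prep_alone$scale)
})

test_that("null data gives chance-level test AUC", {
  aucs <- vapply(1:4, function(s) {
    ds <- generate_dataset(synthetic_spec(n_samples = 120, n_features = 10,
                                          effect_size = 0, seed = 600 + s))
    sp <- stratified_split(ds, seed = s)
    evaluate_train_test(model_spec("PLS-DA", list(n_latent = 2), seed = s),
                        ds, sp)$auc_test
  }, numeric(1))
  n1 <- 20; n0 <- 20  # test set is ~40 samples, balanced
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se / sqrt(4) + 0.05)
})

test_that("flipping the positive label mirrors scores and fixed-score AUC", {
  ds <- generate_dataset(synthetic_spec(n_samples = 60, n_features = 8,
                                        seed = 5))
  ds_flip <- tidy_dataset(ds$data_table, ds$peak_table,
                          positive_label = "0")
  sp <- stratified_split(ds, seed = 3)
  spec <- model_spec("PLS-DA", list(n_latent = 2))
  tt <- evaluate_train_test(spec, ds, sp)
  tt_flip <- evaluate_train_test(spec, ds_flip, sp)
  x_test <- apply_preprocessing(tt$preprocessing,
                                feature_matrix(ds, sp$test_ids))
  s <- predict_scores(tt$fitted, x_test)
  s_flip <- predict_scores(tt_flip$fitted, x_test)
  # a least-squares fit to 1 - y mirrors the linear scores exactly,
  # so refitting leaves the AUC unchanged ...
  expect_equal(s_flip, 1 - s, tolerance = 1e-10)
  expect_equal(tt$auc_test, tt_flip$auc_test, tolerance = 1e-10)
  # ... while flipping labels against fixed scores mirrors the AUC
  y_test <- outcome_vector(ds, sp$test_ids)
  expect_equal(auc(1 - y_test, s), 1 - tt$auc_test, tolerance = 1e-12)
})

test_that("a single-class test set is rejected", {
  ds <- generate_dataset(synthetic_spec(n_samples = 30, n_features = 5,
                                        seed = 1))
  y <- outcome_vector(ds)
  zeros <- names(y)[y == 0]
  ones <- names(y)[y == 1]
  split <- structure(list(train_ids = c(ones, zeros[1:10]),
                          test_ids = zeros[-(1:10)],
                          seed = 1L),
                     class = "split_indices")
  expect_error(evaluate_train_test(model_spec("PLS-DA", list(n_latent = 1)),
                                   ds, split),
               class = "metabench_evaluation_error")
})

test_that("bootstrap produces n_boot disjoint IB/OOB curve records", {
  ds <- generate_dataset(synthetic_spec(n_samples = 50, n_features = 8,
                                        seed = 8))
  spec <- model_spec("PLS-DA", list(n_latent = 2))
  b <- bootstrap_evaluate(spec, ds, n_boot = 25, seed = 4)
  expect_equal(nrow(b$resamples), 25)
  expect_equal(dim(b$ib_curves), c(25, 101))
  expect_equal(dim(b$oob_curves), c(25, 101))
  for (i in seq_len(25)) {
    expect_length(intersect(b$resamples$ib_ids[[i]],
                            b$resamples$oob_ids[[i]]), 0)
    expect_setequal(union(b$resamples$ib_ids[[i]],
                          b$resamples$oob_ids[[i]]), sample_ids(ds))
  }
  # unique in-bag fraction concentrates near 1 - 1/e
  ib_frac <- mean(lengths(b$resamples$ib_ids)) / n_samples(ds)
  expect_gt(ib_frac, 0.55)
  expect_lt(ib_frac, 0.72)
  expect_true(all(b$bands$ib_lower <= b$bands$ib_upper + 1e-12))
  expect_true(all(b$bands$oob_lower <= b$bands$oob_upper + 1e-12))
  expect_true(all(b$resamples$auc_ib >= 0 & b$resamples$auc_ib <= 1))
})

test_that("bootstrap sub-seeding is reproducible and redraws are logged", {
  ds <- generate_dataset(synthetic_spec(n_samples = 40, n_features = 6,
                                        class_balance = 0.15, seed = 10))
  spec <- model_spec("PLS-DA", list(n_latent = 1))
  b1 <- bootstrap_evaluate(spec, ds, n_boot = 10, seed = 2)
  b2 <- bootstrap_evaluate(spec, ds, n_boot = 10, seed = 2)
  expect_equal(b1$resamples$auc_oob, b2$resamples$auc_oob)
  expect_equal(b1$bands, b2$bands)
  expect_gte(b1$n_redraws, 0)
  for (i in 1:10) {
    y_oob <- outcome_vector(ds, b1$resamples$oob_ids[[i]])
    expect_setequal(unique(y_oob), c(0, 1))
  }
})

test_that("the OOB band contains its own median curve", {
  ds <- generate_dataset(synthetic_spec(n_samples = 60, n_features = 8,
                                        seed = 6))
  b <- bootstrap_evaluate(model_spec("PLS-DA", list(n_latent = 2)), ds,
                          n_boot = 20, seed = 3)
  med <- tibble::tibble(fpr = b$bands$fpr, tpr = b$bands$oob_median,
                        threshold = NA_real_)
  class(med) <- c("roc_curve", class(med))
  expect_true(roc_within_oob_band(b, med))
})

test_that("run summaries aggregate cells and pairwise differences", {
  fake_tt <- function(a_tr, a_te) {
    structure(list(auc_train = a_tr, auc_test = a_te,
                   spec = list(family = "x")),
              class = "train_test_evaluation")
  }
  evals <- tibble::tibble(
    dataset_id = rep(c("d1", "d2"), each = 2),
    family = rep(c("A", "B"), 2),
    train_test = list(fake_tt(0.95, 0.9), fake_tt(0.9, 0.85),
                      fake_tt(0.85, 0.8), fake_tt(0.9, 0.85))
  )
  s <- summarise_runs(evals)
  expect_equal(nrow(s), 4)
  expect_equal(s$auc_test, c(0.9, 0.85, 0.8, 0.85))
  pw <- pairwise_auc_differences(s)
  # A - B: ((0.9 - 0.85) + (0.8 - 0.85)) / 2 = 0
  expect_equal(pw$mean_diff[pw$family_a == "A" & pw$family_b == "B"], 0)
  # identical families -> zero difference
  evals2 <- evals
  evals2$train_test <- rep(list(fake_tt(0.9, 0.88)), 4)
  expect_equal(pairwise_auc_differences(summarise_runs(evals2))$mean_diff,
               c(0, 0))
  one <- summarise_runs(evals[evals$dataset_id == "d1", ])
  expect_equal(nrow(one), 2)
})

test_that("overtraining gap grows with model complexity on small wide data", {
  gap_for <- function(family) {
    mean(vapply(1:10, function(s) {
      ds <- generate_dataset(synthetic_spec(n_samples = 80,
                                            n_features = 200,
                                            seed = 400 + s))
      spec <- switch(family,
        "PLS-DA" = model_spec("PLS-DA", list(n_latent = 2), seed = s),
        "RF" = model_spec("RF", list(max_depth = 8,
                                     min_leaf_fraction = 0.02), seed = s),
        "ANN-SS" = model_spec("ANN-SS", list(n_neurons = 8,
                                             learning_rate = 0.3),
                              seed = s))
      b <- bootstrap_evaluate(spec, ds, n_boot = 20, seed = s)
      mean(b$resamples$auc_ib - b$resamples$auc_oob)
    }, numeric(1)))
  }
  gap_pls <- gap_for("PLS-DA")
  expect_gt(gap_for("RF"), gap_pls)
  expect_gt(gap_for("ANN-SS"), gap_pls)
})
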