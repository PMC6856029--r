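test_that("default grids expose the documented axes and orderings", {
  g <- default_hyper_grid("SVM-RBF")
  expect_named(g$axes, c("C", "gamma"))
  expect_equal(g$axes$C, 10^seq(-2, 4))
  expect_equal(g$axes$gamma, 10^seq(-5, 1))
  g2 <- default_hyper_grid("PLS-DA", max_rank = 7)
  expect_equal(g2$axes$n_latent, 1:7)
  g3 <- default_hyper_grid("RF")
  expect_equal(unname(g3$complexity["min_leaf_fraction"]), -1)
  expect_error(default_hyper_grid("PLS-DA", overrides = list(n_latent = 3)),
               class = "metabench_spec_error")
  expect_error(default_hyper_grid("PLS-DA", overrides = list(C = 1:3)),
               class = "metabench_spec_error")
})

test_that("pareto_front returns exactly the non-dominated points", {
  one <- pareto_front(data.frame(value = 0.4, gap = 0.1))
  expect_equal(nrow(one), 1)
  f <- pareto_front(data.frame(value = c(0.6, 0.5, 0.4),
                               gap = c(0.05, 0.01, 0.20)))
  expect_equal(f$value, c(0.5, 0.6))
  expect_equal(f$gap, c(0.01, 0.05))
  dup <- pareto_front(data.frame(value = c(0.5, 0.5, 0.6),
                                 gap = c(0.01, 0.01, 0.05)))
  expect_equal(nrow(dup), 2)
})

test_that("pareto_front matches an exhaustive dominance oracle", {
  set.seed(81)
  for (i in 1:200) {
    n <- sample(1:50, 1)
    value <- round(runif(n), 2)  # rounding forces ties/duplicates
    gap <- round(runif(n), 2)
    got <- pareto_front(data.frame(value = value, gap = gap))
    want <- brute_force_front(value, gap)
    want <- want[order(want$value), ]
    expect_equal(got$value, want$value)
    expect_equal(got$gap, want$gap)
  }
})

test_that("the knee rule picks the maximal-distance front point", {
  surf <- make_fake_surface(q2 = c(0.2, 0.5, 0.6),
                            gap = c(0.01, 0.02, 0.30))
  sel <- select_optimum(surf)
  expect_equal(sel$rule, "inflection")
  expect_equal(sel$chosen$q2, 0.5)
  k <- brute_force_knee(c(0.2, 0.5, 0.6), c(0.01, 0.02, 0.30))
  expect_equal(sel$chosen$q2, c(0.2, 0.5, 0.6)[k])
})

test_that("a collinear front falls back to the |R2-Q2| = 0.2 line", {
  surf <- make_fake_surface(q2 = c(0.2, 0.5, 0.8),
                            gap = c(0.00, 0.18, 0.36))
  sel <- select_optimum(surf)
  expect_equal(sel$rule, "fallback_0.2")
  expect_equal(sel$chosen$q2, 0.5)
  expect_equal(abs(sel$chosen$r2 - sel$chosen$q2), 0.18)
})

test_that("degenerate and tied selections resolve deterministically", {
  single <- make_fake_surface(q2 = 0.5, gap = 0.1)
  sel <- select_optimum(single)
  expect_equal(sel$rule, "fallback_0.2")
  expect_equal(sel$chosen$q2, 0.5)
  # two front points equidistant from the line: lower complexity wins
  tie <- make_fake_surface(q2 = c(0.4, 0.6), gap = c(0.15, 0.25))
  sel_tie <- select_optimum(tie)
  expect_equal(sel_tie$chosen$n_latent, 1)
})

test_that("selection is invariant to the order of grid points", {
  q2 <- c(0.1, 0.45, 0.52, 0.3, 0.6)
  gap <- c(0.02, 0.03, 0.10, 0.01, 0.35)
  s1 <- select_optimum(make_fake_surface(q2, gap))
  perm <- c(4, 1, 5, 3, 2)
  surf2 <- make_fake_surface(q2[perm], gap[perm])
  surf2$n_latent <- (1:5)[perm]
  s2 <- select_optimum(surf2)
  expect_equal(s1$chosen$q2, s2$chosen$q2)
  expect_equal(s1$chosen$n_latent, s2$chosen$n_latent)
  expect_equal(s1$rule, s2$rule)
})

test_that("MC-CV on a constant-score reference model is at chance", {
  ds <- generate_dataset(synthetic_spec(n_samples = 60, n_features = 8,
                                        seed = 3))
  prep <- fit_preprocessing(feature_matrix(ds))
  x <- apply_preprocessing(prep, feature_matrix(ds))
  y <- unname(outcome_vector(ds))
  surf <- mc_cv_evaluate("Dummy", default_hyper_grid("Dummy"), x, y,
                         repartitions = 3, seed = 2)
  expect_true(all(surf$q2 <= 1e-10))
  expect_equal(surf$auc_cv, rep(0.5, nrow(surf)))
  expect_equal(surf$auc_full, rep(0.5, nrow(surf)))
})

test_that("MC-CV surfaces are deterministic and carry per-repartition Q2", {
  ds <- generate_dataset(synthetic_spec(n_samples = 80, n_features = 10,
                                        seed = 5))
  prep <- fit_preprocessing(feature_matrix(ds))
  x <- apply_preprocessing(prep, feature_matrix(ds))
  y <- unname(outcome_vector(ds))
  g <- default_hyper_grid("PLS-DA", max_rank = 4)
  s1 <- mc_cv_evaluate("PLS-DA", g, x, y, repartitions = 4, seed = 9)
  s2 <- mc_cv_evaluate("PLS-DA", g, x, y, repartitions = 4, seed = 9)
  expect_equal(tibble::as_tibble(s1), tibble::as_tibble(s2))
  expect_equal(nrow(s1), 4)
  expect_true(all(lengths(s1$q2_reps) == 4))
  expect_equal(s1$q2, vapply(s1$q2_reps, mean, numeric(1)))
  expect_error(
    mc_cv_evaluate("PLS-DA", g, x[1:8, ], y[1:8], k = 5, seed = 1),
    class = "metabench_fold_error"
  )
})

test_that("Q2 peaks near the generating latent rank for PLS-DA", {
  ds <- generate_dataset(synthetic_spec(n_samples = 200, n_features = 30,
                                        latent_rank = 2, effect_size = 2,
                                        seed = 13))
  sp <- stratified_split(ds, seed = 13)
  prep <- fit_preprocessing(feature_matrix(ds, sp$train_ids))
  x <- apply_preprocessing(prep, feature_matrix(ds, sp$train_ids))
  y <- unname(outcome_vector(ds, sp$train_ids))
  surf <- mc_cv_evaluate("PLS-DA", default_hyper_grid("PLS-DA", max_rank = 6),
                         x, y, repartitions = 5, seed = 13)
  best <- surf$n_latent[which.max(surf$q2)]
  expect_gte(best, 1)
  expect_lte(best, 3)
  # averaged over repartitions, the full fit explains at least as much as CV
  expect_true(all(surf$r2 >= surf$q2))
})
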