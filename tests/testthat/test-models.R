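make_xy <- function(n = 80, m = 12, effect = 2, seed = 1) {
  ds <- generate_dataset(synthetic_spec(n_samples = n, n_features = m,
                                        effect_size = effect, seed = seed))
  prep <- fit_preprocessing(feature_matrix(ds))
  list(x = apply_preprocessing(prep, feature_matrix(ds)),
       y = unname(outcome_vector(ds)))
}

test_that("model specs validate family-specific hyperparameter sets", {
  expect_s3_class(model_spec("PLS-DA", list(n_latent = 2)), "model_spec")
  expect_error(model_spec("PLS-DA", list(k = 2)),
               class = "metabench_spec_error")
  expect_error(model_spec("SVM-RBF", list(C = 1)),
               class = "metabench_spec_error")
  expect_error(model_spec("SVM-RBF", list(C = -1, gamma = 1)),
               class = "metabench_spec_error")
  expect_error(model_spec("RF", list(max_depth = 0, min_leaf_fraction = 0.1)),
               class = "metabench_spec_error")
  expect_error(model_spec("RF", list(max_depth = 3, min_leaf_fraction = 0.6)),
               class = "metabench_spec_error")
  expect_error(model_spec("nope"), class = "metabench_spec_error")
  ann <- model_spec("ANN-SS", list(n_neurons = 3, learning_rate = 0.1))
  expect_equal(ann$fixed_settings$momentum, 0.5)
  expect_equal(ann$fixed_settings$decay, 0)
  expect_equal(ann$fixed_settings$epochs, 400L)
})

test_that("the RBF kernel follows the Gaussian convention", {
  x <- rbind(c(0, 0), c(1, 0))
  k <- rbf_kernel_matrix(x, x, gamma = 1)
  expect_equal(diag(k), c(1, 1))
  expect_equal(k[1, 2], exp(-1))
  expect_equal(k, t(k))
  expect_true(all(k > 0 & k <= 1))
  k0 <- rbf_kernel_matrix(x, x, gamma = 1e-10)
  expect_equal(as.numeric(k0), rep(1, 4), tolerance = 1e-8)
  expect_error(rbf_kernel_matrix(x, x, gamma = 0),
               class = "metabench_spec_error")
  expect_equal(dim(rbf_kernel_matrix(x, x[1, , drop = FALSE], 2)), c(2, 1))
})

test_that("PLS-DA and PCR reduce to an explicit linear form", {
  d <- make_xy()
  for (spec in list(model_spec("PLS-DA", list(n_latent = 3)),
                    model_spec("PCR", list(n_components = 3)))) {
    f <- fit_model(spec, d$x, d$y)
    b <- coef(f)
    manual <- b[1] + as.numeric(d$x %*% b[-1])
    expect_equal(predict_scores(f, d$x), manual, tolerance = 1e-10)
  }
})

test_that("PLS-DA at full rank equals least squares on X", {
  d <- make_xy(n = 30, m = 6)
  f <- fit_model(model_spec("PLS-DA", list(n_latent = 6)), d$x, d$y)
  ls <- qr.coef(qr(cbind(1, d$x)), d$y)
  expect_equal(unname(coef(f)), unname(ls), tolerance = 1e-8)
})

test_that("PCR equals multiple linear regression on the PCA scores", {
  d <- make_xy(n = 40, m = 10)
  k <- 4
  f <- fit_model(model_spec("PCR", list(n_components = k)), d$x, d$y)
  pca <- pca_decompose(d$x, k)
  oracle <- unname(cbind(1, pca$scores) %*%
                     qr.coef(qr(cbind(1, pca$scores)), d$y))
  expect_equal(predict_scores(f, d$x), as.numeric(oracle), tolerance = 1e-8)
})

test_that("PCLR is a maximum-likelihood logistic fit on the PCA scores", {
  d <- make_xy(n = 60, m = 8)
  k <- 3
  f <- fit_model(model_spec("PCLR", list(n_components = k)), d$x, d$y)
  s <- predict_scores(f, d$x)
  expect_true(all(s > 0 & s < 1))
  pca <- pca_decompose(d$x, k)
  g <- glm(d$y ~ pca$scores, family = binomial())
  expect_equal(s, unname(fitted(g)), tolerance = 1e-6)
})

test_that("SVM-Lin separates two well-separated clouds with correct sign", {
  set.seed(9)
  x <- rbind(matrix(rnorm(40, -3, 0.5), 20, 2),
             matrix(rnorm(40, 3, 0.5), 20, 2))
  colnames(x) <- c("M1", "M2")
  y <- rep(c(0, 1), each = 20)
  f <- fit_model(model_spec("SVM-Lin", list(C = 1)), x, y)
  s <- predict_scores(f, x)
  expect_true(all(s[y == 1] > 0))
  expect_true(all(s[y == 0] < 0))
  expect_equal(auc(y, s), 1)
})

test_that("refitting with flipped labels reverses the score ranking", {
  d <- make_xy(n = 50, m = 8)
  for (spec in list(model_spec("PLS-DA", list(n_latent = 2)),
                    model_spec("PCR", list(n_components = 2)),
                    model_spec("PCLR", list(n_components = 2)),
                    model_spec("SVM-Lin", list(C = 1)),
                    model_spec("SVM-RBF", list(C = 1, gamma = 0.05)))) {
    s <- predict_scores(fit_model(spec, d$x, d$y), d$x)
    s_flip <- predict_scores(fit_model(spec, d$x, 1 - d$y), d$x)
    expect_equal(auc(d$y, s), 1 - auc(d$y, s_flip), tolerance = 1e-6,
                 label = spec$family)
  }
})

test_that("an untrained network is the seeded forward pass at chance level", {
  d <- make_xy(n = 60, m = 10, effect = 0, seed = 5)
  spec0 <- model_spec("ANN-SS", list(n_neurons = 3, learning_rate = 0.1),
                      fixed_settings = list(epochs = 0L), seed = 2)
  s1 <- predict_scores(fit_model(spec0, d$x, d$y), d$x)
  s2 <- predict_scores(fit_model(spec0, d$x, d$y), d$x)
  expect_identical(s1, s2)
  expect_true(all(s1 > 0 & s1 < 1))
  spec400 <- model_spec("ANN-SS", list(n_neurons = 3, learning_rate = 0.1),
                        seed = 2)
  expect_false(identical(
    s1, predict_scores(fit_model(spec400, d$x, d$y), d$x)))
})

test_that("a one-neuron linear-hidden network approaches logistic regression", {
  set.seed(42)
  n <- 200
  x <- matrix(rnorm(n * 3), n, 3); colnames(x) <- paste0("M", 1:3)
  y <- rbinom(n, 1, plogis(1.5 * x[, 1] - x[, 2]))
  ce <- function(p) -mean(y * log(p) + (1 - y) * log(1 - p))
  f <- fit_model(model_spec("ANN-LS",
                            list(n_neurons = 1, learning_rate = 0.1),
                            seed = 3), x, y)
  p_glm <- pmin(pmax(fitted(glm(y ~ x, family = binomial())), 1e-12),
                1 - 1e-12)
  expect_lt(ce(predict_scores(f, x)), ce(p_glm) * 1.05)
  expect_true(all(predict_scores(f, x) > 0 & predict_scores(f, x) < 1))
})

test_that("RF and ANN refits are bitwise reproducible given the seed", {
  d <- make_xy(n = 50, m = 8)
  for (spec in list(
    model_spec("RF", list(max_depth = 4, min_leaf_fraction = 0.05),
               seed = 7),
    model_spec("ANN-LS", list(n_neurons = 2, learning_rate = 0.1), seed = 7),
    model_spec("ANN-SS", list(n_neurons = 3, learning_rate = 0.2),
               seed = 7))) {
    s1 <- predict_scores(fit_model(spec, d$x, d$y), d$x)
    s2 <- predict_scores(fit_model(spec, d$x, d$y), d$x)
    expect_identical(s1, s2, label = spec$family)
  }
})

test_that("forest trees respect depth and leaf-occupancy constraints", {
  d <- make_xy(n = 60, m = 10)
  max_depth <- 3
  min_leaf_fraction <- 0.1
  f <- fit_model(model_spec("RF", list(max_depth = max_depth,
                                       min_leaf_fraction = min_leaf_fraction),
                            seed = 1), d$x, d$y)
  rf <- f$model
  node_depth <- function(info) {
    depth <- rep(NA_real_, nrow(info))
    depth[1] <- 0
    for (i in seq_len(nrow(info))) {
      for (child in c(info$leftChild[i], info$rightChild[i])) {
        if (!is.na(child)) depth[child + 1] <- depth[i] + 1
      }
    }
    depth
  }
  terminal <- predict(rf, data = as.data.frame(d$x),
                      type = "terminalNodes", num.threads = 1)$predictions
  min_leaf <- ceiling(min_leaf_fraction * nrow(d$x))
  for (tr in c(1, 50, 100)) {
    info <- ranger::treeInfo(rf, tr)
    expect_lte(max(node_depth(info), na.rm = TRUE), max_depth)
    inbag <- rf$inbag.counts[[tr]]
    counts <- tapply(inbag, terminal[, tr], sum)
    expect_gte(min(counts), min_leaf)
  }
})

test_that("score orientation and shape contracts hold across families", {
  d <- make_xy(n = 50, m = 8)
  f <- fit_model(model_spec("PLS-DA", list(n_latent = 2)), d$x, d$y)
  expect_error(predict_scores(f, d$x[, 1:3]),
               class = "metabench_shape_error")
  # column reordering by name is reconciled
  perm <- d$x[, rev(colnames(d$x))]
  expect_equal(predict_scores(f, perm), predict_scores(f, d$x))
  expect_error(fit_model(model_spec("PLS-DA", list(n_latent = 2)),
                         d$x, rep(1, nrow(d$x))),
               class = "metabench_fit_error")
  dummy <- fit_model(model_spec("Dummy"), d$x, d$y)
  expect_equal(predict_scores(dummy, d$x), rep(mean(d$y), nrow(d$x)))
  expect_equal(classify_scores(c(0.4, 0.5, 0.6)), c(0L, 0L, 1L))
})
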