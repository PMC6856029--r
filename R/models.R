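#' The eight model families
#'
#' Family identifiers accepted by [model_spec()]: `"PLS-DA"`, `"PCR"`,
#' `"PCLR"`, `"SVM-Lin"`, `"SVM-RBF"`, `"RF"`, `"ANN-LS"`, `"ANN-SS"`.
#' A ninth degenerate family, `"Dummy"`, predicts the training class
#' prevalence for every sample and serves as a chance-level reference model.
#' @export
MODEL_FAMILIES <- c("PLS-DA", "PCR", "PCLR", "SVM-Lin", "SVM-RBF",
                    "RF", "ANN-LS", "ANN-SS")

tunable_hyperparameters <- list(
  "PLS-DA" = "n_latent",
  "PCR" = "n_components",
  "PCLR" = "n_components",
  "SVM-Lin" = "C",
  "SVM-RBF" = c("C", "gamma"),
  "RF" = c("max_depth", "min_leaf_fraction"),
  "ANN-LS" = c("n_neurons", "learning_rate"),
  "ANN-SS" = c("n_neurons", "learning_rate"),
  "Dummy" = character(0)
)

default_fixed_settings <- function(family) {
  switch(family,
    "RF" = list(n_trees = 100L, min_samples_split = 2L),
    "ANN-LS" = ,
    "ANN-SS" = list(momentum = 0.5, decay = 0, epochs = 400L,
                    batch_size = 32L),
    list()
  )
}

#' Specify a model: family, hyperparameters, fixed settings, seed
#'
#' Each family exposes exactly its tunable hyperparameters
#' (see `tunable names` below); everything else about the training recipe is
#' a fixed setting with a documented default. Fixed defaults: random forests
#' use 100 CART trees, `sqrt(M)` candidate features per split and a minimum
#' of 2 samples to attempt a split; neural networks use momentum 0.5, no
#' learning-rate decay, 400 epochs, and mini-batches of 32 samples.
#'
#' Tunable names: PLS-DA `n_latent`; PCR and PCLR `n_components`;
#' SVM-Lin `C`; SVM-RBF `C`, `gamma`; RF `max_depth`, `min_leaf_fraction`
#' (fraction of training samples required in each leaf, in (0, 0.5\]);
#' ANN-LS and ANN-SS `n_neurons`, `learning_rate`.
#'
#' @param family One of [MODEL_FAMILIES] (or `"Dummy"`).
#' @param hyperparameters Named list supplying exactly the family's tunable
#'   hyperparameters.
#' @param fixed_settings Named list overriding fixed-setting defaults.
#' @param seed Integer seed controlling every stochastic element of training
#'   (forest resampling, network initialisation and batch order).
#' @return An object of class `model_spec`.
#' @export
#' @examples
#' model_spec("PLS-DA", list(n_latent = 2))
model_spec <- function(family, hyperparameters = list(),
                       fixed_settings = list(), seed = 1L) {
  if (!family %in% names(tunable_hyperparameters)) {
    stop_metabench(paste0("Unknown model family '", family, "'."),
                   "metabench_spec_error")
  }
  expected <- tunable_hyperparameters[[family]]
  got <- sort(as.character(names(hyperparameters) %||% character(0)))
  if (!identical(got, sort(as.character(expected)))) {
    stop_metabench(
      paste0(family, " requires exactly hyperparameters {",
             paste(expected, collapse = ", "), "}; got {",
             paste(got, collapse = ", "), "}."),
      "metabench_spec_error"
    )
  }
  h <- hyperparameters
  check_pos <- function(nm) {
    if (!is.null(h[[nm]]) && h[[nm]] <= 0) {
      stop_metabench(paste0(nm, " must be > 0."), "metabench_spec_error")
    }
  }
  for (nm in c("C", "gamma", "learning_rate")) check_pos(nm)
  for (nm in c("n_latent", "n_components", "n_neurons", "max_depth")) {
    if (!is.null(h[[nm]]) && (h[[nm]] < 1 || h[[nm]] != round(h[[nm]]))) {
      stop_metabench(paste0(nm, " must be an integer >= 1."),
                     "metabench_spec_error")
    }
  }
  if (!is.null(h$min_leaf_fraction) &&
      (h$min_leaf_fraction <= 0 || h$min_leaf_fraction > 0.5)) {
    stop_metabench("min_leaf_fraction must lie in (0, 0.5].",
                   "metabench_spec_error")
  }
  fixed <- modifyList(default_fixed_settings(family), fixed_settings)
  structure(
    list(family = family, hyperparameters = h, fixed_settings = fixed,
         seed = as.integer(seed)),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  hp <- paste(names(x$hyperparameters),
              vapply(x$hyperparameters, format, character(1)),
              sep = "=", collapse = ", ")
  cat("<model_spec> ", x$family, " (", hp, "); seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Gaussian radial basis function kernel matrix
#'
#' `K[i, j] = exp(-gamma * ||a_i - b_j||^2)`, the standard RBF convention
#' (the same parameterisation the SVM backend uses). Entries lie in (0, 1\]
#' with `K(x, x) = 1`.
#'
#' @param a,b Numeric matrices with the same number of columns.
#' @param gamma Positive shape parameter.
#' @return The `nrow(a)` x `nrow(b)` kernel matrix.
#' @export
rbf_kernel_matrix <- function(a, b, gamma) {
  if (gamma <= 0) {
    stop_metabench("gamma must be > 0.", "metabench_spec_error")
  }
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(ncol(a) == ncol(b))
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

#' Fit a model specification to preprocessed training data
#'
#' Trains one of the model families on an already preprocessed (transformed,
#' imputed, autoscaled) intensity matrix and a 0/1 outcome, returning a
#' fitted model whose [predict_scores()] output is a continuous score per
#' sample, oriented so that higher means more likely positive class.
#'
#' Score conventions: PLS-DA and PCR return the linear regression prediction
#' `y* = b0 + X beta` (threshold 0.5); PCLR, ANN-LS and ANN-SS return
#' probabilities in (0, 1); SVMs return the signed decision value (distance
#' from the separating hyperplane); RF returns the forest class-1 vote
#' fraction.
#'
#' @param spec A [model_spec()].
#' @param x Numeric training matrix (samples x features), preprocessed.
#' @param y Binary 0/1 training outcome with both classes present.
#' @return An object of class `fitted_model`.
#' @export
fit_model <- function(spec, x, y) {
  stopifnot(inherits(spec, "model_spec"))
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("M", seq_len(ncol(x)))
  y <- as.numeric(y)
  if (!is_binary01(y)) {
    stop_metabench("y must be 0/1 with both classes present.",
                   "metabench_fit_error")
  }
  h <- spec$hyperparameters
  fs <- spec$fixed_settings
  fit <- switch(spec$family,
    "PLS-DA" = list(kind = "linear", model = simpls(x, y, h$n_latent)),
    "PCR" = fit_pcr(x, y, h$n_components, logistic = FALSE),
    "PCLR" = fit_pcr(x, y, h$n_components, logistic = TRUE),
    "SVM-Lin" = fit_svm(x, y, kernel = "linear", C = h$C),
    "SVM-RBF" = fit_svm(x, y, kernel = "radial", C = h$C, gamma = h$gamma),
    "RF" = fit_rf(x, y, h, fs, spec$seed),
    "ANN-LS" = list(kind = "ann",
                    model = ann_fit(x, y, h$n_neurons, h$learning_rate,
                                    hidden = "linear",
                                    momentum = fs$momentum, decay = fs$decay,
                                    epochs = fs$epochs,
                                    batch_size = fs$batch_size,
                                    seed = spec$seed)),
    "ANN-SS" = list(kind = "ann",
                    model = ann_fit(x, y, h$n_neurons, h$learning_rate,
                                    hidden = "sigmoid",
                                    momentum = fs$momentum, decay = fs$decay,
                                    epochs = fs$epochs,
                                    batch_size = fs$batch_size,
                                    seed = spec$seed)),
    "Dummy" = list(kind = "dummy", model = list(score = mean(y)))
  )
  structure(
    c(fit, list(spec = spec, feature_names = colnames(x),
                n_train = nrow(x))),
    class = "fitted_model"
  )
}

fit_pcr <- function(x, y, k, logistic) {
  pca <- pca_decompose(x, k)
  scores <- pca$scores
  if (logistic) {
    g <- glm.fit(cbind(1, scores), y, family = binomial(),
                 control = list(epsilon = 1e-8, maxit = 100L))
    b <- coef(g)
  } else {
    b <- qr.coef(qr(cbind(1, scores)), y)
  }
  beta <- as.numeric(pca$loadings %*% b[-1])
  intercept <- b[1] - sum(pca$centre * beta)
  list(kind = if (logistic) "linear_logit" else "linear",
       model = list(coefficients = setNames(beta, colnames(x)),
                    intercept = intercept, pca = pca))
}

fit_svm <- function(x, y, kernel, C, gamma = NULL) {
  yf <- factor(y, levels = c("0", "1"))
  args <- list(x = x, y = yf, type = "C-classification", kernel = kernel,
               cost = C, scale = FALSE)
  if (!is.null(gamma)) args$gamma <- gamma
  model <- do.call(e1071::svm, args)
  dv <- attr(predict(model, x, decision.values = TRUE), "decision.values")
  # libsvm decision values are positive towards the first label of the
  # column name; orient so higher score = class 1
  flip <- if (startsWith(colnames(dv)[1], "1")) 1 else -1
  list(kind = "svm", model = model, flip = flip)
}

fit_rf <- function(x, y, h, fs, seed) {
  n <- nrow(x)
  model <- ranger::ranger(
    y = factor(y, levels = c("0", "1")),
    x = as.data.frame(x),
    num.trees = fs$n_trees,
    mtry = max(1L, floor(sqrt(ncol(x)))),
    max.depth = h$max_depth,
    min.bucket = ceiling(h$min_leaf_fraction * n),
    min.node.size = fs$min_samples_split,
    probability = TRUE,
    keep.inbag = TRUE,
    seed = seed,
    num.threads = 1
  )
  list(kind = "rf", model = model)
}

#' Continuous classification scores for new samples
#'
#' @param fitted A `fitted_model`.
#' @param x Numeric matrix with the training feature columns (order is
#'   reconciled by name when column names are present).
#' @return Numeric score vector, higher = more likely positive class.
#' @export
predict_scores <- function(fitted, x) {
  stopifnot(inherits(fitted, "fitted_model"))
  x <- as.matrix(x)
  if (!is.null(colnames(x))) {
    if (!all(fitted$feature_names %in% colnames(x))) {
      stop_metabench("Feature columns do not match the training features.",
                     "metabench_shape_error")
    }
    x <- x[, fitted$feature_names, drop = FALSE]
  } else if (ncol(x) != length(fitted$feature_names)) {
    stop_metabench("Feature count does not match the training features.",
                   "metabench_shape_error")
  }
  out <- switch(fitted$kind,
    "linear" = fitted$model$intercept +
      as.numeric(x %*% fitted$model$coefficients),
    "linear_logit" = plogis(fitted$model$intercept +
      as.numeric(x %*% fitted$model$coefficients)),
    "svm" = {
      dv <- attr(predict(fitted$model, x, decision.values = TRUE),
                 "decision.values")
      fitted$flip * as.numeric(dv)
    },
    "rf" = as.numeric(
      predict(fitted$model, data = as.data.frame(x),
              num.threads = 1)$predictions[, "1"]),
    "ann" = ann_predict(fitted$model, x),
    "dummy" = rep(fitted$model$score, nrow(x))
  )
  unname(out)
}

#' Hard class labels from scores
#'
#' Applies the strict `score > 0.5` rule used for PLS/PCR regression scores
#' and probability models (a score equal to 0.5 classifies negative).
#' @param scores Numeric scores.
#' @param threshold Decision threshold, default 0.5.
#' @return Integer 0/1 labels.
#' @export
classify_scores <- function(scores, threshold = 0.5) {
  as.integer(scores > threshold)
}

#' @export
print.fitted_model <- function(x, ...) {
  cat("<fitted_model> ", x$spec$family, " trained on ", x$n_train,
      " samples x ", length(x$feature_names), " features\n", sep = "")
  invisible(x)
}

#' @export
coef.fitted_model <- function(object, ...) {
  if (!object$kind %in% c("linear", "linear_logit")) {
    stop_metabench(
      paste0(object$spec$family,
             " has no single linear-form coefficient vector."),
      "metabench_spec_error"
    )
  }
  c("(Intercept)" = unname(object$model$intercept),
    object$model$coefficients)
}

#' @export
tidy.fitted_model <- function(x, ...) {
  b <- coef(x)
  tibble::tibble(term = names(b), estimate = unname(b))
}

#' @export
glance.fitted_model <- function(x, ...) {
  tibble::as_tibble(c(
    list(family = x$spec$family, n_train = x$n_train,
         n_features = length(x$feature_names), seed = x$spec$seed),
    x$spec$hyperparameters
  ))
}
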