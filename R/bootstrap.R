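#' Train/test evaluation of an optimised model
#'
#' Fits preprocessing and the model on the training rows of a split only,
#' then scores both sets: nothing from the test rows ever enters the
#' preprocessing statistics or the fit.
#'
#' @param spec A [model_spec()] carrying the selected hyperparameters.
#' @param dataset A `tidy_dataset`.
#' @param split A `split_indices` from [stratified_split()].
#' @param transform Preprocessing transform (`"log10"` or `"none"`).
#' @return An object of class `train_test_evaluation`: `auc_train`,
#'   `auc_test`, `roc_train`, `roc_test`, the fitted model and
#'   preprocessing state.
#' @export
evaluate_train_test <- function(spec, dataset, split, transform = "log10") {
  y_train <- outcome_vector(dataset, split$train_ids)
  y_test <- outcome_vector(dataset, split$test_ids)
  if (length(unique(y_test)) < 2) {
    stop_metabench("Test set contains a single class.",
                   "metabench_evaluation_error")
  }
  prep <- fit_preprocessing(feature_matrix(dataset, split$train_ids),
                            transform = transform)
  x_train <- apply_preprocessing(prep, feature_matrix(dataset,
                                                      split$train_ids))
  x_test <- apply_preprocessing(prep, feature_matrix(dataset,
                                                     split$test_ids))
  fit <- fit_model(spec, x_train, y_train)
  s_train <- predict_scores(fit, x_train)
  s_test <- predict_scores(fit, x_test)
  structure(
    list(auc_train = auc(y_train, s_train),
         auc_test = auc(y_test, s_test),
         roc_train = roc_curve(y_train, s_train),
         roc_test = roc_curve(y_test, s_test),
         fitted = fit, preprocessing = prep, spec = spec),
    class = "train_test_evaluation"
  )
}

#' @export
print.train_test_evaluation <- function(x, ...) {
  cat(sprintf("<train_test_evaluation> %s: AUC_train = %.3f, AUC_test = %.3f\n",
              x$spec$family, x$auc_train, x$auc_test))
  invisible(x)
}

#' @export
glance.train_test_evaluation <- function(x, ...) {
  tibble::tibble(family = x$spec$family,
                 auc_train = x$auc_train, auc_test = x$auc_test)
}

#' Out-of-bag bootstrap evaluation of a fixed model configuration
#'
#' Retrains a model with fixed optimal hyperparameters on `n_boot`
#' bootstrap resamples of the complete dataset and evaluates each on its
#' unused samples. Each resample draws N samples with replacement,
#' stratified by class (so roughly 63.2% of samples are in-bag, ~2/3,
#' leaving ~1/3 out-of-bag); preprocessing is refit on the in-bag rows of
#' every resample. The `n_boot` in-bag (IB) and out-of-bag (OOB) ROC
#' curves are interpolated onto a common false-positive-rate grid, from
#' which pointwise 95% percentile confidence bands and percentile AUC
#' intervals are formed.
#'
#' A resample whose OOB set lacks one of the classes is redrawn (up to
#' `max_retries` extra draws, recorded in the result).
#'
#' Two band constructions are available. `"simultaneous"` (the default)
#' calibrates the per-point quantile level so that 95% of the bootstrap
#' curves lie entirely inside the band; this is the construction under
#' which the statement "the held-out test ROC lies within the 95% OOB
#' band" is meaningful for the whole curve. `"pointwise"` applies the
#' 2.5/97.5 percentiles independently at every grid point; it is narrower
#' but jointly covers a full curve with much lower probability than 95%.
#'
#' @param spec A [model_spec()] with the fixed optimal hyperparameters.
#' @param dataset A `tidy_dataset`.
#' @param transform Preprocessing transform.
#' @param n_boot Number of bootstrap resamples (default 100).
#' @param seed Integer seed; resample b uses sub-seed (seed, b) so any
#'   single resample is reproducible in isolation.
#' @param fpr_grid Common FPR grid for the bands (default 101 uniform
#'   points).
#' @param band_type `"simultaneous"` (default) or `"pointwise"`; see
#'   Details.
#' @param max_retries Redraw budget for degenerate OOB sets.
#' @return An object of class `bootstrap_evaluation`: per-resample tibble
#'   `resamples` (`auc_ib`, `auc_oob`), band tibble `bands` (`fpr`,
#'   `ib_lower`, `ib_upper`, `oob_lower`, `oob_upper`, medians), the raw
#'   interpolated curve matrices `ib_curves` / `oob_curves` (`n_boot` rows),
#'   AUC interval list `auc_interval`, `n_boot`, `n_redraws`.
#' @export
bootstrap_evaluate <- function(spec, dataset, transform = "log10",
                               n_boot = 100L, seed = 1L,
                               fpr_grid = seq(0, 1, length.out = 101L),
                               band_type = c("simultaneous", "pointwise"),
                               max_retries = 20L) {
  band_type <- match.arg(band_type)
  ids <- sample_ids(dataset)
  y <- outcome_vector(dataset)
  x_raw <- feature_matrix(dataset)
  by_class <- split(seq_along(y), y)
  ib_tpr <- matrix(NA_real_, n_boot, length(fpr_grid))
  oob_tpr <- matrix(NA_real_, n_boot, length(fpr_grid))
  auc_ib <- numeric(n_boot)
  auc_oob <- numeric(n_boot)
  n_redraws <- 0L
  ib_sets <- vector("list", n_boot)
  oob_sets <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    attempt <- 0L
    repeat {
      draw <- with_seed(sub_seed(seed, b, 3 + attempt), {
        unlist(lapply(by_class, function(idx) {
          sample(idx, length(idx), replace = TRUE)
        }), use.names = FALSE)
      })
      oob <- setdiff(seq_along(y), draw)
      if (length(oob) >= 2 && length(unique(y[oob])) == 2) break
      attempt <- attempt + 1L
      n_redraws <- n_redraws + 1L
      if (attempt > max_retries) {
        stop_metabench(
          "Could not draw a bootstrap resample with both classes out-of-bag.",
          "metabench_bootstrap_error"
        )
      }
    }
    prep <- withCallingHandlers(
      fit_preprocessing(x_raw[draw, , drop = FALSE], transform = transform),
      metabench_dropped_features = function(w) {
        invokeRestart("muffleWarning")
      }
    )
    fit <- fit_model(spec, apply_preprocessing(prep,
                                               x_raw[draw, , drop = FALSE]),
                     y[draw])
    s_ib <- predict_scores(fit, apply_preprocessing(prep,
                                                    x_raw[draw, , drop = FALSE]))
    s_oob <- predict_scores(fit,
                            apply_preprocessing(prep,
                                                x_raw[oob, , drop = FALSE]))
    roc_ib <- roc_curve(y[draw], s_ib)
    roc_oob <- roc_curve(y[oob], s_oob)
    ib_tpr[b, ] <- interpolate_roc(roc_ib, fpr_grid)
    oob_tpr[b, ] <- interpolate_roc(roc_oob, fpr_grid)
    auc_ib[b] <- auc(y[draw], s_ib)
    auc_oob[b] <- auc(y[oob], s_oob)
    ib_sets[[b]] <- ids[sort(unique(draw))]
    oob_sets[[b]] <- ids[oob]
  }
  q <- function(m, p) apply(m, 2, quantile, probs = p, names = FALSE)
  band_ib <- curve_band(ib_tpr, band_type)
  band_oob <- curve_band(oob_tpr, band_type)
  bands <- tibble::tibble(
    fpr = fpr_grid,
    ib_lower = band_ib$lower, ib_median = q(ib_tpr, 0.5),
    ib_upper = band_ib$upper,
    oob_lower = band_oob$lower, oob_median = q(oob_tpr, 0.5),
    oob_upper = band_oob$upper
  )
  structure(
    list(
      resamples = tibble::tibble(resample = seq_len(n_boot),
                                 auc_ib = auc_ib, auc_oob = auc_oob,
                                 ib_ids = ib_sets, oob_ids = oob_sets),
      bands = bands, band_type = band_type, fpr_grid = fpr_grid,
      ib_curves = ib_tpr, oob_curves = oob_tpr,
      auc_interval = list(
        ib = quantile(auc_ib, c(0.025, 0.975), names = FALSE),
        oob = quantile(auc_oob, c(0.025, 0.975), names = FALSE)
      ),
      n_boot = as.integer(n_boot),
      n_redraws = n_redraws,
      spec = spec, seed = as.integer(seed)
    ),
    class = "bootstrap_evaluation"
  )
}

# 95% confidence band over an ensemble of curves (rows of `m`).
# "pointwise": independent 2.5/97.5 percentiles at each grid point.
# "simultaneous": the per-point tail level is relaxed until at least 95%
# of the ensemble's curves lie entirely inside the band, giving a band
# with joint (whole-curve) coverage of the ensemble at the nominal level.
curve_band <- function(m, band_type, level = 0.95) {
  if (band_type == "pointwise") {
    return(list(lower = apply(m, 2, quantile, 0.025, names = FALSE),
                upper = apply(m, 2, quantile, 0.975, names = FALSE)))
  }
  for (a in c(0.025, 0.02, 0.015, 0.01, 0.0075, 0.005, 0.0025, 0.001, 0)) {
    lower <- apply(m, 2, quantile, a, names = FALSE)
    upper <- apply(m, 2, quantile, 1 - a, names = FALSE)
    inside <- mean(apply(m, 1, function(r) {
      all(r >= lower - 1e-12 & r <= upper + 1e-12)
    }))
    if (inside >= level) break
  }
  list(lower = lower, upper = upper)
}

#' Is a ROC curve contained in the out-of-bag band?
#'
#' Interpolates `roc` onto the evaluation's FPR grid and checks
#' containment within the OOB band at every grid point.
#'
#' @param evaluation A `bootstrap_evaluation`.
#' @param roc A `roc_curve` (typically the held-out test ROC).
#' @return Logical scalar.
#' @export
roc_within_oob_band <- function(evaluation, roc) {
  tpr <- interpolate_roc(roc, evaluation$fpr_grid)
  all(tpr >= evaluation$bands$oob_lower - 1e-9 &
        tpr <= evaluation$bands$oob_upper + 1e-9)
}

#' @export
print.bootstrap_evaluation <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_evaluation> %s, %d resamples: AUC_OOB 95%% CI [%.3f, %.3f]\n",
    x$spec$family, x$n_boot, x$auc_interval$oob[1], x$auc_interval$oob[2]))
  invisible(x)
}

#' @export
tidy.bootstrap_evaluation <- function(x, ...) {
  x$resamples[c("resample", "auc_ib", "auc_oob")]
}

#' @export
glance.bootstrap_evaluation <- function(x, ...) {
  tibble::tibble(
    family = x$spec$family, n_boot = x$n_boot,
    auc_ib_median = median(x$resamples$auc_ib),
    auc_ib_lower = x$auc_interval$ib[1], auc_ib_upper = x$auc_interval$ib[2],
    auc_oob_median = median(x$resamples$auc_oob),
    auc_oob_lower = x$auc_interval$oob[1],
    auc_oob_upper = x$auc_interval$oob[2]
  )
}

#' @export
autoplot.bootstrap_evaluation <- function(object, roc_train = NULL,
                                          roc_test = NULL, ...) {
  b <- object$bands
  p <- ggplot2::ggplot(b, ggplot2::aes(x = .data$fpr)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ib_lower,
                                      ymax = .data$ib_upper),
                         fill = "darkgreen", alpha = 0.2) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$oob_lower,
                                      ymax = .data$oob_upper),
                         fill = "goldenrod", alpha = 0.3) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate")
  if (!is.null(roc_train)) {
    p <- p + ggplot2::geom_step(data = roc_train,
                                ggplot2::aes(x = .data$fpr, y = .data$tpr),
                                colour = "darkgreen")
  }
  if (!is.null(roc_test)) {
    p <- p + ggplot2::geom_step(data = roc_test,
                                ggplot2::aes(x = .data$fpr, y = .data$tpr),
                                colour = "goldenrod4")
  }
  p
}

#' Summarise a grid of model-by-dataset evaluations
#'
#' @param evaluations A tibble with columns `dataset_id`, `family`, and
#'   list-columns `train_test` (`train_test_evaluation` objects) and
#'   optionally `bootstrap` (`bootstrap_evaluation` objects).
#' @return A tibble, one row per (dataset, family), with `auc_train`,
#'   `auc_test` and (when bootstrap results are present) the IB/OOB 95%
#'   AUC interval bounds. The pairwise mean AUC_test differences between
#'   families across datasets are available via
#'   [pairwise_auc_differences()].
#' @export
summarise_runs <- function(evaluations) {
  stopifnot(nrow(evaluations) >= 1)
  rows <- purrr::pmap(evaluations, function(dataset_id, family, train_test,
                                            bootstrap = NULL, ...) {
    out <- tibble::tibble(
      dataset_id = dataset_id, family = family,
      auc_train = train_test$auc_train, auc_test = train_test$auc_test
    )
    if (!is.null(bootstrap)) {
      out$auc_ib_lower <- bootstrap$auc_interval$ib[1]
      out$auc_ib_upper <- bootstrap$auc_interval$ib[2]
      out$auc_oob_lower <- bootstrap$auc_interval$oob[1]
      out$auc_oob_upper <- bootstrap$auc_interval$oob[2]
    }
    out
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("run_summary", class(out))
  out
}

#' Pairwise mean AUC_test differences between model families
#'
#' For every ordered pair of families, the mean over datasets of
#' `AUC_test(family_a) - AUC_test(family_b)`.
#'
#' @param summary_table Output of [summarise_runs()] (or any tibble with
#'   `dataset_id`, `family`, `auc_test`).
#' @return A tibble with `family_a`, `family_b`, `mean_diff`.
#' @export
pairwise_auc_differences <- function(summary_table) {
  wide <- tidyr::pivot_wider(
    summary_table[c("dataset_id", "family", "auc_test")],
    names_from = "family", values_from = "auc_test"
  )
  fams <- setdiff(names(wide), "dataset_id")
  pairs <- expand.grid(family_a = fams, family_b = fams,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$family_a != pairs$family_b, ]
  pairs$mean_diff <- vapply(seq_len(nrow(pairs)), function(i) {
    mean(wide[[pairs$family_a[i]]] - wide[[pairs$family_b[i]]])
  }, numeric(1))
  tibble::as_tibble(pairs)
}

#' @export
autoplot.run_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("dataset_id", "family", "auc_train",
                                "auc_test")],
    cols = c("auc_train", "auc_test"),
    names_to = "metric", values_to = "auc"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$family, y = .data$dataset_id,
                                     fill = .data$auc)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$auc)),
                       size = 3) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0.5, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "AUC")
}
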