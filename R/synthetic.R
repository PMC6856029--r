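#' Specification of a synthetic metabolomics feature table
#'
#' Describes a generator for two-table tidy datasets with the statistical
#' structure the modelling workflow assumes: a low-rank latent factor space
#' (inter-metabolite covariance), a binary class effect that is either
#' linear in the latent space or nonlinear (radial or XOR-like), feature
#' intensities that are log-normal (effects act in log space, matching the
#' default log10 preprocessing), multiplicative noise, and optional
#' completely-at-random missing values.
#'
#' @param n_samples Number of samples.
#' @param n_features Number of metabolite features (default 100).
#' @param class_balance Fraction of samples in the positive class (0, 1);
#'   default 0.5.
#' @param latent_rank Number of latent factors `r` (default 2).
#' @param effect_size Class separation in latent standard-deviation units
#'   (difference between class means along latent axis 1 for the linear
#'   scenario); default 2.
#' @param scenario `"linear"` (class mean shift along latent axis 1),
#'   `"nonlinear_radial"` (class set by the latent radius) or
#'   `"nonlinear_xor"` (class set by the sign parity of the first two
#'   latent coordinates).
#' @param feature_noise_sd Standard deviation of the per-cell log-space
#'   noise (default 0.1).
#' @param missing_fraction Fraction of intensity cells set missing
#'   completely at random, in \[0, 0.5); default 0.
#' @param intensity_scale Log-space baseline intensity (default 6, i.e.
#'   raw intensities around exp(6)).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples, n_features = 100L, class_balance = 0.5,
                           latent_rank = 2L, effect_size = 2,
                           scenario = c("linear", "nonlinear_radial",
                                        "nonlinear_xor"),
                           feature_noise_sd = 0.1, missing_fraction = 0,
                           intensity_scale = 6, seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(n_samples >= 4, n_features >= 1, latent_rank >= 1,
            feature_noise_sd >= 0, intensity_scale > 0,
            missing_fraction >= 0, missing_fraction < 0.5,
            class_balance > 0, class_balance < 1)
  if (scenario == "nonlinear_xor" && latent_rank < 2) {
    stop_metabench("The XOR scenario needs latent_rank >= 2.",
                   "metabench_spec_error")
  }
  n_pos <- round(class_balance * n_samples)
  if (n_pos < 2 || n_samples - n_pos < 2) {
    stop_metabench("class_balance leaves fewer than 2 samples in a class.",
                   "metabench_spec_error")
  }
  structure(
    list(n_samples = as.integer(n_samples),
         n_features = as.integer(n_features),
         class_balance = class_balance,
         latent_rank = as.integer(latent_rank),
         effect_size = effect_size, scenario = scenario,
         feature_noise_sd = feature_noise_sd,
         missing_fraction = missing_fraction,
         intensity_scale = intensity_scale, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a tidy dataset from a synthetic specification
#'
#' Latent scores `T` (n x r) are standard normal. For the linear scenario
#' the two classes are shifted by `+/- effect_size / 2` along latent axis 1;
#' for the nonlinear scenarios the class label is assigned by thresholding
#' the latent radius (`nonlinear_radial`) or the product of the first two
#' latent coordinates (`nonlinear_xor`) at the empirical quantile matching
#' `class_balance`, so class counts are exact. Feature intensities are
#' `exp(intensity_scale + T W' + E)` with a seeded loading matrix `W`
#' (m x r, standard normal entries) and log-space noise `E`; missing cells
#' are then inserted completely at random.
#'
#' @param spec A [synthetic_spec()].
#' @return A validated `tidy_dataset` with outcome labels 0/1
#'   (positive label `"1"`).
#' @export
#' @examples
#' ds <- generate_dataset(synthetic_spec(n_samples = 40, n_features = 10))
#' table(outcome_vector(ds))
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_samples; m <- spec$n_features; r <- spec$latent_rank
  with_seed(spec$seed, {
    W <- matrix(rnorm(m * r), m, r)
    Tm <- matrix(rnorm(n * r), n, r)
    n_pos <- round(spec$class_balance * n)
    if (spec$scenario == "linear") {
      y <- sample(rep(c(1L, 0L), c(n_pos, n - n_pos)))
      Tm[, 1] <- Tm[, 1] + ifelse(y == 1, spec$effect_size / 2,
                                  -spec$effect_size / 2)
    } else {
      s <- if (spec$scenario == "nonlinear_radial") {
        sqrt(rowSums(Tm^2))
      } else {
        Tm[, 1] * Tm[, 2]
      }
      thr <- quantile(s, 1 - spec$class_balance, names = FALSE)
      y <- as.integer(s > thr)
      # exact counts even under (improbable) ties at the threshold
      if (sum(y) != n_pos) {
        y <- integer(n)
        y[order(s, decreasing = TRUE)[seq_len(n_pos)]] <- 1L
      }
    }
    log_x <- spec$intensity_scale + tcrossprod(Tm, W) +
      matrix(rnorm(n * m, sd = spec$feature_noise_sd), n, m)
    x <- exp(log_x)
    if (spec$missing_fraction > 0) {
      mask <- matrix(runif(n * m) < spec$missing_fraction, n, m)
      # keep at least 2 observed values per feature
      for (j in which(colSums(!mask) < 2)) {
        mask[seq_len(2), j] <- FALSE
      }
      x[mask] <- NA_real_
    }
    colnames(x) <- paste0("M", seq_len(m))
    data_table <- dplyr::bind_cols(
      tibble::tibble(
        SampleID = sprintf("S%04d", seq_len(n)),
        Class = y
      ),
      tibble::as_tibble(x)
    )
    peak_table <- tibble::tibble(
      Idx = seq_len(m),
      Name = paste0("M", seq_len(m)),
      Label = paste0("Synthetic metabolite ", seq_len(m))
    )
    tidy_dataset(data_table, peak_table, positive_label = "1")
  })
}

#' Generate a suite of synthetic benchmark datasets
#'
#' One dataset per (sample size, scenario) combination, with seeds derived
#' deterministically from the base specification's seed. Mirrors a
#' multi-dataset benchmarking design spanning small to large cohorts.
#'
#' @param base A [synthetic_spec()] supplying all other parameters.
#' @param n_values Vector of sample sizes.
#' @param scenarios Vector of scenario names.
#' @return A tibble with columns `n`, `scenario`, `seed` and a list-column
#'   `dataset` of `tidy_dataset` objects.
#' @export
generate_benchmark_suite <- function(base, n_values,
                                     scenarios = "linear") {
  stopifnot(length(n_values) >= 1, length(scenarios) >= 1)
  cells <- tidyr::expand_grid(n = as.integer(n_values), scenario = scenarios)
  cells$seed <- vapply(seq_len(nrow(cells)),
                       function(i) sub_seed(base$seed, i, 4), integer(1))
  cells$dataset <- purrr::pmap(cells, function(n, scenario, seed) {
    generate_dataset(synthetic_spec(
      n_samples = n, n_features = base$n_features,
      class_balance = base$class_balance, latent_rank = base$latent_rank,
      effect_size = base$effect_size, scenario = scenario,
      feature_noise_sd = base$feature_noise_sd,
      missing_fraction = base$missing_fraction,
      intensity_scale = base$intensity_scale, seed = seed
    ))
  })
  cells
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec> ", x$scenario, ": n=", x$n_samples, ", m=",
      x$n_features, ", r=", x$latent_rank, ", effect=", x$effect_size,
      ", seed=", x$seed, "\n", sep = "")
  invisible(x)
}
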