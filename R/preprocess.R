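#' Fit a train-derived preprocessing state
#'
#' Learns, from training rows only, the statistics used to transform and
#' scale intensity matrices: an optional `log10` transform, per-feature
#' median imputation of missing values, and autoscaling (mean-centring and
#' division by the per-feature population standard deviation). Applying the
#' same state to a test matrix uses only these training statistics, so no
#' information leaks from test rows.
#'
#' Zero-variance training features cannot be autoscaled and are dropped;
#' the drop is reported through a warning of class
#' `metabench_dropped_features` and recorded in the returned state.
#'
#' @param x_train Numeric training matrix (samples x features), column names
#'   required.
#' @param transform `"log10"` (default; requires positive non-missing
#'   values) or `"none"`.
#' @return An object of class `preprocessing_state` with elements
#'   `transform`, `centre`, `scale`, `impute` (per-feature training
#'   medians), `kept` and `dropped` feature names.
#' @export
#' @examples
#' x <- cbind(M1 = c(10, 100, 1000), M2 = c(1, 2, 4))
#' st <- fit_preprocessing(x, transform = "log10")
#' apply_preprocessing(st, x)
fit_preprocessing <- function(x_train, transform = c("log10", "none")) {
  transform <- match.arg(transform)
  x_train <- as.matrix(x_train)
  if (nrow(x_train) < 2) {
    stop_metabench("Need at least 2 training rows to fit preprocessing.",
                   "metabench_preprocessing_error")
  }
  if (is.null(colnames(x_train))) {
    colnames(x_train) <- paste0("M", seq_len(ncol(x_train)))
  }
  z <- transform_values(x_train, transform)
  impute <- apply(z, 2, median, na.rm = TRUE)
  if (anyNA(impute)) {
    stop_metabench("A feature has no observed training values.",
                   "metabench_preprocessing_error")
  }
  for (j in seq_len(ncol(z))) z[is.na(z[, j]), j] <- impute[j]
  centre <- colMeans(z)
  # population sd (n denominator): the scale of the autoscaled training
  # column is then exactly 1 including for tiny n
  scale <- sqrt(colMeans(sweep(z, 2, centre)^2))
  kept <- colnames(z)[scale > 1e-12]
  dropped <- setdiff(colnames(z), kept)
  if (length(dropped)) {
    warn(
      paste0("Dropped ", length(dropped),
             " zero-variance training feature(s): ",
             paste(head(dropped, 5), collapse = ", ")),
      class = "metabench_dropped_features"
    )
  }
  if (!length(kept)) {
    stop_metabench("All features have zero training variance.",
                   "metabench_preprocessing_error")
  }
  structure(
    list(transform = transform,
         centre = centre[kept], scale = scale[kept],
         impute = impute[kept], kept = kept, dropped = dropped),
    class = "preprocessing_state"
  )
}

#' Apply a fitted preprocessing state to a matrix
#'
#' @param state A `preprocessing_state` from [fit_preprocessing()].
#' @param x Numeric matrix with (at least) the retained feature columns.
#' @return The transformed, imputed, autoscaled matrix restricted to the
#'   retained features.
#' @export
apply_preprocessing <- function(state, x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("M", seq_len(ncol(x)))
  missing_cols <- setdiff(state$kept, colnames(x))
  if (length(missing_cols)) {
    stop_metabench(
      paste0("Matrix lacks retained feature(s): ",
             paste(head(missing_cols, 5), collapse = ", ")),
      "metabench_shape_error"
    )
  }
  z <- transform_values(x[, state$kept, drop = FALSE], state$transform)
  for (j in seq_along(state$kept)) z[is.na(z[, j]), j] <- state$impute[j]
  sweep(sweep(z, 2, state$centre), 2, state$scale, "/")
}

transform_values <- function(x, transform) {
  if (transform == "log10") {
    if (any(x <= 0, na.rm = TRUE)) {
      stop_metabench(
        "log10 transform requires strictly positive intensities.",
        "metabench_preprocessing_error"
      )
    }
    log10(x)
  } else {
    x
  }
}

#' @export
print.preprocessing_state <- function(x, ...) {
  cat("<preprocessing_state> transform=", x$transform, "; ",
      length(x$kept), " features kept, ", length(x$dropped), " dropped\n",
      sep = "")
  invisible(x)
}
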