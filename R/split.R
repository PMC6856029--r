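#' Stratified train/test split
#'
#' Splits the samples of a tidy dataset into training and test sets by
#' stratified random selection: within each outcome class,
#' `round(train_fraction * n_class)` samples (round-half-to-even) are drawn
#' into the training set and the remainder go to the test set. The default
#' 2:1 ratio (2/3 training) is the conventional design for benchmarking
#' binary classifiers on feature tables; one split is drawn per dataset and
#' reused unchanged across all model families so comparisons are unbiased.
#'
#' @param dataset A `tidy_dataset`.
#' @param train_fraction Fraction of each class assigned to training,
#'   in (0, 1). Default `2/3`.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return An object of class `split_indices`: a list with `train_ids`,
#'   `test_ids` (disjoint sample identifier vectors covering all samples)
#'   and `seed`.
#' @export
#' @examples
#' ds <- generate_dataset(synthetic_spec(n_samples = 30, n_features = 5))
#' sp <- stratified_split(ds, seed = 1)
#' length(sp$train_ids)
stratified_split <- function(dataset, train_fraction = 2 / 3, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  y <- outcome_vector(dataset)
  ids <- sample_ids(dataset)
  counts <- table(y)
  if (any(counts < 2)) {
    stop_metabench(
      "Every outcome class needs at least 2 samples for a stratified split.",
      "metabench_stratification_error"
    )
  }
  train_ids <- with_seed(seed, {
    unlist(lapply(sort(unique(y)), function(cl) {
      cl_ids <- ids[y == cl]
      n_train <- round(train_fraction * length(cl_ids))
      n_train <- min(max(n_train, 1L), length(cl_ids) - 1L)
      sample(cl_ids, n_train)
    }), use.names = FALSE)
  })
  train_ids <- ids[ids %in% train_ids]  # restore dataset order
  structure(
    list(
      train_ids = train_ids,
      test_ids = setdiff(ids, train_ids),
      seed = as.integer(seed)
    ),
    class = "split_indices"
  )
}

#' @export
print.split_indices <- function(x, ...) {
  cat("<split_indices> ", length(x$train_ids), " train / ",
      length(x$test_ids), " test (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

# Stratified k-fold assignment for cross-validation: within each class the
# samples are permuted and dealt round-robin into k folds, so every fold
# holds both classes whenever each class has >= k samples.
stratified_folds <- function(y, k, seed) {
  if (any(table(y) < k)) {
    stop_metabench(
      paste0("Each class needs at least k = ", k,
             " samples for stratified k-fold CV."),
      "metabench_fold_error"
    )
  }
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}
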