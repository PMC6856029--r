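#' Workflow configuration
#'
#' Bundles every setting of the per-dataset, per-family benchmarking
#' workflow (split, optimise, evaluate, bootstrap, report). The defaults
#' reproduce the reference design: a stratified 2:1 train/test split,
#' fivefold cross-validation with 10 Monte-Carlo repartitions, knee/fallback
#' hyperparameter selection against the `|R2 - Q2| = 0.2` guide line, and
#' 100 bootstrap resamples.
#'
#' @param datasets Named list of `tidy_dataset` objects (names become
#'   dataset identifiers), or a benchmark-suite tibble from
#'   [generate_benchmark_suite()].
#' @param families Model families to run (default all eight).
#' @param train_fraction Training fraction of the split (default 2/3).
#' @param k Cross-validation folds (default 5).
#' @param repartitions Monte-Carlo repartitions (default 10).
#' @param n_boot Bootstrap resamples (default 100).
#' @param metric_basis `"R2Q2"` or `"AUC"` optimisation basis.
#' @param transform Preprocessing transform (default `"log10"`).
#' @param grid_overrides Named list (by family) of axis-value overrides
#'   passed to [default_hyper_grid()].
#' @param run_bootstrap Whether to run the bootstrap stage (default TRUE).
#' @param output_dir Optional directory for artefacts (resolved config,
#'   CV surfaces, report).
#' @param seed Master seed for the run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(datasets, families = MODEL_FAMILIES,
                       train_fraction = 2 / 3, k = 5L, repartitions = 10L,
                       n_boot = 100L, metric_basis = "R2Q2",
                       transform = "log10", grid_overrides = list(),
                       run_bootstrap = TRUE, output_dir = NULL, seed = 1L) {
  if (tibble::is_tibble(datasets) && "dataset" %in% names(datasets)) {
    nms <- paste0("synthetic_", datasets$scenario, "_n", datasets$n)
    datasets <- setNames(datasets$dataset, make.unique(nms))
  }
  if (is.null(names(datasets)) || any(names(datasets) == "")) {
    names(datasets) <- paste0("dataset_", seq_along(datasets))
  }
  stopifnot(all(families %in% c(MODEL_FAMILIES, "Dummy")))
  structure(
    list(datasets = datasets, families = families,
         train_fraction = train_fraction, k = as.integer(k),
         repartitions = as.integer(repartitions),
         n_boot = as.integer(n_boot), metric_basis = metric_basis,
         transform = transform, grid_overrides = grid_overrides,
         run_bootstrap = isTRUE(run_bootstrap), output_dir = output_dir,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Run the full benchmarking workflow
#'
#' For each dataset: draw one stratified train/test split (reused unchanged
#' by every family), fit preprocessing on the training rows, and then for
#' each family run the Monte-Carlo cross-validated grid search, select the
#' optimal hyperparameters by the knee/fallback rule, evaluate the
#' optimised model on the held-out test set, and (optionally) compute
#' in-bag/out-of-bag bootstrap ROC bands on the complete dataset. A failure
#' in one (dataset, family) cell is recorded in that cell's `status` and
#' does not abort the remaining cells.
#'
#' @param config A [run_config()].
#' @return An object of class `workflow_run`: a tibble with one row per
#'   (dataset, family) holding `status`, the selected hyperparameters
#'   (list-column `selection`), and list-columns `surface`, `train_test`,
#'   `bootstrap`; the summary report is available through [tidy()] /
#'   [summarise_runs()]. Artefacts are written to `config$output_dir` when
#'   set.
#' @export
run_workflow <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cells <- tidyr::expand_grid(dataset_id = names(config$datasets),
                              family = config$families)
  results <- purrr::pmap(cells, function(dataset_id, family) {
    run_workflow_cell(config, dataset_id, family)
  })
  out <- dplyr::bind_cols(cells, dplyr::bind_rows(
    purrr::map(results, function(r) {
      tibble::tibble(status = r$status,
                     rule = r$rule %||% NA_character_,
                     auc_train = r$auc_train %||% NA_real_,
                     auc_test = r$auc_test %||% NA_real_)
    })
  ))
  out$selection <- purrr::map(results, "selection")
  out$surface <- purrr::map(results, "surface")
  out$train_test <- purrr::map(results, "train_test")
  out$bootstrap <- purrr::map(results, "bootstrap")
  class(out) <- c("workflow_run", class(out))
  attr(out, "config") <- config
  if (!is.null(config$output_dir)) {
    write_workflow_artefacts(out, config)
  }
  out
}

#' Optimise one family on a split and evaluate it on the held-out test set
#'
#' Convenience wrapper around one workflow cell without the bootstrap
#' stage: fit preprocessing on the training rows, run the Monte-Carlo
#' cross-validated grid search, select the optimum by the knee/fallback
#' rule, and evaluate the selected model on the test rows.
#'
#' @param family Model family name.
#' @param dataset A `tidy_dataset`.
#' @param split A `split_indices`.
#' @param grid A `hyper_grid`; defaults to [default_hyper_grid()] capped at
#'   the training-matrix rank.
#' @param k,repartitions Cross-validation settings.
#' @param seed Integer seed.
#' @param transform Preprocessing transform.
#' @param metric_basis `"R2Q2"` or `"AUC"`.
#' @return A list with `surface` (`cv_surface`), `selection`
#'   (`pareto_selection`) and `evaluation` (`train_test_evaluation`).
#' @export
optimise_and_evaluate <- function(family, dataset, split, grid = NULL,
                                  k = 5L, repartitions = 10L, seed = 1L,
                                  transform = "log10",
                                  metric_basis = "R2Q2") {
  prep <- withCallingHandlers(
    fit_preprocessing(feature_matrix(dataset, split$train_ids),
                      transform = transform),
    metabench_dropped_features = function(w) invokeRestart("muffleWarning")
  )
  x_train <- apply_preprocessing(prep,
                                 feature_matrix(dataset, split$train_ids))
  y_train <- outcome_vector(dataset, split$train_ids)
  if (is.null(grid)) {
    grid <- default_hyper_grid(
      family, max_rank = min(20L, qr(scale(x_train, scale = FALSE))$rank))
  }
  surface <- mc_cv_evaluate(family, grid, x_train, y_train, k = k,
                            repartitions = repartitions, seed = seed)
  selection <- select_optimum(surface, metric_basis = metric_basis)
  spec <- selected_model_spec(selection, seed = seed)
  list(surface = surface, selection = selection,
       evaluation = evaluate_train_test(spec, dataset, split,
                                        transform = transform))
}

run_workflow_cell <- function(config, dataset_id, family) {
  tryCatch({
    dataset <- config$datasets[[dataset_id]]
    split <- stratified_split(dataset, config$train_fraction,
                              seed = sub_seed(config$seed, 0, 5))
    prep <- withCallingHandlers(
      fit_preprocessing(feature_matrix(dataset, split$train_ids),
                        transform = config$transform),
      metabench_dropped_features = function(w) invokeRestart("muffleWarning")
    )
    x_train <- apply_preprocessing(prep,
                                   feature_matrix(dataset, split$train_ids))
    y_train <- outcome_vector(dataset, split$train_ids)
    grid <- default_hyper_grid(
      family,
      max_rank = min(20L, qr(scale(x_train, scale = FALSE))$rank),
      overrides = config$grid_overrides[[family]] %||% list()
    )
    surface <- mc_cv_evaluate(family, grid, x_train, y_train,
                              k = config$k,
                              repartitions = config$repartitions,
                              seed = sub_seed(config$seed, 1, 6))
    selection <- select_optimum(surface, metric_basis = config$metric_basis)
    spec <- selected_model_spec(selection,
                                seed = sub_seed(config$seed, 2, 7))
    tt <- evaluate_train_test(spec, dataset, split,
                              transform = config$transform)
    boot <- NULL
    if (config$run_bootstrap) {
      boot <- bootstrap_evaluate(spec, dataset,
                                 transform = config$transform,
                                 n_boot = config$n_boot,
                                 seed = sub_seed(config$seed, 3, 8))
    }
    list(status = "ok", rule = selection$rule, selection = selection,
         surface = surface, train_test = tt, bootstrap = boot,
         auc_train = tt$auc_train, auc_test = tt$auc_test)
  }, error = function(e) {
    list(status = paste0("error: ", conditionMessage(e)),
         selection = NULL, surface = NULL, train_test = NULL,
         bootstrap = NULL)
  })
}

write_workflow_artefacts <- function(run, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  resolved <- config[c("families", "train_fraction", "k", "repartitions",
                       "n_boot", "metric_basis", "transform", "seed")]
  resolved$datasets <- names(config$datasets)
  jsonlite::write_json(resolved,
                       file.path(config$output_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  readr::write_csv(tidy(run), file.path(config$output_dir, "report.csv"),
                   progress = FALSE)
  for (i in seq_len(nrow(run))) {
    if (!is.null(run$surface[[i]])) {
      s <- tibble::as_tibble(run$surface[[i]])
      s$q2_reps <- vapply(s$q2_reps, paste, character(1), collapse = ";")
      readr::write_csv(
        s,
        file.path(config$output_dir,
                  paste0("cv_surface_", run$dataset_id[i], "_",
                         gsub("[^A-Za-z0-9]", "", run$family[i]), ".csv")),
        progress = FALSE
      )
    }
  }
  invisible(config$output_dir)
}

#' @export
tidy.workflow_run <- function(x, ...) {
  ok <- x$status == "ok"
  base <- tibble::as_tibble(x)[c("dataset_id", "family", "status", "rule",
                                 "auc_train", "auc_test")]
  boot_rows <- purrr::map2(x$bootstrap, ok, function(b, is_ok) {
    if (is_ok && !is.null(b)) {
      tibble::tibble(auc_ib_lower = b$auc_interval$ib[1],
                     auc_ib_upper = b$auc_interval$ib[2],
                     auc_oob_lower = b$auc_interval$oob[1],
                     auc_oob_upper = b$auc_interval$oob[2])
    } else {
      tibble::tibble(auc_ib_lower = NA_real_, auc_ib_upper = NA_real_,
                     auc_oob_lower = NA_real_, auc_oob_upper = NA_real_)
    }
  })
  dplyr::bind_cols(base, dplyr::bind_rows(boot_rows))
}

#' @export
glance.workflow_run <- function(x, ...) {
  tibble::tibble(
    n_datasets = length(unique(x$dataset_id)),
    n_families = length(unique(x$family)),
    n_ok = sum(x$status == "ok"),
    n_failed = sum(x$status != "ok")
  )
}

#' @export
print.workflow_run <- function(x, ...) {
  cat("<workflow_run> ", length(unique(x$dataset_id)), " dataset(s) x ",
      length(unique(x$family)), " family(ies); ",
      sum(x$status == "ok"), "/", nrow(x), " cells ok\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Template for placing a manually downloaded accession
#'
#' Public metabolomics repositories (MetaboLights `MTBLSxxx`, Metabolomics
#' Workbench `STxxxxxx`) are not downloaded by this package. This helper
#' validates an accession identifier and returns instructions describing
#' where to place a manually retrieved, tidy-converted CSV pair so that
#' [read_tidy_tables()] and [run_workflow()] can use it. No network access
#' is performed.
#'
#' @param id Accession string, e.g. `"MTBLS404"` or `"ST001047"`.
#' @param dir Target directory for the converted files.
#' @return A character template (invisibly printed) naming the expected
#'   file paths.
#' @export
fetch_accession_stub <- function(id, dir = "data") {
  if (!grepl("^(MTBLS[0-9]+|ST[0-9]+)$", id)) {
    stop_metabench(
      paste0("'", id, "' is not a MetaboLights (MTBLSxxx) or ",
             "Metabolomics Workbench (STxxxxxx) accession."),
      "metabench_id_error"
    )
  }
  repo <- if (startsWith(id, "MTBLS")) {
    "https://www.ebi.ac.uk/metabolights/"
  } else {
    "https://www.metabolomicsworkbench.org/"
  }
  template <- paste0(
    "Accession ", id, "\n",
    "  1. Download the curated feature table from ", repo, "\n",
    "  2. Convert it to the two-table tidy format (Data + Peak).\n",
    "  3. Save the CSV pair as:\n",
    "       ", file.path(dir, paste0(id, "_Data.csv")), "\n",
    "       ", file.path(dir, paste0(id, "_Peak.csv")), "\n",
    "  4. Load with read_tidy_tables('", file.path(dir, id), "').\n"
  )
  cat(template)
  invisible(template)
}
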