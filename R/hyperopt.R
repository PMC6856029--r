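#' Default hyperparameter grid for a model family
#'
#' One- or two-axis candidate grids with a declared complexity ordering per
#' axis (used to break ties toward the simpler model). Defaults: number of
#' latent variables / components 1..min(20, rank); `C` seven log-spaced
#' values 1e-2..1e4; `gamma` seven log-spaced values 1e-5..1e1; tree depth
#' 1..10; minimum leaf fraction eight values 0.01..0.20; hidden neurons
#' 1..10; learning rate seven log-spaced values 1e-3..1.
#'
#' @param family A model family name.
#' @param max_rank Upper bound for component-count axes (e.g. the rank of
#'   the training matrix); default 20.
#' @param overrides Named list replacing the default candidate values of an
#'   axis.
#' @return An object of class `hyper_grid`: `family`, `axes` (named list of
#'   ordered candidate values) and `complexity` (+1 if larger values mean a
#'   more complex model, -1 otherwise).
#' @export
default_hyper_grid <- function(family, max_rank = 20L, overrides = list()) {
  axes <- switch(family,
    "PLS-DA" = list(n_latent = seq_len(min(20L, max_rank))),
    "PCR" = list(n_components = seq_len(min(20L, max_rank))),
    "PCLR" = list(n_components = seq_len(min(20L, max_rank))),
    "SVM-Lin" = list(C = 10^seq(-2, 4)),
    "SVM-RBF" = list(C = 10^seq(-2, 4), gamma = 10^seq(-5, 1)),
    "RF" = list(max_depth = 1:10,
                min_leaf_fraction = c(0.01, 0.02, 0.03, 0.05, 0.08,
                                      0.12, 0.16, 0.20)),
    "ANN-LS" = list(n_neurons = 1:10, learning_rate = 10^seq(-3, 0, 0.5)),
    "ANN-SS" = list(n_neurons = 1:10, learning_rate = 10^seq(-3, 0, 0.5)),
    "Dummy" = list(unused = c(0, 1)),
    stop_metabench(paste0("Unknown model family '", family, "'."),
                   "metabench_spec_error")
  )
  complexity <- c(n_latent = 1, n_components = 1, C = 1, gamma = 1,
                  max_depth = 1, min_leaf_fraction = -1, n_neurons = 1,
                  learning_rate = 1, unused = 1)
  for (nm in names(overrides)) {
    if (!nm %in% names(axes)) {
      stop_metabench(paste0("'", nm, "' is not an axis of the ", family,
                            " grid."), "metabench_spec_error")
    }
    axes[[nm]] <- sort(overrides[[nm]])
  }
  if (any(lengths(axes) < 2)) {
    stop_metabench("Every grid axis needs at least 2 candidate values.",
                   "metabench_spec_error")
  }
  structure(list(family = family, axes = axes,
                 complexity = complexity[names(axes)]),
            class = "hyper_grid")
}

#' Reduced hyperparameter grids for synthetic benchmarking
#'
#' Compact per-family grids used by the synthetic benchmark experiments
#' (and their examples in the package tests and reproduction script),
#' chosen so that a full Monte-Carlo CV search over every family stays
#' cheap while still covering the weak-to-strong regularisation range of
#' each axis. For real datasets prefer [default_hyper_grid()].
#'
#' @inheritParams default_hyper_grid
#' @return A `hyper_grid`.
#' @export
benchmark_hyper_grid <- function(family, max_rank = 20L) {
  overrides <- switch(family,
    "PLS-DA" = list(n_latent = seq_len(max(2L, min(4L, max_rank)))),
    "PCR" = list(n_components = seq_len(max(2L, min(4L, max_rank)))),
    "PCLR" = list(n_components = seq_len(max(2L, min(4L, max_rank)))),
    "SVM-Lin" = list(C = 10^(-2:1)),
    "SVM-RBF" = list(C = c(1, 10, 100), gamma = c(1e-3, 1e-2)),
    "RF" = list(max_depth = c(2L, 5L, 8L),
                min_leaf_fraction = c(0.02, 0.1)),
    "ANN-LS" = list(n_neurons = c(2L, 8L), learning_rate = c(0.05, 0.3)),
    "ANN-SS" = list(n_neurons = c(2L, 8L), learning_rate = c(0.05, 0.3)),
    list()
  )
  default_hyper_grid(family, max_rank = max_rank, overrides = overrides)
}

grid_points <- function(grid) {
  do.call(tidyr::expand_grid, grid$axes)
}

# Ordinal complexity score of a grid point: sum over axes of the (signed)
# position of its value in the ordered candidate list. Lower = simpler.
complexity_score <- function(grid, point) {
  sum(vapply(names(grid$axes), function(nm) {
    pos <- match(point[[nm]], grid$axes[[nm]])
    grid$complexity[[nm]] * pos
  }, numeric(1)))
}

#' Monte-Carlo cross-validated evaluation of a hyperparameter grid
#'
#' For every grid point, fits the model once on all training data (giving
#' R2 and AUC_full) and then runs `repartitions` independent stratified
#' k-fold cross-validations. Within each repartition the out-of-fold
#' predictions are pooled and scored once (Q2 uses the full training-set
#' outcome mean in its denominator); Q2 and AUC_CV are the means of the
#' per-repartition values. Fold assignments for repartition r are drawn
#' from sub-seed (seed, r), so the surface is deterministic given `seed`.
#'
#' @param family Model family name.
#' @param grid A [default_hyper_grid()] object.
#' @param x_train Preprocessed training matrix.
#' @param y_train 0/1 training outcome.
#' @param k Folds per repartition (default 5).
#' @param repartitions Monte-Carlo repartitions (default 10).
#' @param seed Integer seed.
#' @param fixed_settings Fixed-setting overrides passed to [model_spec()].
#' @return A tibble of class `cv_surface`: one row per grid point with the
#'   hyperparameter columns, `r2`, `q2`, `auc_full`, `auc_cv`, and a
#'   list-column `q2_reps` of the per-repartition Q2 values.
#' @export
mc_cv_evaluate <- function(family, grid, x_train, y_train, k = 5L,
                           repartitions = 10L, seed = 1L,
                           fixed_settings = list()) {
  x_train <- as.matrix(x_train)
  y_train <- as.numeric(y_train)
  pts <- grid_points(grid)
  fold_sets <- lapply(seq_len(repartitions), function(r) {
    stratified_folds(y_train, k, sub_seed(seed, r, 1))
  })
  y_mean <- mean(y_train)
  rows <- purrr::map(seq_len(nrow(pts)), function(i) {
    hp <- as.list(pts[i, , drop = FALSE])
    spec <- model_spec(family,
                       hyperparameters = hp[tunable_hyperparameters[[family]]],
                       fixed_settings = fixed_settings,
                       seed = sub_seed(seed, i, 2))
    full_fit <- fit_model(spec, x_train, y_train)
    full_scores <- predict_scores(full_fit, x_train)
    q2_reps <- numeric(repartitions)
    auc_reps <- numeric(repartitions)
    for (r in seq_len(repartitions)) {
      folds <- fold_sets[[r]]
      oof <- numeric(length(y_train))
      for (f in seq_len(k)) {
        hold <- folds == f
        fit_f <- fit_model(spec, x_train[!hold, , drop = FALSE],
                           y_train[!hold])
        oof[hold] <- predict_scores(fit_f, x_train[hold, , drop = FALSE])
      }
      q2_reps[r] <- coefficient_of_determination(y_train, oof,
                                                 ss_tot_mean = y_mean)
      auc_reps[r] <- auc(y_train, oof)
    }
    tibble::tibble(
      !!!hp,
      r2 = coefficient_of_determination(y_train, full_scores),
      q2 = mean(q2_reps),
      auc_full = auc(y_train, full_scores),
      auc_cv = mean(auc_reps),
      q2_reps = list(q2_reps)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "family") <- family
  attr(out, "grid") <- grid
  attr(out, "seed") <- as.integer(seed)
  attr(out, "repartitions") <- as.integer(repartitions)
  class(out) <- c("cv_surface", class(out))
  out
}

#' Pareto front of (value, discrepancy) points
#'
#' Returns the non-dominated subset when the first coordinate (Q2 or
#' AUC_CV) is maximised and the second (|R2 - Q2| or |AUC_full - AUC_CV|)
#' is minimised. Duplicated coordinate pairs collapse to one
#' representative. The front is returned sorted by increasing value.
#'
#' @param points A data frame with columns `value` and `gap`.
#' @return The subset of rows (plus originating row index `.idx`) forming
#'   the front.
#' @export
pareto_front <- function(points) {
  points <- tibble::as_tibble(points)
  stopifnot(all(c("value", "gap") %in% names(points)))
  points$.idx <- seq_len(nrow(points))
  pts <- points[order(-points$value, points$gap, points$.idx), ]
  pts <- pts[!duplicated(pts[c("value", "gap")]), ]
  best_gap <- Inf
  keep <- logical(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    if (pts$gap[i] < best_gap) {
      keep[i] <- TRUE
      best_gap <- pts$gap[i]
    }
  }
  front <- pts[keep, ]
  front[order(front$value), ]
}

#' Select the optimal grid point from a CV surface
#'
#' Implements the knee-point rule on the Pareto front in the
#' (Q2, |R2 - Q2|) plane (or the AUC analogue): the front member with the
#' greatest perpendicular distance to the chord joining the front's two
#' extreme points is chosen, provided that distance reaches the
#' knee-strength threshold `delta`. If no clear knee exists (distance below
#' `delta`, or fewer than three front points) the rule falls back to the
#' front point whose discrepancy is closest to the overtraining guide line
#' `|R2 - Q2| = 0.2`. Ties break toward the lower-complexity model.
#'
#' @param surface A `cv_surface` from [mc_cv_evaluate()].
#' @param metric_basis `"R2Q2"` (default) or `"AUC"`.
#' @param delta Knee-strength threshold in the (value, gap) plane
#'   (default 0.02).
#' @param fallback_line Target discrepancy of the fallback rule
#'   (default 0.2).
#' @return An object of class `pareto_selection`: `front` (tibble),
#'   `chosen` (one-row tibble of hyperparameters + metrics), `rule`
#'   (`"inflection"` or `"fallback_0.2"`), and `basis`.
#' @export
select_optimum <- function(surface, metric_basis = c("R2Q2", "AUC"),
                           delta = 0.02, fallback_line = 0.2) {
  metric_basis <- match.arg(metric_basis)
  stopifnot(nrow(surface) >= 1)
  grid <- attr(surface, "grid")
  pts <- tibble::as_tibble(surface)
  if (metric_basis == "R2Q2") {
    pts$value <- pts$q2
    pts$gap <- abs(pts$r2 - pts$q2)
  } else {
    pts$value <- pts$auc_cv
    pts$gap <- abs(pts$auc_full - pts$auc_cv)
  }
  pts$.complexity <- vapply(seq_len(nrow(pts)), function(i) {
    complexity_score(grid, pts[i, , drop = FALSE])
  }, numeric(1))
  # canonical order so the selection cannot depend on input order
  pts <- pts[order(pts$value, pts$gap, pts$.complexity), ]
  pts$.idx0 <- seq_len(nrow(pts))
  front <- pareto_front(pts[c("value", "gap")])
  front_rows <- pts[front$.idx, ]
  rule <- "fallback_0.2"
  chosen_i <- NULL
  if (nrow(front_rows) >= 3) {
    a <- c(front_rows$value[1], front_rows$gap[1])
    b <- c(front_rows$value[nrow(front_rows)],
           front_rows$gap[nrow(front_rows)])
    chord <- b - a
    chord_len <- sqrt(sum(chord^2))
    if (chord_len > 1e-12) {
      d <- abs(chord[2] * (front_rows$value - a[1]) -
                 chord[1] * (front_rows$gap - a[2])) / chord_len
      if (max(d) >= delta) {
        rule <- "inflection"
        cand <- which(d >= max(d) - 1e-12)
        chosen_i <- cand[which.min(front_rows$.complexity[cand])]
      }
    }
  }
  if (is.null(chosen_i)) {
    resid <- abs(front_rows$gap - fallback_line)
    cand <- which(resid <= min(resid) + 1e-12)
    chosen_i <- cand[which.min(front_rows$.complexity[cand])]
  }
  chosen <- front_rows[chosen_i, ]
  drop_cols <- c(".complexity", ".idx0")
  structure(
    list(front = front_rows[setdiff(names(front_rows), drop_cols)],
         chosen = chosen[setdiff(names(chosen), drop_cols)],
         rule = rule, basis = metric_basis,
         family = attr(surface, "family")),
    class = "pareto_selection"
  )
}

#' Build the optimal model spec from a selection
#'
#' @param selection A `pareto_selection`.
#' @param seed Seed for the final model.
#' @param fixed_settings Fixed-setting overrides.
#' @return A [model_spec()] carrying the chosen hyperparameters.
#' @export
selected_model_spec <- function(selection, seed = 1L,
                                fixed_settings = list()) {
  hp <- as.list(selection$chosen[tunable_hyperparameters[[selection$family]]])
  model_spec(selection$family, hyperparameters = hp,
             fixed_settings = fixed_settings, seed = seed)
}

#' @export
print.pareto_selection <- function(x, ...) {
  hp <- tunable_hyperparameters[[x$family]]
  cat("<pareto_selection> ", x$family, " via ", x$rule, " (", x$basis,
      " basis): ",
      paste(hp, vapply(as.list(x$chosen[hp]), format, character(1)),
            sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.pareto_selection <- function(x, ...) {
  dplyr::mutate(x$front,
                chosen = seq_len(nrow(x$front)) %in%
                  which(x$front$value == x$chosen$value &
                          x$front$gap == x$chosen$gap))
}

#' @export
glance.pareto_selection <- function(x, ...) {
  tibble::tibble(family = x$family, rule = x$rule, basis = x$basis,
                 value = x$chosen$value, gap = x$chosen$gap)
}

#' @export
autoplot.cv_surface <- function(object, selection = NULL, ...) {
  pts <- tibble::as_tibble(object)
  pts$gap <- abs(pts$r2 - pts$q2)
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$q2, y = .data$gap)) +
    ggplot2::geom_point(colour = "grey40") +
    ggplot2::labs(x = expression(Q^2), y = expression("|" * R^2 - Q^2 * "|"))
  if (!is.null(selection)) {
    p <- p +
      ggplot2::geom_path(data = selection$front,
                         ggplot2::aes(x = .data$value, y = .data$gap),
                         colour = "steelblue") +
      ggplot2::geom_point(data = selection$chosen,
                          ggplot2::aes(x = .data$value, y = .data$gap),
                          colour = "red", size = 3)
  }
  p
}
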