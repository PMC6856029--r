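# Independent oracles used to cross-check the implementation. These are
# deliberately written with different algorithms than the package code.

# NIPALS PLS1: iterative deflation of X (SIMPLS never deflates X).
nipals_pls <- function(x, y, a_max) {
  x <- as.matrix(x); y <- as.numeric(y)
  x_mean <- colMeans(x); y_mean <- mean(y)
  e <- sweep(x, 2, x_mean); f <- y - y_mean
  W <- NULL; P <- NULL; q <- numeric(a_max)
  for (a in seq_len(a_max)) {
    w <- crossprod(e, f)
    w <- w / sqrt(sum(w^2))
    t <- e %*% w
    tt <- sum(t^2)
    p <- crossprod(e, t) / tt
    q[a] <- sum(f * t) / tt
    e <- e - t %*% t(p)
    f <- f - q[a] * t
    W <- cbind(W, w); P <- cbind(P, p)
  }
  beta <- W %*% solve(crossprod(P, W), q)
  list(coefficients = as.numeric(beta),
       intercept = y_mean - sum(x_mean * beta))
}

# Exhaustive O(n^2) non-dominated filter (maximise value, minimise gap).
brute_force_front <- function(value, gap) {
  n <- length(value)
  nd <- vapply(seq_len(n), function(i) {
    !any(vapply(seq_len(n), function(j) {
      if (i == j) return(FALSE)
      (value[j] >= value[i] && gap[j] <= gap[i]) &&
        (value[j] > value[i] || gap[j] < gap[i])
    }, logical(1)))
  }, logical(1))
  unique(data.frame(value = value[nd], gap = gap[nd]))
}

# Exhaustive Mann-Whitney AUC by pair enumeration with half-weight ties.
brute_force_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Brute-force knee point: maximal perpendicular distance to the chord
# joining the extreme front points.
brute_force_knee <- function(value, gap) {
  a <- c(value[1], gap[1]); b <- c(value[length(value)], gap[length(gap)])
  ch <- b - a
  d <- abs(ch[2] * (value - a[1]) - ch[1] * (gap - a[2])) / sqrt(sum(ch^2))
  which.max(d)
}

# Minimal valid two-table dataset: 4 samples x 3 metabolites.
make_tiny_dataset <- function() {
  d <- tibble::tibble(
    SampleID = paste0("s", 1:4),
    Class = c(0L, 1L, 0L, 1L),
    M1 = c(1, 2, 3, 4), M2 = c(4, 3, 2, 1), M3 = c(1.5, 1, 2, 2.5)
  )
  p <- tibble::tibble(Name = c("M1", "M2", "M3"),
                      Label = paste("metabolite", 1:3))
  tidy_dataset(d, p)
}

# Hand-built dataset with specified per-class sample counts.
make_counted_dataset <- function(n0, n1, m = 3, seed = 1) {
  n <- n0 + n1
  x <- withr::with_seed(seed, matrix(exp(rnorm(n * m)), n, m))
  colnames(x) <- paste0("M", seq_len(m))
  d <- dplyr::bind_cols(
    tibble::tibble(SampleID = sprintf("s%03d", seq_len(n)),
                   Class = rep(c(0L, 1L), c(n0, n1))),
    tibble::as_tibble(x)
  )
  p <- tibble::tibble(Name = paste0("M", seq_len(m)))
  tidy_dataset(d, p)
}

# Fabricate a cv_surface for selection-rule tests: one row per point with
# prescribed (q2, gap) coordinates on a PLS-style single-axis grid.
make_fake_surface <- function(q2, gap, family = "PLS-DA") {
  n <- length(q2)
  grid <- default_hyper_grid(family, max_rank = max(2, n))
  axis <- names(grid$axes)[1]
  out <- tibble::tibble(!!axis := seq_len(n), r2 = q2 + gap, q2 = q2,
                        auc_full = 0.9, auc_cv = 0.8,
                        q2_reps = replicate(n, rep(0.5, 10), simplify = FALSE))
  attr(out, "family") <- family
  attr(out, "grid") <- grid
  class(out) <- c("cv_surface", class(out))
  out
}
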