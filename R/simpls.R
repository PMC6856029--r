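#' SIMPLS partial least squares for a single response
#'
#' Direct computation of PLS latent variables without deflating `X`: each
#' factor maximises covariance with the (current, deflated) cross-product
#' `X'y` subject to orthogonality of the score vectors. The fitted model
#' collapses to the standard linear form `y* = b0 + X beta`, which is what
#' makes PLS-DA interpretable as a linear classifier.
#'
#' Inputs are centred internally; the returned intercept restores the
#' original scale.
#'
#' @param x Numeric N x M matrix.
#' @param y Numeric length-N response (for PLS-DA, the 0/1 class vector).
#' @param n_latent Number of latent variables, `1 <= n_latent <= rank(X)`.
#' @return A list of class `simpls_fit`: `coefficients` (length M),
#'   `intercept`, `scores` (N x A, columnwise orthogonal), `weights`,
#'   `loadings`, `y_loadings`, `n_latent`.
#' @export
#' @examples
#' x <- matrix(rnorm(40), 8, 5)
#' f <- simpls(x, rnorm(8), n_latent = 2)
#' crossprod(f$scores)  # diagonal
simpls <- function(x, y, n_latent) {
  x <- as.matrix(x); y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), n_latent >= 1)
  x_mean <- colMeans(x); y_mean <- mean(y)
  xc <- sweep(x, 2, x_mean); yc <- y - y_mean
  a_max <- qr(xc)$rank
  if (n_latent > a_max) {
    stop_metabench(
      paste0("n_latent = ", n_latent, " exceeds rank(X) = ", a_max, "."),
      "metabench_rank_error"
    )
  }
  m <- ncol(xc); n <- nrow(xc)
  s <- crossprod(xc, yc)                       # m x 1
  R <- matrix(0, m, n_latent)                  # weights (X side)
  P <- matrix(0, m, n_latent)                  # X loadings
  Tm <- matrix(0, n, n_latent)                 # scores
  q <- numeric(n_latent)                       # y loadings
  V <- matrix(0, m, 0)                         # orthonormal basis of P
  for (a in seq_len(n_latent)) {
    r <- s                                     # univariate y: weight = s
    t <- xc %*% r
    t <- t - mean(t)
    nt <- sqrt(sum(t^2))
    if (nt < 1e-12) {
      stop_metabench("X'y deflated to zero before reaching n_latent.",
                     "metabench_rank_error")
    }
    t <- t / nt; r <- r / nt
    p <- crossprod(xc, t)
    q[a] <- sum(yc * t)
    v <- p
    if (a > 1) v <- v - V %*% crossprod(V, p)
    v <- v / sqrt(sum(v^2))
    s <- s - v %*% crossprod(v, s)
    R[, a] <- r; P[, a] <- p; Tm[, a] <- t; V <- cbind(V, v)
  }
  beta <- as.numeric(R %*% q)
  structure(
    list(coefficients = setNames(beta, colnames(x)),
         intercept = y_mean - sum(x_mean * beta),
         scores = Tm, weights = R, loadings = P, y_loadings = q,
         n_latent = n_latent),
    class = "simpls_fit"
  )
}

#' @export
predict.simpls_fit <- function(object, newdata, ...) {
  as.numeric(object$intercept + as.matrix(newdata) %*% object$coefficients)
}

#' Principal component decomposition of a data matrix
#'
#' Thin SVD-based PCA: columns are centred internally, loadings are
#' orthonormal, and explained variances (singular values squared divided by
#' N - 1) are non-increasing. With `k = rank(X)` the decomposition
#' reconstructs the centred matrix exactly.
#'
#' @param x Numeric N x M matrix.
#' @param k Number of components, `1 <= k <= rank(X)`.
#' @return A list of class `pca_fit`: `scores` (N x k), `loadings` (M x k,
#'   orthonormal), `explained_variance` (length k), `centre`.
#' @export
pca_decompose <- function(x, k) {
  x <- as.matrix(x)
  centre <- colMeans(x)
  xc <- sweep(x, 2, centre)
  sv <- svd(xc)
  rank_x <- sum(sv$d > max(dim(xc)) * max(sv$d, 1e-300) * 1e-12)
  if (k < 1 || k > rank_x) {
    stop_metabench(
      paste0("k = ", k, " outside 1..rank(X) = ", rank_x, "."),
      "metabench_rank_error"
    )
  }
  structure(
    list(scores = sv$u[, seq_len(k), drop = FALSE] %*%
           diag(sv$d[seq_len(k)], k, k),
         loadings = sv$v[, seq_len(k), drop = FALSE],
         explained_variance = sv$d[seq_len(k)]^2 / (nrow(x) - 1),
         centre = centre, rank = rank_x),
    class = "pca_fit"
  )
}
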