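# Two-layer feed-forward networks trained by mini-batch stochastic gradient
# descent on the binary cross-entropy loss. Two variants are used:
#   ANN-LS: linear hidden neurons, sigmoidal output (a learned linear
#           projection pushed through a logistic squashing function);
#   ANN-SS: sigmoidal hidden and output neurons (fully non-linear).
# Momentum, weight decay and the epoch count are fixed settings of the
# training recipe; the tunable hyperparameters are the hidden-layer size and
# the learning rate. Weights are initialised from a seeded uniform
# distribution scaled by fan-in, so training is deterministic given the seed.

sigmoid <- function(z) 1 / (1 + exp(-z))

ann_init <- function(m, n_neurons, seed) {
  with_seed(seed, {
    list(
      w1 = matrix(runif(m * n_neurons, -1, 1) / sqrt(m), m, n_neurons),
      b1 = numeric(n_neurons),
      w2 = matrix(runif(n_neurons, -1, 1) / sqrt(n_neurons), n_neurons, 1),
      b2 = 0
    )
  })
}

ann_forward <- function(w, x, hidden) {
  a1 <- sweep(x %*% w$w1, 2, w$b1, "+")
  h <- if (hidden == "sigmoid") sigmoid(a1) else a1
  p <- sigmoid(as.numeric(h %*% w$w2) + w$b2)
  list(h = h, p = p)
}

ann_fit <- function(x, y, n_neurons, learning_rate,
                    hidden = c("linear", "sigmoid"),
                    momentum = 0.5, decay = 0, epochs = 400,
                    batch_size = 32, seed = 1L) {
  hidden <- match.arg(hidden)
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x); m <- ncol(x)
  w <- ann_init(m, n_neurons, sub_seed(seed, 0, 11))
  v <- list(w1 = 0 * w$w1, b1 = 0 * w$b1, w2 = 0 * w$w2, b2 = 0)
  batch_size <- min(batch_size, n)
  if (epochs > 0) {
    with_seed(sub_seed(seed, 1, 11), {
      for (e in seq_len(epochs)) {
        lr <- learning_rate / (1 + decay * (e - 1))
        idx <- sample(n)
        starts <- seq(1, n, by = batch_size)
        for (s in starts) {
          b <- idx[s:min(s + batch_size - 1, n)]
          xb <- x[b, , drop = FALSE]; yb <- y[b]
          fw <- ann_forward(w, xb, hidden)
          # d loss / d pre-sigmoid output = p - y (cross-entropy + sigmoid)
          dout <- (fw$p - yb) / length(b)
          g_w2 <- crossprod(fw$h, dout)
          g_b2 <- sum(dout)
          dh <- tcrossprod(dout, w$w2)
          if (hidden == "sigmoid") dh <- dh * fw$h * (1 - fw$h)
          g_w1 <- crossprod(xb, dh)
          g_b1 <- colSums(dh)
          v$w1 <- momentum * v$w1 - lr * g_w1
          v$b1 <- momentum * v$b1 - lr * g_b1
          v$w2 <- momentum * v$w2 - lr * g_w2
          v$b2 <- momentum * v$b2 - lr * g_b2
          w$w1 <- w$w1 + v$w1; w$b1 <- w$b1 + v$b1
          w$w2 <- w$w2 + v$w2; w$b2 <- w$b2 + v$b2
        }
      }
    })
  }
  list(weights = w, hidden = hidden)
}

ann_predict <- function(fit, x) {
  p <- ann_forward(fit$weights, as.matrix(x), fit$hidden)$p
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}
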