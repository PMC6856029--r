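#' @importFrom rlang abort warn inform .data %||%
#' @importFrom stats approx coef glm.fit median plogis predict quantile rbinom
#'   rnorm runif sd setNames var binomial
#' @importFrom utils head modifyList
NULL

# Deterministic sub-seed scheme: every internal source of randomness
# (repartition r, bootstrap resample b, benchmark cell ...) draws its own
# stream from (seed, index) so any single unit is reproducible in isolation.
# Result stays inside the 32-bit integer range set.seed() accepts.
sub_seed <- function(seed, index, stream = 0L) {
  s <- (as.numeric(seed) %% 1e6) * 2011 +
    as.numeric(index) * 7919 +
    as.numeric(stream) * 104729 + 1
  as.integer(s %% 2147483629)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

stop_metabench <- function(message, class) {
  abort(message, class = c(class, "metabench_error"))
}

is_binary01 <- function(y) {
  all(y %in% c(0, 1)) && length(unique(y)) == 2L
}
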