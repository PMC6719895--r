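#' @importFrom stats rnorm runif pnorm dnorm sd var cor median optim fft
#' @importFrom methods as is
NULL

# Internal: consistent argument checking helpers.  These are deliberately
# minimal; user-facing constructors do the heavy validation.
.assert <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)

#' Derive reproducible child seeds from a master seed
#'
#' All stochastic routines in the package draw their randomness from integer
#' seeds.  Where a routine needs several independent streams (benchmark
#' sample sets, multi-start fits, trajectory pairs), child seeds are derived
#' deterministically from one master seed so that any result is reproducible
#' from `(inputs, master seed)` alone.
#'
#' @param master integer master seed (kept below 2^31).
#' @param n number of child seeds.
#' @return integer vector of `n` seeds in `[1, 2^31 - 1]`.
#' @export
seed_stream <- function(master, n) {
  .assert(.is_count(n), "n must be a positive integer")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master %% .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the RNG seeded by `seed` and restores the caller's
#' random stream afterwards, so seeded computations never perturb
#' surrounding randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# log(sum(exp(x))) guarded against underflow/overflow.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
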