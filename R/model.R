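#' Elementwise ReLU transfer function
#'
#' Applies \eqn{\phi(z) = \max(z, 0)} elementwise; for a linear (LDS)
#' parameter set the transfer function is the identity.
#'
#' @param z numeric vector or matrix.
#' @param linear logical; identity instead of ReLU.
#' @return transformed object of the same shape.
#' @export
relu <- function(z, linear = FALSE) {
  if (linear) z else pmax(z, 0)
}

#' One deterministic-plus-noise step of the latent map
#'
#' Computes \eqn{A \circ z_{prev} + W \phi(z_{prev}) + h + C s_t + noise}.
#'
#' @param params a [plrnn_params()] object.
#' @param z_prev numeric M-vector, previous state.
#' @param s_t optional K-vector of external inputs at time t.
#' @param noise numeric M-vector added to the deterministic step (zero by
#'   default).
#' @return numeric M-vector.
#' @export
latent_step <- function(params, z_prev, s_t = NULL, noise = 0) {
  M <- length(params$A)
  .assert(length(z_prev) == M, "z_prev has wrong length")
  z <- params$A * z_prev + drop(params$W %*% relu(z_prev, params$linear)) +
    params$h
  if (!is.null(params$C)) {
    .assert(!is.null(s_t) && length(s_t) == ncol(params$C),
            "s_t has wrong length")
    z <- z + drop(params$C %*% s_t)
  }
  z + noise
}

#' Generate a free-running latent trajectory
#'
#' Iterates the latent PLRNN map for `T` steps.  The initial state is drawn
#' from \eqn{N(\mu_0 + C s_1, \Sigma)} unless `z1` is supplied; per-step
#' process noise \eqn{N(0, \Sigma)} is added unless `noise = FALSE`.  If
#' any state magnitude exceeds `divergence_threshold` the run is flagged
#' globally unstable (attribute `"unstable"`), integration stops, and the
#' remaining rows repeat the last pre-divergence state.
#'
#' @param params a [plrnn_params()] object.
#' @param T number of steps.
#' @param S optional T x K input matrix.
#' @param seed optional RNG seed (fixed seed gives identical output).
#' @param z1 optional initial state (overrides the random draw).
#' @param noise logical; include process noise (default `TRUE`).
#' @param divergence_threshold magnitude defining global instability
#'   (default 1e10).
#' @return T x M matrix of latent states with logical attribute
#'   `"unstable"`.
#' @export
plrnn_generate <- function(params, T, S = NULL, seed = NULL, z1 = NULL,
                           noise = TRUE, divergence_threshold = 1e10) {
  .assert(.is_count(T), "T must be a positive integer")
  M <- length(params$A)
  if (!is.null(S)) {
    S <- as.matrix(S)
    .assert(nrow(S) >= T, "S must have at least T rows")
  }
  run <- function() {
    Z <- matrix(NA_real_, T, M)
    sdn <- if (noise) sqrt(params$Sigma) else rep(0, M)
    z <- if (is.null(z1)) {
      m1 <- params$mu0
      if (!is.null(params$C) && !is.null(S)) m1 <- m1 + drop(params$C %*% S[1, ])
      m1 + rnorm(M) * sdn
    } else as.numeric(z1)
    Z[1, ] <- z
    unstable <- FALSE
    if (T > 1) for (t in 2:T) {
      s_t <- if (!is.null(params$C) && !is.null(S)) S[t, ] else NULL
      eps <- if (noise) rnorm(M) * sdn else 0
      z <- latent_step(params, z, s_t, eps)
      if (!all(is.finite(z)) || max(abs(z)) > divergence_threshold) {
        unstable <- TRUE
        zlast <- Z[t - 1, ]
        Z[t:T, ] <- matrix(zlast, T - t + 1, M, byrow = TRUE)
        break
      }
      Z[t, ] <- z
    }
    attr(Z, "unstable") <- unstable
    Z
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Analytic enumeration of PLRNN fixed points
#'
#' For the autonomous noise-free map, fixed points within the linear region
#' indexed by the active set \eqn{\Omega} solve
#' \eqn{z^* = (I - A - W D_\Omega)^{-1} h}, where \eqn{D_\Omega} is the
#' diagonal 0/1 matrix of active (\eqn{z > 0}, strict) units.  All
#' \eqn{2^M} region configurations are enumerated; a candidate is accepted
#' iff its sign pattern matches its region.  Stability is assessed by the
#' spectral radius of \eqn{A + W D_\Omega} (unstable if \eqn{> 1}).  For a
#' linear parameter set the single fixed point of \eqn{A + W} is returned.
#'
#' @param params a [plrnn_params()] object (inputs treated as zero).
#' @param dedup_digits duplicates on region boundaries are merged after
#'   rounding locations to this many digits.
#' @return list with components `fixed_points` (list of
#'   `location`/`region`/`stable`/`max_abs_eig`), `n_stable_fp`,
#'   `n_unstable_fp`, and `skipped` (count of singular configurations).
#' @export
enumerate_fixed_points <- function(params, dedup_digits = 8) {
  M <- length(params$A)
  .assert(M <= 20, "fixed-point enumeration guarded at M <= 20")
  A <- diag(params$A, M)
  W <- params$W
  h <- params$h
  eye <- diag(M)

  accept <- list()
  skipped <- 0L
  configs <- if (params$linear) list(rep(TRUE, M)) else {
    lapply(0:(2^M - 1), function(k) as.logical(bitwAnd(bitwShiftR(k, 0:(M - 1)), 1L)))
  }
  for (act in configs) {
    D <- diag(as.numeric(act), M)
    Kmat <- A + W %*% D
    sys <- eye - Kmat
    z <- tryCatch(solve(sys, h), error = function(e) NULL)
    if (is.null(z)) { skipped <- skipped + 1L; next }
    ok <- params$linear || all((z > 0) == act)
    if (!ok) next
    ev <- max(abs(eigen(Kmat, only.values = TRUE)$values))
    accept[[length(accept) + 1L]] <- list(location = as.numeric(z),
                                          region = act,
                                          stable = ev <= 1,
                                          max_abs_eig = ev)
  }
  if (length(accept) > 1) {   # dedup boundary solutions
    key <- vapply(accept, function(f)
      paste(round(f$location, dedup_digits), collapse = ","), "")
    accept <- accept[!duplicated(key)]
  }
  stable <- vapply(accept, `[[`, TRUE, "stable")
  list(fixed_points = accept,
       n_stable_fp = sum(stable),
       n_unstable_fp = sum(!stable),
       skipped = skipped)
}

#' Maximal Lyapunov exponent from trajectory-pair divergence
#'
#' Estimates the largest Lyapunov exponent of a deterministic system from
#' the growth of the Euclidean distance between trajectory pairs started a
#' distance `d0` apart: log-distance curves are averaged over `origins`,
#' and a linear regression is fit to the pre-plateau segment of the
#' averaged curve (the plateau marks the full attractor extent).  The fit
#' window ends at the first lag where the curve has risen by
#' `plateau_frac` of the total rise toward its asymptotic median (median
#' over the final 20% of lags).  If no growth segment exists the exponent
#' is reported from the full curve with `low_confidence = TRUE`.
#'
#' @param simulate function `(x0, T)` returning a T x D matrix of states
#'   for a deterministic run started at `x0`.
#' @param origins matrix of starting points (rows), typically sampled from
#'   a long run on the attractor.
#' @param T_max number of steps tracked per pair.
#' @param d0 initial separation (default 1e-12; must be below 1e-10).
#' @param dt time units per step, so the exponent is per unit time.
#' @param seed seed for the random perturbation directions.
#' @param plateau_frac fraction of the total rise defining the fit window
#'   (default 0.9).
#' @return list with `exponent` (slope per unit time), `fit_end` (last lag
#'   used), `curve` (averaged log-distance), `low_confidence` flag.
#' @export
lyapunov_exponent <- function(simulate, origins, T_max, d0 = 1e-12, dt = 1,
                              seed = 1, plateau_frac = 0.9) {
  .assert(d0 < 1e-10, "d0 must be < 1e-10")
  origins <- as.matrix(origins)
  npair <- nrow(origins)
  D <- ncol(origins)
  dirs <- with_seed(seed, {
    V <- matrix(rnorm(npair * D), npair, D)
    V / sqrt(rowSums(V^2))
  })
  logd <- matrix(NA_real_, npair, T_max)
  for (i in seq_len(npair)) {
    x0 <- origins[i, ]
    X1 <- simulate(x0, T_max)
    X2 <- simulate(x0 + d0 * dirs[i, ], T_max)
    dd <- sqrt(rowSums((X1 - X2)^2))
    dd[dd == 0] <- .Machine$double.xmin
    logd[i, ] <- log(dd)
  }
  curve <- colMeans(logd)
  tail_n <- max(1L, floor(0.2 * T_max))
  plateau <- median(curve[(T_max - tail_n + 1L):T_max])
  rise <- plateau - curve[1]
  low_confidence <- rise <= 0
  fit_end <- if (low_confidence) T_max else {
    idx <- which(curve >= curve[1] + plateau_frac * rise)
    if (length(idx)) max(2L, idx[1]) else T_max
  }
  lag <- (seq_len(fit_end) - 1) * dt
  slope <- unname(coef(stats::lm(curve[seq_len(fit_end)] ~ lag))[2])
  list(exponent = slope, fit_end = fit_end, curve = curve,
       low_confidence = low_confidence)
}

#' Census of attractors by forward simulation
#'
#' Runs the autonomous noise-free PLRNN from `n_init` random initial
#' conditions for `T_run` steps and classifies the long-run behavior of
#' each run: convergence to a (stable) fixed point, a sustained recurrent
#' pattern classified as chaotic if the two-trajectory log-distance slope
#' is positive (above `chaos_slope`) and as a limit cycle otherwise, or
#' global instability (divergence beyond 1e10, counted separately).
#' Distinct non-fixed-point attractors are merged when their final-segment
#' point sets lie within `merge_tol` under nearest-neighbour matching.
#' Stable/unstable fixed-point counts come from the analytic enumeration
#' when \eqn{M \le 20}.
#'
#' @param params a [plrnn_params()] object.
#' @param n_init number of random initial conditions (default 100).
#' @param T_run steps per run (default 5000).
#' @param seed master seed for initial conditions.
#' @param init_sd standard deviation of the Gaussian initial conditions.
#' @param merge_tol attractor-identity tolerance (default 0.1).
#' @param chaos_slope per-step log-distance slope above which a recurrent
#'   attractor is called chaotic (default 0.005).
#' @param tail_len number of final steps used for attractor identity
#'   (default 500).
#' @return list with counts `n_stable_fp`, `n_unstable_fp`,
#'   `n_limit_cycles`, `n_chaotic`, `n_unstable_runs`, the enumerated
#'   `fixed_points`, and `lyapunov_estimates` per non-fixed-point
#'   attractor.
#' @export
classify_attractors <- function(params, n_init = 100, T_run = 5000, seed = 1,
                                init_sd = 2, merge_tol = 0.1,
                                chaos_slope = 0.005, tail_len = 500) {
  M <- length(params$A)
  tail_len <- min(tail_len, T_run %/% 2)
  seeds <- seed_stream(seed, n_init)
  fp_report <- if (M <= 20) enumerate_fixed_points(params) else
    list(fixed_points = list(), n_stable_fp = NA_integer_,
         n_unstable_fp = NA_integer_, skipped = NA_integer_)

  attractors <- list()   # each: list(tail = matrix, chaotic, lyap)
  n_unstable_runs <- 0L
  fp_locs <- list()
  for (i in seq_len(n_init)) {
    z1 <- with_seed(seeds[i], rnorm(M, 0, init_sd))
    Z <- plrnn_generate(params, T_run, z1 = z1, noise = FALSE)
    if (isTRUE(attr(Z, "unstable"))) { n_unstable_runs <- n_unstable_runs + 1L; next }
    tail_seg <- Z[(T_run - tail_len + 1L):T_run, , drop = FALSE]
    step_move <- sqrt(sum((Z[T_run, ] - Z[T_run - 1, ])^2))
    span <- max(apply(tail_seg, 2, function(v) diff(range(v))))
    if (step_move < 1e-8 && span < 1e-6) {            # fixed point
      fp_locs[[length(fp_locs) + 1L]] <- Z[T_run, ]
      next
    }
    merged <- FALSE
    for (k in seq_along(attractors)) {
      if (.pointset_dist(tail_seg, attractors[[k]]$tail) < merge_tol) {
        merged <- TRUE; break
      }
    }
    if (merged) next
    lyo <- tail_seg[round(seq(1, tail_len, length.out = 5)), , drop = FALSE]
    ly <- lyapunov_exponent(
      simulate = function(x0, T) plrnn_generate(params, T, z1 = x0, noise = FALSE),
      origins = lyo, T_max = min(1000L, T_run),
      d0 = 1e-12, dt = 1, seed = seeds[i])
    attractors[[length(attractors) + 1L]] <-
      list(tail = tail_seg, lyap = ly$exponent,
           chaotic = !ly$low_confidence && ly$exponent > chaos_slope)
  }
  chaotic <- vapply(attractors, `[[`, TRUE, "chaotic")
  n_sfp <- fp_report$n_stable_fp
  if (is.na(n_sfp)) {   # fall back to simulated fixed points when M > 20
    if (length(fp_locs)) {
      locs <- do.call(rbind, fp_locs)
      n_sfp <- nrow(unique(round(locs, 4)))
    } else n_sfp <- 0L
  }
  list(n_stable_fp = n_sfp,
       n_unstable_fp = fp_report$n_unstable_fp,
       n_limit_cycles = sum(!chaotic),
       n_chaotic = sum(chaotic),
       n_unstable_runs = n_unstable_runs,
       fixed_points = fp_report$fixed_points,
       lyapunov_estimates = vapply(attractors, `[[`, 0, "lyap"))
}

# Symmetric mean nearest-neighbour distance between two point sets
# (rows = points); states that have drifted to very large negative values
# are excluded from the computation.
.pointset_dist <- function(P1, P2, cap = 1e6) {
  keep1 <- rowSums(abs(P1) > cap) == 0
  keep2 <- rowSums(abs(P2) > cap) == 0
  if (!any(keep1) || !any(keep2)) return(Inf)
  P1 <- P1[keep1, , drop = FALSE]; P2 <- P2[keep2, , drop = FALSE]
  # subsample for speed; identity decision only needs coarse coverage
  sub <- function(P, n = 100L)
    P[unique(round(seq(1, nrow(P), length.out = min(n, nrow(P))))), , drop = FALSE]
  P1 <- sub(P1); P2 <- sub(P2)
  cross <- function(A, B) {
    d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
      outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
    sqrt(pmax(d2, 0))
  }
  Dm <- cross(P1, P2)
  max(mean(apply(Dm, 1, min)), mean(apply(Dm, 2, min)))
}
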