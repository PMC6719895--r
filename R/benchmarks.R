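#' Ground-truth benchmark systems
#'
#' Noisy training trajectories are drawn from two classic nonlinear flows:
#' the Lorenz system
#' \deqn{\dot x = s(y - x),\quad \dot y = x(r - z) - y,\quad \dot z = xy - bz}
#' (chaotic at the default \eqn{s = 10, r = 28, b = 8/3}) and the van der
#' Pol oscillator \eqn{\ddot x - \mu(1 - x^2)\dot x + \omega^2 x = 0}
#' written as a 2-D first-order system (limit cycle at \eqn{\mu = 2,
#' \omega = 1}).  Integration is fourth-order Runge-Kutta with step `dt`;
#' process noise is injected Euler-Maruyama style, i.e. after each RK4 step
#' an independent \eqn{N(0, \sigma^2 dt)} increment is added per state.
#' Initial conditions are drawn uniformly in an attractor bounding box and
#' a transient is discarded before recording, so recorded samples start on
#' (or very near) the attractor.
#'
#' @param T number of recorded samples (rows).
#' @param dt integration step, one output sample per step (default 0.01).
#' @param noise_var per-state process-noise variance \eqn{\sigma^2}
#'   (variance \eqn{\sigma^2 dt} is added per step); 0 for deterministic
#'   integration.
#' @param seed RNG seed; with `noise_var = 0` and a fixed initial condition
#'   the output is bit-reproducible.
#' @param s,r,b Lorenz parameters.
#' @param mu,omega van der Pol parameters.
#' @param transient number of initial integration steps discarded
#'   (default 1000).
#' @param x0 optional initial state (length 3 / 2); overrides the random
#'   draw, in which case `transient` is still applied.
#' @param standardize if `TRUE` (default) columns of the recorded
#'   trajectory are z-scored (see [standardize()]).
#' @return a `trajectory` object: list with `states` (T x D matrix), `dt`,
#'   `standardized` flag and, when standardized, the `center`/`scale` used.
#' @export
simulate_lorenz <- function(T, dt = 0.01, noise_var = 0, seed = NULL,
                            s = 10, r = 28, b = 8 / 3,
                            transient = 1000, x0 = NULL,
                            standardize = TRUE) {
  .assert(.is_count(T) && T >= 2, "T must be an integer >= 2")
  .assert(dt > 0, "dt must be positive")
  .assert(noise_var >= 0, "noise_var must be >= 0")
  deriv <- function(u) c(s * (u[2] - u[1]),
                         u[1] * (r - u[3]) - u[2],
                         u[1] * u[2] - b * u[3])
  box <- rbind(c(-20, 20), c(-25, 25), c(5, 45))   # typical attractor extent
  .simulate_flow(deriv, D = 3, T = T, dt = dt, noise_var = noise_var,
                 seed = seed, transient = transient, x0 = x0, box = box,
                 standardize = standardize)
}

#' @rdname simulate_lorenz
#' @export
simulate_vdp <- function(T, dt = 0.01, noise_var = 0, seed = NULL,
                         mu = 2, omega = 1,
                         transient = 1000, x0 = NULL, standardize = TRUE) {
  .assert(.is_count(T) && T >= 2, "T must be an integer >= 2")
  .assert(dt > 0, "dt must be positive")
  .assert(noise_var >= 0, "noise_var must be >= 0")
  deriv <- function(u) c(u[2],
                         mu * (1 - u[1]^2) * u[2] - omega^2 * u[1])
  box <- rbind(c(-2.5, 2.5), c(-4, 4))
  .simulate_flow(deriv, D = 2, T = T, dt = dt, noise_var = noise_var,
                 seed = seed, transient = transient, x0 = x0, box = box,
                 standardize = standardize)
}

# Shared RK4 + additive-noise integrator.
.simulate_flow <- function(deriv, D, T, dt, noise_var, seed, transient,
                           x0, box, standardize) {
  run <- function() {
    u <- if (is.null(x0)) {
      box[, 1] + runif(D) * (box[, 2] - box[, 1])
    } else {
      .assert(length(x0) == D, "x0 has wrong length")
      as.numeric(x0)
    }
    nstep <- transient + T
    out <- matrix(NA_real_, T, D)
    sdn <- sqrt(noise_var * dt)
    for (i in seq_len(nstep)) {
      k1 <- deriv(u)
      k2 <- deriv(u + dt / 2 * k1)
      k3 <- deriv(u + dt / 2 * k2)
      k4 <- deriv(u + dt * k3)
      u <- u + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (sdn > 0) u <- u + rnorm(D, 0, sdn)
      if (!all(is.finite(u)))
        stop(sprintf("integration failure: non-finite state at step %d", i),
             call. = FALSE)
      if (i > transient) out[i - transient, ] <- u
    }
    out
  }
  states <- if (is.null(seed)) run() else with_seed(seed, run())
  traj <- new_trajectory(states, dt = dt)
  if (standardize) standardize(traj) else traj
}

#' Trajectory container
#'
#' @param states T x D numeric matrix, one row per time point.
#' @param dt sampling interval.
#' @param standardized logical flag.
#' @param center,scale optional per-column transform parameters retained by
#'   [standardize()] for inverse mapping.
#' @return object of class `trajectory`.
#' @export
new_trajectory <- function(states, dt = 1, standardized = FALSE,
                           center = NULL, scale = NULL) {
  states <- as.matrix(states)
  structure(list(states = states, dt = dt, standardized = standardized,
                 center = center, scale = scale),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: T = %d, D = %d, dt = %g%s\n",
              nrow(x$states), ncol(x$states), x$dt,
              if (x$standardized) ", standardized" else ""))
  invisible(x)
}

#' Z-score a trajectory column-wise
#'
#' Columns are standardized with the trajectory's own mean and standard
#' deviation; the transform parameters are retained on the returned object
#' so observations can be mapped back.  Standardizing an already
#' standardized trajectory is a no-op up to numerical precision
#' (idempotence).
#'
#' @param traj a `trajectory` (or plain matrix, which is wrapped).
#' @return standardized `trajectory`.
#' @export
standardize <- function(traj) {
  if (!inherits(traj, "trajectory")) traj <- new_trajectory(traj)
  X <- traj$states
  .assert(nrow(X) >= 2, "need T >= 2 to standardize")
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  .assert(all(scl > 0), "degenerate input: zero-variance column")
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  # compose with any earlier transform so center/scale always map back to
  # the original coordinates
  if (traj$standardized && !is.null(traj$center)) {
    scl0 <- traj$scale; ctr0 <- traj$center
    ctr <- ctr0 + ctr * scl0
    scl <- scl0 * scl
  }
  new_trajectory(Xs, dt = traj$dt, standardized = TRUE,
                 center = ctr, scale = scl)
}

#' Reference teacher PLRNN with a stable limit cycle
#'
#' A fixed 3-unit PLRNN used as a ground-truth ("teacher") system for
#' recovery experiments: it has one unstable fixed point and a single
#' globally attracting stable limit cycle (maximal Lyapunov exponent
#' \eqn{\approx 0}), with state amplitudes of a few units.  The
#' parameters are frozen constants so teacher-student experiments are
#' exactly reproducible.
#'
#' @param Sigma process-noise variances of the teacher (default 1e-3).
#' @return a [plrnn_params()] object, M = 3.
#' @export
teacher_limit_cycle <- function(Sigma = rep(1e-3, 3)) {
  plrnn_params(
    A = c(0.7554, 0.706058, 0.75178),
    W = matrix(c(0, -0.664397, -0.2002,
                 1.448378, 0, -0.312822,
                 0.000947, 1.198149, 0), 3, 3),
    h = c(-0.611063, -0.363329, 0.407673),
    mu0 = c(0, 0, 0),
    Sigma = Sigma)
}

#' Simulate standardized observations from a teacher PLRNN
#'
#' Generates a latent trajectory from `params` (discarding a transient),
#' maps it through a Gaussian decoder, and standardizes the result — the
#' synthetic-data path for teacher-student recovery experiments.
#'
#' @param params teacher [plrnn_params()].
#' @param obs observation model (default: identity loadings with small
#'   noise `gamma`).
#' @param T number of samples.
#' @param seed RNG seed.
#' @param gamma observation-noise variance of the default decoder.
#' @param burn discarded transient steps (default 200).
#' @return standardized `trajectory` with the latent path in attribute
#'   `"Z"`.
#' @export
simulate_teacher <- function(params, obs = NULL, T = 1000, seed = 1,
                             gamma = 0.01, burn = 200) {
  M <- length(params$A)
  if (is.null(obs)) obs <- obs_gaussian(diag(M), rep(gamma, M))
  Z <- plrnn_generate(params, T + burn, seed = seed, noise = TRUE)
  Z <- Z[(burn + 1):(burn + T), , drop = FALSE]
  X <- emit(obs, Z, noise = TRUE, seed = seed + 1, linear = params$linear)
  tr <- standardize(new_trajectory(X, dt = 1))
  attr(tr, "Z") <- Z
  tr
}

#' Draw a set of independent benchmark trajectories
#'
#' The protocol evaluation draws `n` standardized trajectories of length
#' `T` from a ground-truth system; child seeds are derived reproducibly
#' from one master seed via [seed_stream()], so `n = 1` coincides with a
#' direct simulator call using that child seed.
#'
#' @param system `"lorenz"` or `"vdp"`.
#' @param n number of samples.
#' @param T samples per trajectory (default 1000).
#' @param noise_var process-noise variance; defaults to the benchmark
#'   levels 0.3 (Lorenz) and 0.1 (van der Pol).
#' @param master_seed master RNG seed.
#' @param ... further arguments passed to the simulator.
#' @return list of `n` standardized `trajectory` objects; the child seed of
#'   each is stored in attribute `"seed"`.
#' @export
sample_benchmark_set <- function(system = c("lorenz", "vdp"), n, T = 1000,
                                 noise_var = NULL, master_seed = 1, ...) {
  system <- match.arg(system)
  .assert(.is_count(n), "n must be a positive integer")
  if (is.null(noise_var)) noise_var <- if (system == "lorenz") 0.3 else 0.1
  sim <- if (system == "lorenz") simulate_lorenz else simulate_vdp
  seeds <- seed_stream(master_seed, n)
  lapply(seq_len(n), function(i) {
    tr <- sim(T = T, noise_var = noise_var, seed = seeds[i], ...)
    attr(tr, "seed") <- seeds[i]
    tr
  })
}
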