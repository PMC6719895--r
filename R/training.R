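#' Training configuration
#'
#' Collects all tunables of the stepwise annealing protocol and the EM
#' loop.  Defaults follow the protocol: process noise fixed at the
#' identity for the LDS initialization and first PLRNN round, then
#' annealed through `diag(10^-i)`, `i = 1..3`, with the observation
#' loadings frozen from the first annealing round on (and the observation
#' noise additionally frozen in `fmri_mode`).
#'
#' @param M latent dimension.
#' @param anneal_sigma_levels decreasing process-noise variances; the
#'   first is used for the LDS and first PLRNN rounds, the rest for the
#'   annealing rounds.
#' @param fix_obs_from_step protocol step index (1-based over the EM
#'   rounds run) from which `B` is frozen; default 3 = first annealing
#'   round.
#' @param fmri_mode logical; additionally freeze `Gamma` from
#'   `fix_obs_from_step` on.
#' @param em_max_iter maximum EM iterations per round (default 50).
#' @param em_tol relative expected-joint-log-likelihood change stopping
#'   threshold (default 1e-4).
#' @param lambda_reg L2 regularization on the latent regression
#'   coefficients (default 0; 50 is typical for empirical BOLD data).
#' @param random_sigma fixed process-noise variance of the
#'   random-initialization protocol (default 1e-3).
#' @param seed RNG seed for the parameter draw.
#' @param stability_T free-run length used to flag globally unstable
#'   estimates (default 10000).
#' @param max_flip_rounds E-step bit-flip cap per solve.
#' @param em_drop_abort relative expected-joint-log-likelihood drop that
#'   aborts a round with diagnostics (default 0.5, i.e. only
#'   catastrophic collapse; the approximate Laplace E-step routinely
#'   produces transient dips of up to ~10% that healthy runs recover
#'   from).
#' @return list of class `training_config`.
#' @export
training_config <- function(M, anneal_sigma_levels = c(1, 1e-1, 1e-2, 1e-3),
                            fix_obs_from_step = 3, fmri_mode = FALSE,
                            em_max_iter = 50, em_tol = 1e-4,
                            lambda_reg = 0, random_sigma = 1e-3,
                            seed = 1, stability_T = 10000,
                            max_flip_rounds = 100, em_drop_abort = 0.5) {
  .assert(.is_count(M), "M must be a positive integer")
  .assert(all(diff(anneal_sigma_levels) < 0), "sigma levels must decrease")
  .assert(em_tol > 0, "em_tol must be positive")
  structure(list(M = M, anneal_sigma_levels = anneal_sigma_levels,
                 fix_obs_from_step = fix_obs_from_step,
                 fmri_mode = fmri_mode,
                 em_max_iter = em_max_iter, em_tol = em_tol,
                 lambda_reg = lambda_reg, random_sigma = random_sigma,
                 seed = seed, stability_T = stability_T,
                 max_flip_rounds = max_flip_rounds,
                 em_drop_abort = em_drop_abort),
            class = "training_config")
}

#' Random parameter initialization biased toward stable models
#'
#' Draws `A` uniform in (0.5, 0.99), off-diagonal `W` as
#' \eqn{N(0, 0.01/M)}, and rescales the pair until the spectral radius of
#' \eqn{A + W} is below 1 (stability bias).  `B` gets random orthonormal
#' columns, biases and input/nuisance weights are small normal, and both
#' noise covariances start at the identity.
#'
#' @param M,N latent and observed dimension.
#' @param K number of external inputs (0 for none).
#' @param P number of nuisance regressors (0 for none).
#' @param seed RNG seed; equal seeds give identical draws.
#' @param linear logical; mark the latent model as linear (LDS).
#' @return list with `params` ([plrnn_params()]) and `obs_template`
#'   (list with `B`, `J`, `Gamma`).
#' @export
init_random <- function(M, N, K = 0, P = 0, seed = 1, linear = FALSE) {
  with_seed(seed, {
    A <- runif(M, 0.5, 0.99)
    W <- matrix(rnorm(M * M, 0, sqrt(0.01 / M)), M, M)
    diag(W) <- 0
    rad <- function() max(abs(eigen(diag(A, M) + W, only.values = TRUE)$values))
    while (rad() >= 1) {
      kappa <- 0.98 / rad()
      A <- A * kappa; W <- W * kappa
    }
    h <- rnorm(M, 0, 0.1)
    mu0 <- rnorm(M, 0, 0.1)
    C <- if (K > 0) matrix(rnorm(M * K, 0, 0.1), M, K) else NULL
    Bfull <- matrix(rnorm(N * max(N, M)), N)
    B <- qr.Q(qr(Bfull))[, seq_len(min(M, N)), drop = FALSE]
    if (M > N) B <- cbind(B, matrix(rnorm(N * (M - N), 0, 1 / sqrt(N)), N))
    J <- if (P > 0) matrix(rnorm(N * P, 0, 0.1), N, P) else NULL
    list(params = plrnn_params(A = A, W = W, h = h, mu0 = mu0,
                               Sigma = rep(1, M), C = C, linear = linear),
         obs_template = list(B = B, J = J, Gamma = rep(1, N)))
  })
}

# One EM round with a prescribed freezing pattern.
#   fixed_sigma: numeric scalar variance to hold Sigma at (always fixed
#   within a round under the stepwise protocol).
em_round <- function(X, S, R, params, obs, fixed_sigma,
                     update_B = TRUE, update_gamma = TRUE,
                     lambda = 0, max_iter = 50, tol = 1e-4,
                     max_flip_rounds = 100, z_init = NULL,
                     drop_abort = 0.5) {
  M <- length(params$A)
  params$Sigma <- rep(fixed_sigma, M)
  trace <- numeric(0)
  ll_prev <- -Inf
  post <- NULL
  for (it in seq_len(max_iter)) {
    post <- estep(params, obs, X, S, R, z_init = z_init,
                  max_rounds = max_flip_rounds)
    z_init <- post$z
    ll <- expected_joint_loglik(params, obs, post, X, S, R)
    if (!is.finite(ll))
      stop(sprintf("non-finite joint log-likelihood at iteration %d", it),
           call. = FALSE)
    # the Laplace/bit-flip E-step is approximate, so percent-level
    # likelihood dips can occur; only large drops indicate divergence
    if (is.finite(ll_prev) && ll < ll_prev - drop_abort * max(1, abs(ll_prev)))
      stop(sprintf(
        "expected joint log-likelihood dropped %.3g -> %.3g at iteration %d",
        ll_prev, ll, it), call. = FALSE)
    trace <- c(trace, ll)
    stats <- accumulate_stats(post, obs, X, S, R)
    if (update_B || update_gamma || !is.null(obs$J)) {
      # nuisance coefficients J stay free even when B/Gamma are frozen
      up <- update_obs_params(stats,
                              B_fixed = if (update_B) NULL else obs$B)
      if (update_B) obs$B <- up$B
      if (!is.null(up$J)) obs$J <- up$J
      if (update_gamma) obs$Gamma <- up$Gamma
    }
    lat <- update_latent_params(stats, lambda = lambda, update_sigma = FALSE)
    params <- plrnn_params(A = lat$A, W = lat$W, h = lat$h, mu0 = lat$mu0,
                           Sigma = rep(fixed_sigma, M), C = lat$C,
                           linear = params$linear)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) < tol * max(1, abs(ll))) break
    ll_prev <- ll
  }
  list(params = params, obs = obs, post = post, trace = trace,
       z_last = z_init)
}

.as_fit <- function(params, obs, post, traces, config, protocol, seed) {
  stab_T <- min(config$stability_T, 10000)
  Zfree <- plrnn_generate(params, stab_T, seed = seed, noise = TRUE)
  structure(list(params = params, obs = obs, posterior = post,
                 loglik_trace = traces,
                 unstable = isTRUE(attr(Zfree, "unstable")),
                 provenance = list(protocol = protocol, config = config,
                                   seed = seed,
                                   package_version =
                                     as.character(utils::packageVersion("plrnnssm")))),
            class = "plrnn_fit")
}

#' @export
print.plrnn_fit <- function(x, ...) {
  cat(sprintf("PLRNN fit (%s): M = %d%s%s\n",
              x$provenance$protocol, length(x$params$A),
              if (x$params$linear) ", linear" else "",
              if (x$unstable) ", GLOBALLY UNSTABLE" else ""))
  ll <- x$loglik_trace[[length(x$loglik_trace)]]
  cat(sprintf("  final expected joint log-lik: %.2f\n", ll[length(ll)]))
  invisible(x)
}

# Re-estimate the posterior covariance with Sigma = I (final protocol
# step); the MAP path is kept fixed.
.final_posterior <- function(params, obs, X, S, R, z_init, max_flip_rounds) {
  p2 <- params
  p2$Sigma <- rep(1, length(params$A))
  estep(p2, obs, X, S, R, z_init = z_init, max_rounds = max_flip_rounds)
}

.get_xsr <- function(data) {
  if (inherits(data, "trajectory")) list(X = data$states, S = NULL, R = NULL)
  else if (is.matrix(data)) list(X = data, S = NULL, R = NULL)
  else list(X = as.matrix(data$X),
            S = if (!is.null(data$S)) as.matrix(data$S) else NULL,
            R = if (!is.null(data$R)) as.matrix(data$R) else NULL)
}

.make_obs <- function(tmpl, obs_model, hrf, convolve_activation = FALSE) {
  if (obs_model == "gaussian") obs_gaussian(tmpl$B, tmpl$Gamma)
  else obs_bold(tmpl$B, tmpl$Gamma, hrf = hrf, J = tmpl$J,
                convolve_activation = convolve_activation)
}

#' Stepwise annealing training protocol
#'
#' Executes the full stepwise protocol: (0) random stable-biased
#' initialization; (1) LDS EM with \eqn{\Sigma = I} for initialization;
#' (2) PLRNN EM with \eqn{\Sigma = I}; (3) three PLRNN EM rounds with
#' \eqn{\Sigma} fixed at `diag(10^-i)` and `B` frozen at its step-2 value
#' (plus `Gamma` frozen in `fmri_mode`), each warm-started from the
#' previous estimate; (4) posterior covariance re-estimated with
#' \eqn{\Sigma = I}.  Early rounds let the decoder absorb the data; the
#' shrinking process noise then forces temporal consistency onto the
#' latent model, which is what makes the freely generated dynamics (not
#' just the smoothed states) match the underlying system.
#'
#' @param data a `trajectory`, a T x N matrix, or a list with elements
#'   `X` and optionally `S` (inputs) and `R` (nuisance).
#' @param config a [training_config()].
#' @param obs_model `"gaussian"` (default) or `"bold"`.
#' @param hrf kernel for the BOLD decoder (default
#'   `canonical_hrf(1)`); ignored for the Gaussian decoder.
#' @param convolve_activation passed to [obs_bold()].
#' @return a `plrnn_fit`: final parameters, observation model, final
#'   posterior (covariance re-estimated at \eqn{\Sigma = I}), per-round
#'   log-likelihood traces, global-stability flag, and provenance.
#' @export
train_annealed <- function(data, config, obs_model = c("gaussian", "bold"),
                           hrf = NULL, convolve_activation = FALSE) {
  obs_model <- match.arg(obs_model)
  d <- .get_xsr(data)
  X <- d$X
  K <- if (is.null(d$S)) 0L else ncol(d$S)
  P <- if (is.null(d$R)) 0L else ncol(d$R)
  if (obs_model == "bold" && is.null(hrf)) hrf <- canonical_hrf(1)
  init <- init_random(config$M, ncol(X), K, P, seed = config$seed)
  obs <- .make_obs(init$obs_template, obs_model, hrf, convolve_activation)
  lv <- config$anneal_sigma_levels
  traces <- list()

  # step 1: LDS initialization at Sigma = lv[1]
  p <- init$params; p$linear <- TRUE
  r <- em_round(X, d$S, d$R, p, obs, fixed_sigma = lv[1],
                lambda = config$lambda_reg,
                max_iter = config$em_max_iter, tol = config$em_tol,
                max_flip_rounds = config$max_flip_rounds,
                drop_abort = config$em_drop_abort)
  traces$lds_init <- r$trace
  # step 2: PLRNN at Sigma = lv[1]
  p <- r$params; p$linear <- FALSE
  r <- em_round(X, d$S, d$R, p, r$obs, fixed_sigma = lv[1],
                lambda = config$lambda_reg,
                max_iter = config$em_max_iter, tol = config$em_tol,
                max_flip_rounds = config$max_flip_rounds,
                z_init = r$z_last, drop_abort = config$em_drop_abort)
  traces$plrnn_sigma1 <- r$trace
  # step 3: annealing rounds with frozen decoder loadings
  step_idx <- 2L
  for (sig in lv[-1]) {
    step_idx <- step_idx + 1L
    freeze <- step_idx >= config$fix_obs_from_step
    r <- em_round(X, d$S, d$R, r$params, r$obs, fixed_sigma = sig,
                  update_B = !freeze,
                  update_gamma = !(freeze && config$fmri_mode),
                  lambda = config$lambda_reg,
                  max_iter = config$em_max_iter, tol = config$em_tol,
                  max_flip_rounds = config$max_flip_rounds,
                  z_init = r$z_last, drop_abort = config$em_drop_abort)
    traces[[sprintf("anneal_sigma_%g", sig)]] <- r$trace
  }
  post <- .final_posterior(r$params, r$obs, X, d$S, d$R, r$z_last,
                           config$max_flip_rounds)
  .as_fit(r$params, r$obs, post, traces, config, "anneal", config$seed)
}

#' Plain randomly initialized EM baseline
#'
#' A single PLRNN EM run from the random initialization with the process
#' noise directly fixed at `config$random_sigma` — the stepwise protocol
#' reduced to its first PLRNN round at the final noise level.
#'
#' @inheritParams train_annealed
#' @return a `plrnn_fit`.
#' @export
train_random <- function(data, config, obs_model = c("gaussian", "bold"),
                         hrf = NULL, convolve_activation = FALSE) {
  obs_model <- match.arg(obs_model)
  d <- .get_xsr(data)
  X <- d$X
  K <- if (is.null(d$S)) 0L else ncol(d$S)
  P <- if (is.null(d$R)) 0L else ncol(d$R)
  if (obs_model == "bold" && is.null(hrf)) hrf <- canonical_hrf(1)
  init <- init_random(config$M, ncol(X), K, P, seed = config$seed)
  obs <- .make_obs(init$obs_template, obs_model, hrf, convolve_activation)
  r <- em_round(X, d$S, d$R, init$params, obs,
                fixed_sigma = config$random_sigma,
                lambda = config$lambda_reg,
                max_iter = config$em_max_iter, tol = config$em_tol,
                max_flip_rounds = config$max_flip_rounds,
                drop_abort = config$em_drop_abort)
  post <- .final_posterior(r$params, r$obs, X, d$S, d$R, r$z_last,
                           config$max_flip_rounds)
  .as_fit(r$params, r$obs, post, list(plrnn_random = r$trace), config,
          "random", config$seed)
}

#' Linear (LDS) variant of the stepwise protocol
#'
#' Runs the identical stepwise protocol with the identity transfer
#' function throughout — the baseline that is mathematically incapable of
#' sustained limit cycles or chaos.
#'
#' @inheritParams train_annealed
#' @return a `plrnn_fit` with `params$linear = TRUE`.
#' @export
train_lds <- function(data, config, obs_model = c("gaussian", "bold"),
                      hrf = NULL, convolve_activation = FALSE) {
  obs_model <- match.arg(obs_model)
  d <- .get_xsr(data)
  X <- d$X
  K <- if (is.null(d$S)) 0L else ncol(d$S)
  P <- if (is.null(d$R)) 0L else ncol(d$R)
  if (obs_model == "bold" && is.null(hrf)) hrf <- canonical_hrf(1)
  init <- init_random(config$M, ncol(X), K, P, seed = config$seed,
                      linear = TRUE)
  obs <- .make_obs(init$obs_template, obs_model, hrf, convolve_activation)
  lv <- config$anneal_sigma_levels
  traces <- list()
  r <- em_round(X, d$S, d$R, init$params, obs, fixed_sigma = lv[1],
                lambda = config$lambda_reg,
                max_iter = config$em_max_iter, tol = config$em_tol,
                max_flip_rounds = config$max_flip_rounds,
                drop_abort = config$em_drop_abort)
  traces$lds_init <- r$trace
  r <- em_round(X, d$S, d$R, r$params, r$obs, fixed_sigma = lv[1],
                lambda = config$lambda_reg,
                max_iter = config$em_max_iter, tol = config$em_tol,
                max_flip_rounds = config$max_flip_rounds, z_init = r$z_last,
                drop_abort = config$em_drop_abort)
  traces$lds_sigma1 <- r$trace
  step_idx <- 2L
  for (sig in lv[-1]) {
    step_idx <- step_idx + 1L
    freeze <- step_idx >= config$fix_obs_from_step
    r <- em_round(X, d$S, d$R, r$params, r$obs, fixed_sigma = sig,
                  update_B = !freeze,
                  update_gamma = !(freeze && config$fmri_mode),
                  lambda = config$lambda_reg,
                  max_iter = config$em_max_iter, tol = config$em_tol,
                  max_flip_rounds = config$max_flip_rounds,
                  z_init = r$z_last, drop_abort = config$em_drop_abort)
    traces[[sprintf("anneal_sigma_%g", sig)]] <- r$trace
  }
  post <- .final_posterior(r$params, r$obs, X, d$S, d$R, r$z_last,
                           config$max_flip_rounds)
  .as_fit(r$params, r$obs, post, traces, config, "lds", config$seed)
}
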