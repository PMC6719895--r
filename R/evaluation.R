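# Reconstruction-quality measures.
#
# The central question after training is whether the *freely generated*
# dynamics — not the data-constrained smoothed states — occupy the same
# region of state space as the true system.  That is quantified by KL
# divergences taken across space (not time): KL_x on a binned observation
# space against the ground truth where it is known, and KL_z between the
# inferred posterior state mixture and the free-running prior mixture
# where it is not.

#' Histogram specification for the binned state-space measure
#'
#' @param bin_width bin width per dimension (default 1, in standardized
#'   units).
#' @param range common per-dimension range (default `c(-4, 4)`).
#' @param alpha Laplace smoothing constant (default 1e-6).
#' @param D dimensionality of the space.
#' @return list of class `histogram_spec` with derived total bin count
#'   `K`.
#' @export
histogram_spec <- function(D, bin_width = 1, range = c(-4, 4),
                           alpha = 1e-6) {
  .assert(bin_width > 0, "bin_width must be positive")
  .assert(alpha >= 0, "alpha must be >= 0")
  .assert(all(is.finite(range)) && diff(range) > 0, "invalid range")
  edges <- seq(range[1], range[2], by = bin_width)
  if (edges[length(edges)] < range[2]) edges <- c(edges, range[2])
  nb <- length(edges) - 1L
  structure(list(D = D, bin_width = bin_width, range = range,
                 alpha = alpha, edges = edges, nbins = nb, K = nb^D),
            class = "histogram_spec")
}

#' Binned state-space occupancy with Laplace smoothing
#'
#' Counts points over the regular grid of `spec` (out-of-range points are
#' clipped to the edge bins so both compared distributions stay
#' normalized over the same support) and returns the additively smoothed
#' probabilities \eqn{\hat p^{(k)} = (n^{(k)} + \alpha)/(T + \alpha K)}.
#'
#' @param points T x D matrix of (standardized) states.
#' @param spec a [histogram_spec()].
#' @return probability vector of length `spec$K` summing to 1, with the
#'   sample size in attribute `"T"`.
#' @export
histogram_states <- function(points, spec) {
  points <- as.matrix(points)
  .assert(nrow(points) >= 1, "empty point set")
  .assert(ncol(points) == spec$D, "dimension mismatch with spec")
  .assert(all(is.finite(points)), "non-finite points")
  nb <- spec$nbins
  idx <- rep(0L, nrow(points))
  for (d in seq_len(spec$D)) {
    bd <- findInterval(points[, d], spec$edges, rightmost.closed = TRUE)
    bd <- pmin(pmax(bd, 1L), nb)
    idx <- idx * nb + (bd - 1L)
  }
  n <- tabulate(idx + 1L, nbins = spec$K)
  T <- nrow(points)
  p <- (n + spec$alpha) / (T + spec$alpha * spec$K)
  attr(p, "T") <- T
  p
}

#' State-space KL divergence between binned occupancies
#'
#' Computes \eqn{KL = \sum_k \hat p_{true}^{(k)}
#' \log(\hat p_{true}^{(k)} / \hat p_{gen}^{(k)})} and its normalized
#' version \eqn{\widetilde{KL}_x = KL / KL_{max} \in [0, 1]}, where
#' \eqn{KL_{max} = \sum_k \hat p_{true}^{(k)} \log(\hat p_{true}^{(k)} /
#' p_{floor})} with \eqn{p_{floor} = \alpha/(T_{gen} + \alpha K)} is the
#' divergence attained when the generated mass shares no occupied bin
#' with the truth (fully disjoint supports give exactly 1).
#'
#' @param p_true,p_gen smoothed probability vectors from
#'   [histogram_states()] built with the same `spec`.
#' @param spec the common [histogram_spec()].
#' @return list with `raw` (nats) and `normalized` (clipped to
#'   `[0, 1]`).
#' @export
kl_x <- function(p_true, p_gen, spec) {
  .assert(length(p_true) == spec$K && length(p_gen) == spec$K,
          "probability vectors do not match spec")
  pos <- p_true > 0
  raw <- sum(p_true[pos] * log(p_true[pos] / p_gen[pos]))
  T_gen <- attr(p_gen, "T")
  .assert(!is.null(T_gen), "p_gen lacks sample-size attribute")
  p_floor <- spec$alpha / (T_gen + spec$alpha * spec$K)
  kl_max <- sum(p_true[pos] * log(p_true[pos] / p_floor))
  list(raw = raw, normalized = min(max(raw / kl_max, 0), 1))
}

#' Normalized KL between trajectories in observation space
#'
#' Convenience wrapper: histograms the two point sets under a common spec
#' and returns [kl_x()].
#'
#' @param true_states,gen_states matrices of standardized points.
#' @param spec optional [histogram_spec()] (defaults to bin width 1 on
#'   `[-4, 4]`).
#' @return as [kl_x()].
#' @export
kl_x_trajectories <- function(true_states, gen_states, spec = NULL) {
  true_states <- as.matrix(true_states)
  if (is.null(spec)) spec <- histogram_spec(ncol(true_states))
  kl_x(histogram_states(true_states, spec),
       histogram_states(gen_states, spec), spec)
}

# ---- Gaussian mixtures over time -------------------------------------------

#' Gaussian mixture across trajectory time points
#'
#' Equal-weight mixture with one Gaussian component per time point, the
#' spatial approximation used for latent-space KL measures.
#'
#' @param means T x M matrix of component means.
#' @param covs M x M x T array of component covariances.
#' @param side `"inferred"`, `"generated"` or `"reference"`.
#' @return object of class `gaussian_mixture`.
#' @export
gaussian_mixture <- function(means, covs,
                             side = c("inferred", "generated", "reference")) {
  side <- match.arg(side)
  means <- as.matrix(means)
  .assert(length(dim(covs)) == 3 && dim(covs)[3] == nrow(means),
          "covs must be M x M x T")
  structure(list(means = means, covs = covs, side = side,
                 T = nrow(means), M = ncol(means)),
            class = "gaussian_mixture")
}

#' Posterior ("inferred") state mixture of a fit
#'
#' Mixture of the per-time marginal posteriors \eqn{p(z_t | x_{1:T})}
#' from the final posterior (whose covariance was re-estimated at
#' \eqn{\Sigma = I}); marginal variances are floored at `var_floor`
#' (default 1, required to keep the divergence well defined).
#'
#' @param fit a `plrnn_fit`.
#' @param var_floor minimum marginal variance (default 1).
#' @return a `gaussian_mixture`, side `"inferred"`.
#' @export
posterior_mixture <- function(fit, var_floor = 1) {
  z <- fit$posterior$z
  covs <- fit$posterior$Vtt
  M <- ncol(z)
  for (t in seq_len(dim(covs)[3])) {
    Ct_ <- matrix(covs[, , t], M, M)
    dg <- diag(Ct_)
    covs[, , t] <- Ct_ + diag(pmax(var_floor - dg, 0), M)
  }
  gaussian_mixture(z, covs, side = "inferred")
}

#' Free-running ("generated") state mixture
#'
#' Simulates the trained latent model freely for `T_gen` steps and forms
#' the mixture of one-step predictive distributions
#' \eqn{p(z_t | z_{t-1}) = N(A z_{t-1} + W\phi(z_{t-1}) + h, \Sigma)}
#' along the generated path.
#'
#' @param params a [plrnn_params()] object.
#' @param T_gen number of free-running components (default 1000).
#' @param seed RNG seed for the generation.
#' @param burn initial steps discarded (default 100).
#' @return a `gaussian_mixture`, side `"generated"`, or `NULL` if the
#'   free run is globally unstable.
#' @export
generated_mixture <- function(params, T_gen = 1000, seed = 1, burn = 100) {
  Z <- plrnn_generate(params, T_gen + burn + 1L, seed = seed, noise = TRUE)
  if (isTRUE(attr(Z, "unstable"))) return(NULL)
  Zprev <- Z[(burn + 1):(burn + T_gen), , drop = FALSE]
  M <- ncol(Z)
  means <- t(apply(Zprev, 1, function(z) latent_step(params, z)))
  if (M == 1) means <- matrix(means, ncol = 1)
  covs <- array(diag(params$Sigma, M), c(M, M, T_gen))
  gaussian_mixture(means, covs, side = "generated")
}

# per-component Cholesky factors and log-determinants
.mix_chol <- function(mix) {
  T <- mix$T
  lapply(seq_len(T), function(t) {
    S <- (mix$covs[, , t] + t(mix$covs[, , t])) / 2
    ch <- tryCatch(chol(S), error = function(e)
      chol(S + diag(1e-8, nrow(S))))
    ch
  })
}

# log density of every row of Z under the mixture (equal weights)
.mix_logdens <- function(mix, Z) {
  Z <- as.matrix(Z)
  n <- nrow(Z); M <- mix$M
  chs <- .mix_chol(mix)
  lw <- -log(mix$T)
  comp <- matrix(NA_real_, n, mix$T)
  for (t in seq_len(mix$T)) {
    ch <- chs[[t]]
    D <- sweep(Z, 2, mix$means[t, ])
    Y <- backsolve(ch, t(D), transpose = TRUE)     # solves t(ch) y = d
    q <- colSums(Y^2)
    comp[, t] <- -0.5 * q - sum(log(diag(ch))) - 0.5 * M * log(2 * pi)
  }
  apply(comp, 1, function(r) logsumexp(r + lw))
}

#' Monte-Carlo estimate of the latent-space KL divergence
#'
#' Draws `n_samples` from the inferred mixture and averages the
#' log-density ratio against the generated mixture.
#'
#' @param p_inf,p_gen `gaussian_mixture` objects (inferred / generated).
#' @param n_samples number of MC samples (default 10000; the estimator
#'   is unbiased for any n, use more for tight estimates).
#' @param seed RNG seed.
#' @return scalar KL estimate (nats) with attribute `"se"` (MC standard
#'   error).
#' @export
kl_z_mc <- function(p_inf, p_gen, n_samples = 10000, seed = 1) {
  .assert(p_inf$M == p_gen$M, "mixture dimension mismatch")
  draws <- with_seed(seed, {
    comp <- sample.int(p_inf$T, n_samples, replace = TRUE)
    E <- matrix(rnorm(n_samples * p_inf$M), n_samples)
    t(vapply(seq_len(n_samples), function(i) {
      t <- comp[i]
      ch <- tryCatch(chol(p_inf$covs[, , t]), error = function(e)
        chol(p_inf$covs[, , t] + diag(1e-8, p_inf$M)))
      p_inf$means[t, ] + drop(crossprod(ch, E[i, ]))
    }, numeric(p_inf$M)))
  })
  if (p_inf$M == 1) draws <- matrix(draws, ncol = 1)
  lr <- .mix_logdens(p_inf, draws) - .mix_logdens(p_gen, draws)
  est <- mean(lr)
  attr(est, "se") <- sd(lr) / sqrt(n_samples)
  est
}

# matrix of pairwise Gaussian KLs: KL(p_t || q_k), rows t (components of
# `from`), cols k (components of `to`)
.pairwise_gauss_kl <- function(from, to) {
  M <- from$M
  Tf <- from$T; Tt <- to$T
  S0mat <- matrix(from$covs, M * M, Tf)          # vectorized covariances
  ld0 <- vapply(seq_len(Tf), function(t)
    determinant(matrix(from$covs[, , t], M, M), logarithm = TRUE)$modulus, 0)
  out <- matrix(NA_real_, Tf, Tt)
  for (k in seq_len(Tt)) {
    Sk <- (matrix(to$covs[, , k], M, M) + t(matrix(to$covs[, , k], M, M))) / 2
    ch <- tryCatch(chol(Sk), error = function(e) chol(Sk + diag(1e-8, M)))
    Ski <- chol2inv(ch)
    ldk <- 2 * sum(log(diag(ch)))
    tr <- colSums(as.numeric(Ski) * S0mat)
    D <- sweep(from$means, 2, to$means[k, ])
    q <- rowSums((D %*% Ski) * D)
    out[, k] <- 0.5 * (tr + q - M + ldk - ld0)
  }
  out
}

#' Variational approximation of the latent-space KL divergence
#'
#' Deterministic approximation of the mixture KL built from pairwise
#' Gaussian KLs (log-sum-exp stabilized):
#' \deqn{KL \approx \frac1T \sum_t \log
#'   \frac{\sum_j e^{-KL(p_t, p_j)}}{\sum_k e^{-KL(p_t, q_k)}}.}
#'
#' @param p_inf,p_gen `gaussian_mixture` objects.
#' @return scalar KL approximation (nats), clipped below at 0.
#' @export
kl_z_variational <- function(p_inf, p_gen) {
  .assert(p_inf$M == p_gen$M, "mixture dimension mismatch")
  Kii <- .pairwise_gauss_kl(p_inf, p_inf)
  Kig <- .pairwise_gauss_kl(p_inf, p_gen)
  num <- apply(-Kii, 1, logsumexp) - log(p_inf$T)
  den <- apply(-Kig, 1, logsumexp) - log(p_gen$T)
  max(mean(num - den), 0)
}

#' Normalized latent-space KL divergence
#'
#' \eqn{\widetilde{KL}_z = KL(p_{inf}, p_{gen}) / KL(p_{inf}, p_{ref})}
#' where the reference \eqn{p_{ref}} is the single Gaussian with the
#' time-averaged generated means and covariances — a structureless blob
#' at the same average location, destroying all information about the
#' trajectory flow.  Clipped to `[0, 1]`.
#'
#' @param p_inf,p_gen `gaussian_mixture` objects.
#' @param estimator `"variational"` (default, deterministic) or `"mc"`.
#' @param ... passed to [kl_z_mc()] when `estimator = "mc"`.
#' @return scalar in `[0, 1]`, `NA` (with a warning) when the reference
#'   divergence is degenerate.
#' @export
kl_z_normalized <- function(p_inf, p_gen, estimator = c("variational", "mc"),
                            ...) {
  estimator <- match.arg(estimator)
  M <- p_gen$M
  mref <- colMeans(p_gen$means)
  Sref <- rowMeans(p_gen$covs, dims = 2)
  p_ref <- gaussian_mixture(matrix(mref, 1), array(Sref, c(M, M, 1)),
                            side = "reference")
  f <- if (estimator == "variational") kl_z_variational else
    function(a, b) as.numeric(kl_z_mc(a, b, ...))
  num <- f(p_inf, p_gen)
  den <- f(p_inf, p_ref)
  if (!is.finite(den) || den < 1e-12) {
    warning("degenerate reference divergence; normalized KL undefined")
    return(NA_real_)
  }
  min(max(num / den, 0), 1)
}

#' n-step-ahead prediction error
#'
#' From each origin time the latent model is run deterministically
#' `horizon` steps starting at the inferred state, predictions are mapped
#' through the observation model, and squared errors against the true
#' observations are averaged over origins and channels per step.
#'
#' @param fit a `plrnn_fit`.
#' @param data data as passed to training.
#' @param horizon number of ahead-prediction steps.
#' @param origin_stride evaluate every `origin_stride`-th origin
#'   (default 1).
#' @return numeric vector of length `horizon` (MSE per step).
#' @export
n_step_mse <- function(fit, data, horizon, origin_stride = 1) {
  d <- .get_xsr(data)
  X <- d$X
  T <- nrow(X)
  .assert(horizon < T, "horizon exceeds series length")
  params <- fit$params
  obs <- fit$obs
  zpath <- fit$posterior$z
  L <- if (inherits(obs, "obs_bold")) length(obs$hrf) else 1L
  origins <- seq(1L, T - horizon, by = origin_stride)
  se <- matrix(0, length(origins), horizon)
  for (oi in seq_along(origins)) {
    t0 <- origins[oi]
    z <- zpath[t0, ]
    Zw <- zpath[max(1, t0 - L + 1):t0, , drop = FALSE]  # history for conv
    for (n in seq_len(horizon)) {
      s_t <- if (!is.null(params$C) && !is.null(d$S)) d$S[t0 + n, ] else NULL
      z <- latent_step(params, z, s_t)
      Zw <- rbind(Zw, z)
      xhat <- if (inherits(obs, "obs_gaussian")) {
        drop(obs$B %*% relu(z, params$linear))
      } else {
        Zin <- if (obs$convolve_activation) relu(Zw, params$linear) else Zw
        nw <- nrow(Zin)
        k <- obs$hrf[seq_len(min(L, nw))]
        w <- drop(t(Zin[nw:(nw - length(k) + 1L), , drop = FALSE]) %*% k)
        xh <- drop(obs$B %*% w)
        if (!is.null(obs$J)) xh <- xh + drop(obs$J %*% d$R[t0 + n, ])
        xh
      }
      se[oi, n] <- mean((X[t0 + n, ] - xhat)^2)
    }
  }
  colMeans(se)
}

#' Average power-spectrum correlation between two trajectories
#'
#' Per matched dimension, smoothed periodogram power spectra are computed
#' (detrended, demeaned) on the common length, and the Pearson
#' correlations between the spectra are averaged across dimensions.
#'
#' @param traj_a,traj_b matrices (or `trajectory` objects) with matching
#'   column counts and sampling rate.
#' @param spans smoothing spans passed to [stats::spec.pgram()].
#' @return average Pearson correlation.
#' @export
spectrum_correlation <- function(traj_a, traj_b, spans = c(5, 5)) {
  A <- if (inherits(traj_a, "trajectory")) traj_a$states else as.matrix(traj_a)
  B <- if (inherits(traj_b, "trajectory")) traj_b$states else as.matrix(traj_b)
  .assert(ncol(A) == ncol(B), "dimension mismatch")
  n <- min(nrow(A), nrow(B))
  .assert(n >= 64, "need at least 64 samples")
  A <- A[seq_len(n), , drop = FALSE]; B <- B[seq_len(n), , drop = FALSE]
  rs <- vapply(seq_len(ncol(A)), function(j) {
    sa <- stats::spec.pgram(A[, j], spans = spans, detrend = TRUE,
                            plot = FALSE, taper = 0.1)
    sb <- stats::spec.pgram(B[, j], spans = spans, detrend = TRUE,
                            plot = FALSE, taper = 0.1)
    suppressWarnings(cor(sa$spec, sb$spec))
  }, 0)
  mean(rs, na.rm = TRUE)
}

#' Characteristic frequencies of a block task design
#'
#' For a repeating sequence of `n_tasks` tasks, each consisting of a
#' resting and a task block, the design has two marker frequencies: one
#' full task-sequence cycle (`n_tasks * (task_s + rest_s)` seconds) and
#' one task-plus-rest block (`task_s + rest_s` seconds).  With the
#' default 36 s blocks and 3 tasks these are 1/216 s = 0.0046 Hz and
#' 1/72 s = 0.0139 Hz.
#'
#' @param task_s task block duration in seconds (default 36).
#' @param rest_s resting block duration in seconds (default 36).
#' @param n_tasks number of tasks per sequence (default 3).
#' @return named vector `c(sequence = ..., block = ...)` in Hz.
#' @export
task_block_frequencies <- function(task_s = 36, rest_s = 36, n_tasks = 3) {
  block <- task_s + rest_s
  c(sequence = 1 / (n_tasks * block), block = 1 / block)
}
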