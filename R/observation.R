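#' Canonical double-gamma hemodynamic response kernel
#'
#' The BOLD observation model convolves latent activity with a hemodynamic
#' response function (HRF).  The kernel here is the standard double-gamma
#' form: a response gamma density peaking around 5 s minus an undershoot
#' gamma peaking around 15 s scaled by `1/ratio`, sampled at the data's
#' sampling interval over `duration` seconds and normalized to peak 1.
#' A `duration` of one sample yields the delta kernel `1`, under which
#' convolution is the identity.
#'
#' @param sampling_interval sampling interval (s), e.g. the fMRI TR.
#' @param duration kernel length in seconds (default 32).
#' @param peak1,peak2 gamma shape parameters of response and undershoot
#'   (rate 1), defaults 6 and 16 (modes at 5 s and 15 s).
#' @param ratio response/undershoot amplitude ratio (default 6).
#' @return numeric kernel, lag 0 first, peak value 1.
#' @export
canonical_hrf <- function(sampling_interval, duration = 32,
                          peak1 = 6, peak2 = 16, ratio = 6) {
  .assert(sampling_interval > 0, "sampling_interval must be positive")
  .assert(duration >= sampling_interval,
          "duration must cover at least one sample")
  tt <- seq(0, duration - sampling_interval / 2, by = sampling_interval)
  if (length(tt) == 1L) return(1)
  k <- stats::dgamma(tt, shape = peak1, rate = 1) -
    stats::dgamma(tt, shape = peak2, rate = 1) / ratio
  k / max(k)
}

#' Causal convolution of a state matrix with a kernel
#'
#' Convolves each column of `Z` with `kernel`, truncating the sum at the
#' first sample (zero padding before t = 1):
#' \eqn{w_t = \sum_{l=0}^{L-1} k_l z_{t-l}}.
#'
#' @param Z T x M matrix.
#' @param kernel numeric kernel (lag 0 first).
#' @return T x M matrix of convolved states.
#' @export
hrf_convolve <- function(Z, kernel) {
  Z <- as.matrix(Z)
  L <- length(kernel)
  if (L == 1L) return(Z * kernel)
  T <- nrow(Z)
  out <- Z * kernel[1]
  for (l in seq_len(min(L - 1L, T - 1L))) {
    out[(l + 1):T, ] <- out[(l + 1):T, ] + kernel[l + 1] * Z[1:(T - l), , drop = FALSE]
  }
  out
}

#' Sparse stacked HRF convolution operator
#'
#' Builds the block-banded linear map \eqn{H} acting on the stacked state
#' vector \eqn{z = (z_{11},\dots,z_{M1},\dots,z_{1T},\dots,z_{MT})^T}
#' (time-major, M entries per time point) such that \eqn{Hz} equals the
#' per-coordinate causal convolution of [hrf_convolve()].  \eqn{H} is
#' strictly causal and lower block-banded with bandwidth equal to the
#' kernel length.
#'
#' @param T number of time points.
#' @param M number of latent states.
#' @param kernel numeric kernel (lag 0 first).
#' @return a sparse `Matrix` of dimension MT x MT.
#' @export
build_hrf_operator <- function(T, M, kernel) {
  L <- length(kernel)
  lags <- seq_len(min(L, T)) - 1L
  blocks <- lapply(lags, function(l) {
    # T x T shift-by-l matrix scaled by kernel[l+1]
    if (kernel[l + 1] == 0) return(NULL)
    Matrix::bandSparse(T, T, k = -l, diagonals = list(rep(kernel[l + 1], T - l)))
  })
  blocks <- Filter(Negate(is.null), blocks)
  if (!length(blocks)) return(Matrix::Matrix(0, T * M, T * M, sparse = TRUE))
  Tm <- Reduce(`+`, blocks)
  Matrix::kronecker(Tm, Matrix::Diagonal(M))
}

#' Map latent states to observations
#'
#' Applies the observation ("decoder") model: for the Gaussian variant
#' \eqn{x_t = B\phi(z_t) + \eta_t}; for the BOLD variant
#' \eqn{x_t = B(\mathrm{hrf} * z)_t + J r_t + \eta_t} (raw states are
#' convolved unless the model was built with `convolve_activation`).
#'
#' @param obs an [obs_gaussian()] or [obs_bold()] object.
#' @param Z T x M latent state matrix.
#' @param R optional T x P nuisance matrix (BOLD variant).
#' @param noise logical; add observation noise \eqn{N(0,\Gamma)}.
#' @param seed optional RNG seed for the noise draw.
#' @param linear logical; treat \eqn{\phi} as identity (LDS variant) in
#'   the Gaussian decoder.
#' @return T x N observation matrix.
#' @export
emit <- function(obs, Z, R = NULL, noise = FALSE, seed = NULL,
                 linear = FALSE) {
  Z <- as.matrix(Z)
  T <- nrow(Z)
  .assert(ncol(Z) == ncol(obs$B), "Z has wrong number of columns")
  X <- if (inherits(obs, "obs_gaussian")) {
    relu(Z, linear) %*% t(obs$B)
  } else if (inherits(obs, "obs_bold")) {
    Zin <- if (obs$convolve_activation) relu(Z, linear) else Z
    Xc <- hrf_convolve(Zin, obs$hrf) %*% t(obs$B)
    if (!is.null(obs$J)) {
      .assert(!is.null(R), "BOLD model with nuisance coefficients needs R")
      R <- as.matrix(R)
      .assert(nrow(R) == T && ncol(R) == ncol(obs$J), "R has wrong shape")
      Xc <- Xc + R %*% t(obs$J)
    }
    Xc
  } else stop("unknown observation model class")
  if (noise) {
    eta <- function() matrix(rnorm(T * length(obs$Gamma)), T) %*%
      diag(sqrt(obs$Gamma), length(obs$Gamma))
    X <- X + if (is.null(seed)) eta() else with_seed(seed, eta())
  }
  X
}
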