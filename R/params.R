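#' Latent PLRNN parameter set
#'
#' Container for the parameters of the latent piecewise-linear recurrent
#' neural network process
#' \deqn{z_t = A z_{t-1} + W \phi(z_{t-1}) + h + C s_t + \epsilon_t,
#'       \quad \epsilon_t \sim N(0, \Sigma),}
#' with \eqn{\phi(z) = \max(z, 0)} applied elementwise, \eqn{A} diagonal
#' (auto-regression weights), \eqn{W} off-diagonal (coupling weights),
#' \eqn{h} a bias, \eqn{C} the input loading, and diagonal process noise
#' covariance \eqn{\Sigma}.  The initial state is
#' \eqn{z_1 \sim N(\mu_0 + C s_1, \Sigma)}.  With `linear = TRUE` the
#' nonlinearity is replaced by the identity, giving a linear dynamical
#' system (LDS) with the same parametrization.
#'
#' @param A numeric M-vector of diagonal auto-regression weights.
#' @param W M x M coupling matrix; its diagonal must be (and is stored as)
#'   exactly zero.
#' @param h numeric M-vector of biases.
#' @param mu0 numeric M-vector, initial-state mean.
#' @param Sigma numeric M-vector of diagonal process-noise variances
#'   (strictly positive).
#' @param C optional M x K input-weight matrix (`NULL` for autonomous
#'   models).
#' @param linear logical; if `TRUE` the transfer function is the identity
#'   (LDS variant) rather than the ReLU.
#' @return an object of class `plrnn_params`.
#' @export
plrnn_params <- function(A, W, h, mu0 = rep(0, length(A)),
                         Sigma = rep(1, length(A)), C = NULL,
                         linear = FALSE) {
  M <- length(A)
  W <- as.matrix(W)
  .assert(all(dim(W) == c(M, M)), "W must be M x M")
  .assert(max(abs(diag(W))) == 0, "diag(W) must be exactly zero")
  .assert(length(h) == M && length(mu0) == M && length(Sigma) == M,
          "h, mu0, Sigma must have length M")
  .assert(all(Sigma > 0), "Sigma must be strictly positive")
  if (!is.null(C)) {
    C <- as.matrix(C)
    .assert(nrow(C) == M, "C must have M rows")
  }
  .assert(all(is.finite(c(A, W, h, mu0, Sigma, C))), "non-finite parameter")
  structure(list(A = as.numeric(A), W = W, h = as.numeric(h),
                 mu0 = as.numeric(mu0), Sigma = as.numeric(Sigma),
                 C = C, linear = isTRUE(linear)),
            class = "plrnn_params")
}

#' @export
print.plrnn_params <- function(x, ...) {
  M <- length(x$A)
  K <- if (is.null(x$C)) 0L else ncol(x$C)
  cat(sprintf("PLRNN latent model: M = %d states, K = %d inputs%s\n",
              M, K, if (x$linear) " (linear/LDS variant)" else ""))
  cat(sprintf("  spectral radius of A + W: %.3f\n",
              max(abs(eigen(diag(x$A, M) + x$W, only.values = TRUE)$values))))
  invisible(x)
}

#' Gaussian observation model parameters
#'
#' Parameters of the linear-Gaussian decoder
#' \eqn{x_t = B \phi(z_t) + \eta_t}, \eqn{\eta_t \sim N(0, \Gamma)} with
#' diagonal \eqn{\Gamma}.
#'
#' @param B N x M loading matrix.
#' @param Gamma numeric N-vector of diagonal observation-noise variances.
#' @return object of class `obs_gaussian`.
#' @export
obs_gaussian <- function(B, Gamma) {
  B <- as.matrix(B)
  .assert(length(Gamma) == nrow(B), "Gamma must have length N = nrow(B)")
  .assert(all(Gamma > 0), "Gamma must be strictly positive")
  structure(list(B = B, Gamma = as.numeric(Gamma)), class = "obs_gaussian")
}

#' BOLD (HRF-convolved) observation model parameters
#'
#' Parameters of the fMRI-type decoder
#' \eqn{x_t = B\,(\mathrm{hrf} * z)_t + J r_t + \eta_t},
#' \eqn{\eta_t \sim N(0,\Gamma)}: each latent coordinate's time series is
#' causally convolved with a hemodynamic response kernel before entering a
#' general-linear-model-style observation equation with nuisance regressors
#' \eqn{r_t}.  As printed in the model equations the *raw* states are
#' convolved (not the ReLU-transformed ones); set
#' `convolve_activation = TRUE` to convolve \eqn{\phi(z)} instead.
#'
#' @param B N x M loading matrix.
#' @param Gamma numeric N-vector of diagonal observation-noise variances.
#' @param hrf numeric kernel sampled at the data's sampling interval
#'   (lag 0 first); see [canonical_hrf()].
#' @param J optional N x P nuisance-coefficient matrix.
#' @param convolve_activation logical, default `FALSE` (convolve raw z).
#' @return object of class `obs_bold`.
#' @export
obs_bold <- function(B, Gamma, hrf, J = NULL, convolve_activation = FALSE) {
  B <- as.matrix(B)
  .assert(length(Gamma) == nrow(B), "Gamma must have length N = nrow(B)")
  .assert(all(Gamma > 0), "Gamma must be strictly positive")
  .assert(length(hrf) >= 1 && all(is.finite(hrf)), "hrf kernel must be finite")
  if (!is.null(J)) {
    J <- as.matrix(J)
    .assert(nrow(J) == nrow(B), "J must have N rows")
  }
  structure(list(B = B, Gamma = as.numeric(Gamma), hrf = as.numeric(hrf),
                 J = J, convolve_activation = isTRUE(convolve_activation)),
            class = "obs_bold")
}

#' @export
print.obs_gaussian <- function(x, ...) {
  cat(sprintf("Gaussian observation model: N = %d channels, M = %d states\n",
              nrow(x$B), ncol(x$B)))
  invisible(x)
}

#' @export
print.obs_bold <- function(x, ...) {
  cat(sprintf(
    "BOLD observation model: N = %d channels, M = %d states, kernel length %d, P = %d nuisance\n",
    nrow(x$B), ncol(x$B), length(x$hrf),
    if (is.null(x$J)) 0L else ncol(x$J)))
  invisible(x)
}

# ---- JSON (de)serialization -------------------------------------------------

.PARAM_SCHEMA_VERSION <- 1L

params_to_list <- function(p) {
  list(schema_version = .PARAM_SCHEMA_VERSION,
       M = length(p$A), K = if (is.null(p$C)) 0L else ncol(p$C),
       A = p$A, W = p$W, h = p$h, mu0 = p$mu0, Sigma = p$Sigma,
       C = p$C, linear = p$linear)
}

params_from_list <- function(l) {
  .assert(is.null(l$schema_version) || l$schema_version <= .PARAM_SCHEMA_VERSION,
          "model file written by a newer schema version")
  C <- if (is.null(l$C) || length(l$C) == 0) NULL else
    matrix(unlist(l$C), nrow = l$M)
  plrnn_params(A = unlist(l$A),
               W = matrix(unlist(l$W), nrow = l$M, byrow = is.list(l$W)),
               h = unlist(l$h), mu0 = unlist(l$mu0), Sigma = unlist(l$Sigma),
               C = C, linear = isTRUE(l$linear))
}

#' Write / read PLRNN parameters as JSON
#'
#' Arrays are stored row-major with explicit shapes via the `M`/`K` fields;
#' files are schema-versioned and full double precision is retained.
#'
#' @param params a [plrnn_params()] object.
#' @param path file path.
#' @return `read_params` returns a `plrnn_params` object.
#' @export
write_params <- function(params, path) {
  .assert(inherits(params, "plrnn_params"), "not a plrnn_params object")
  jsonlite::write_json(params_to_list(params), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  params_from_list(jsonlite::read_json(path, simplifyVector = TRUE))
}
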