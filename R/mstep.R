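# Closed-form M-step.
#
# Given the posterior expectations from the E-step, the expected joint
# log-density is quadratic in every parameter block, so all updates are
# (regularized) linear regressions: a stacked least-squares solve for the
# observation loadings [B J] and the observation noise Gamma, and
# independent row-wise solves for the latent parameters (the diagonal/
# off-diagonal split of A and W makes row-wise solves exact and cheap).

# Expected (convolved) design states for the observation equation:
#   Ew  - T x M, E[w_t] with w = phi(z) (Gaussian) or hrf * z (BOLD)
#   Eww - M x M x T, E[w_t w_t']
# For the BOLD model with raw-state convolution the second moments use
# the stored banded covariance blocks; cross-lag covariances beyond the
# stored bandwidth are truncated to zero.  For the (non-default)
# activation-convolution variant, cross-time covariances of phi(z) are
# not available in closed form and only same-time covariance terms are
# retained.
.bold_design_stats <- function(post, obs) {
  T <- nrow(post$z); M <- ncol(post$z)
  if (inherits(obs, "obs_gaussian")) {
    return(list(Ew = post$Ephi, Eww = post$Ephiphi))
  }
  k <- obs$hrf; L <- length(k)
  maxlag <- length(post$Clag)
  if (obs$convolve_activation) {
    Ew <- hrf_convolve(post$Ephi, k)
    Eww <- array(0, c(M, M, T))
    for (t in seq_len(T)) {
      acc <- tcrossprod(Ew[t, ])
      for (l in 0:(min(L, t) - 1L)) {
        Cv <- post$Ephiphi[, , t - l] - tcrossprod(post$Ephi[t - l, ])
        acc <- acc + k[l + 1]^2 * Cv
      }
      Eww[, , t] <- acc
    }
    return(list(Ew = Ew, Eww = Eww))
  }
  Ew <- hrf_convolve(post$z, k)
  Eww <- array(0, c(M, M, T))
  covblk <- function(a, b) {    # Cov(z_a, z_b), a <= b, banded storage
    j <- b - a
    if (j == 0L) return(post$Vtt[, , a])
    if (j <= maxlag && !is.null(post$Clag[[j]])) return(post$Clag[[j]][, , a])
    NULL
  }
  for (t in seq_len(T)) {
    acc <- tcrossprod(Ew[t, ])
    for (l in 0:(min(L, t) - 1L)) {
      for (lp in 0:(min(L, t) - 1L)) {
        a <- t - max(l, lp); b <- t - min(l, lp)
        Cv <- covblk(a, b)
        if (is.null(Cv)) next
        if (lp > l) Cv <- t(Cv)
        acc <- acc + k[l + 1] * k[lp + 1] * Cv
      }
    }
    Eww[, , t] <- acc
  }
  list(Ew = Ew, Eww = Eww)
}

#' Accumulate M-step sufficient statistics
#'
#' Sums the posterior-expected cross products needed by the closed-form
#' updates: observation-side Gram blocks (`F2`, `F7`, `F8`, `H1`, `H2`,
#' `H3` for the stacked `[B J]` solve) and latent-side accumulators over
#' transitions (expectations of lagged state/activation products and
#' input cross products).  All sums use full expectations, not MAP
#' plug-ins; with a point-mass posterior they reduce to plain sample
#' cross products.
#'
#' @param post posterior from [estep()].
#' @param obs observation model (determines the design states).
#' @param X,S,R data matrices.
#' @return list of sufficient statistics (class `plrnn_stats`).
#' @export
accumulate_stats <- function(post, obs, X, S = NULL, R = NULL) {
  X <- as.matrix(X)
  T <- nrow(X); M <- ncol(post$z)
  ds <- .bold_design_stats(post, obs)
  Ew <- ds$Ew
  H3 <- rowSums(ds$Eww, dims = 2)
  H1 <- crossprod(X, Ew)                       # N x M
  F2 <- crossprod(X)
  F7 <- NULL; F8 <- NULL; H2 <- NULL
  if (!is.null(R)) {
    R <- as.matrix(R)
    F7 <- crossprod(X, R); F8 <- crossprod(R); H2 <- crossprod(R, Ew)
  }

  # latent side: sums over t = 2..T, statistics of (z_t, z_{t-1})
  m <- post$z
  i0 <- seq_len(T - 1)                         # "previous" index t-1
  i1 <- i0 + 1L
  Szz_prev <- rowSums(post$Vtt[, , i0, drop = FALSE], dims = 2) +
    crossprod(m[i0, , drop = FALSE])
  Szphi_prev <- rowSums(post$Ezphi[, , i0, drop = FALSE], dims = 2)
  Sphiphi_prev <- rowSums(post$Ephiphi[, , i0, drop = FALSE], dims = 2)
  Szz_cross <- rowSums(post$Czz[, , i0, drop = FALSE], dims = 2)
  Szphi_cross <- rowSums(post$Czphi[, , i0, drop = FALSE], dims = 2)
  Szz_cur <- rowSums(post$Vtt[, , i1, drop = FALSE], dims = 2) +
    crossprod(m[i1, , drop = FALSE])
  Sm_prev <- colSums(m[i0, , drop = FALSE])
  Sm_cur <- colSums(m[i1, , drop = FALSE])
  Sphi_prev <- colSums(post$Ephi[i0, , drop = FALSE])

  SS <- NULL; Sms <- NULL; Smps <- NULL; Sphis <- NULL; Ssum <- NULL
  if (!is.null(S)) {
    S <- as.matrix(S)
    Scur <- S[i1, , drop = FALSE]
    SS <- crossprod(Scur)
    Sms <- crossprod(m[i1, , drop = FALSE], Scur)        # M x K
    Smps <- crossprod(m[i0, , drop = FALSE], Scur)
    Sphis <- crossprod(post$Ephi[i0, , drop = FALSE], Scur)
    Ssum <- colSums(Scur)
  }
  structure(list(F2 = F2, F7 = F7, F8 = F8, H1 = H1, H2 = H2, H3 = H3,
                 Ew = Ew, T = T, M = M,
                 Szz_prev = Szz_prev, Szphi_prev = Szphi_prev,
                 Sphiphi_prev = Sphiphi_prev,
                 Szz_cross = Szz_cross, Szphi_cross = Szphi_cross,
                 Szz_cur = Szz_cur,
                 Sm_prev = Sm_prev, Sm_cur = Sm_cur, Sphi_prev = Sphi_prev,
                 SS = SS, Sms = Sms, Smps = Smps, Sphis = Sphis,
                 Ssum = Ssum,
                 m1 = m[1, ], V1 = post$Vtt[, , 1],
                 s1 = if (!is.null(S)) S[1, ] else NULL),
            class = "plrnn_stats")
}

.solve_ridge <- function(G, rhs, ridge = 0) {
  G <- (G + t(G)) / 2
  if (ridge > 0) G <- G + diag(ridge, nrow(G))
  out <- tryCatch(solve(G, rhs), error = function(e) NULL)
  if (is.null(out)) {
    G2 <- G + diag(1e-8 * max(1, mean(abs(diag(G)))), nrow(G))
    out <- tryCatch(solve(G2, rhs), error = function(e)
      stop(sprintf("singular normal equations (condition ~ %.3g)",
                   kappa(G2)), call. = FALSE))
  }
  out
}

#' Closed-form observation parameter update
#'
#' Solves the stacked expected least-squares problem for `Y = [B J]` and
#' recomputes the diagonal observation noise from the expected residual
#' cross products, floored at 1e-8.  When the loadings are frozen by the
#' training protocol (`B_fixed`), only `J` (if present) is re-solved
#' given the frozen `B`, and the residual noise is computed under the
#' frozen loadings — not under the unconstrained least-squares solution.
#'
#' @param stats sufficient statistics from [accumulate_stats()].
#' @param B_fixed optional frozen loading matrix.
#' @return list with `B`, `J` (`NULL` without nuisance regressors) and
#'   `Gamma`.
#' @export
update_obs_params <- function(stats, B_fixed = NULL) {
  T <- stats$T
  if (is.null(stats$F8)) {
    B <- if (is.null(B_fixed)) t(.solve_ridge(stats$H3, t(stats$H1))) else
      B_fixed
    J <- NULL
    resid <- stats$F2 - stats$H1 %*% t(B) - B %*% t(stats$H1) +
      B %*% stats$H3 %*% t(B)
  } else {
    Mm <- ncol(stats$H3)
    if (is.null(B_fixed)) {
      G <- rbind(cbind(stats$H3, t(stats$H2)),
                 cbind(stats$H2, stats$F8))
      Yt <- .solve_ridge(G, t(cbind(stats$H1, stats$F7)))
      Y <- t(Yt)
      B <- Y[, seq_len(Mm), drop = FALSE]
      J <- Y[, -seq_len(Mm), drop = FALSE]
    } else {
      B <- B_fixed
      # J solves the residual regression given the frozen loadings
      J <- t(.solve_ridge(stats$F8, t(stats$F7 - B %*% t(stats$H2))))
    }
    resid <- stats$F2 - stats$H1 %*% t(B) - B %*% t(stats$H1) +
      B %*% stats$H3 %*% t(B) -
      stats$F7 %*% t(J) - J %*% t(stats$F7) +
      B %*% t(stats$H2) %*% t(J) + J %*% stats$H2 %*% t(B) +
      J %*% stats$F8 %*% t(J)
  }
  Gamma <- pmax(diag(resid) / T, 1e-8)
  list(B = B, J = J, Gamma = Gamma)
}

#' Row-wise latent parameter update
#'
#' Each latent row `m` solves its expected normal equations over the
#' regressors \eqn{(z_{m,t-1}, \phi(z_{j \ne m, t-1}), s_t, 1)} with an
#' optional L2 penalty `lambda` on the regression coefficients (i.e. on
#' A, W, C, h — not on \eqn{\mu_0} or the variances).  The unit's own
#' activation is excluded from its row, which enforces `diag(W) = 0`
#' structurally.  \eqn{\mu_0 = E[z_1] - C s_1} and, when requested,
#' \eqn{\Sigma} is the diagonal of the expected squared residuals
#' (floored at 1e-8).
#'
#' @param stats sufficient statistics from [accumulate_stats()].
#' @param lambda L2 regularization factor (default 0).
#' @param update_sigma logical; return re-estimated `Sigma` (`NULL`
#'   otherwise, for protocols that keep it fixed).
#' @return list with `A`, `W`, `C`, `h`, `mu0`, `Sigma`.
#' @export
update_latent_params <- function(stats, lambda = 0, update_sigma = TRUE) {
  M <- stats$M; T <- stats$T
  K <- if (is.null(stats$SS)) 0L else ncol(stats$SS)
  n_tr <- T - 1
  A <- numeric(M); W <- matrix(0, M, M); h <- numeric(M)
  C <- if (K > 0) matrix(0, M, K) else NULL
  Sig <- numeric(M)
  for (mrow in seq_len(M)) {
    oth <- setdiff(seq_len(M), mrow)
    # regressors: z_m(prev), phi_j (j != m, prev), s, 1
    p <- 1L + (M - 1L) + K + 1L
    G <- matrix(0, p, p)
    iz <- 1L; ip <- 1L + seq_len(M - 1L)
    is_ <- if (K > 0) 1L + (M - 1L) + seq_len(K) else integer(0)
    ic <- p
    G[iz, iz] <- stats$Szz_prev[mrow, mrow]
    G[iz, ip] <- stats$Szphi_prev[mrow, oth]
    G[ip, iz] <- G[iz, ip]
    G[ip, ip] <- stats$Sphiphi_prev[oth, oth]
    G[iz, ic] <- stats$Sm_prev[mrow]
    G[ic, iz] <- G[iz, ic]
    G[ip, ic] <- stats$Sphi_prev[oth]
    G[ic, ip] <- G[ip, ic]
    G[ic, ic] <- n_tr
    if (K > 0) {
      G[iz, is_] <- stats$Smps[mrow, ]
      G[is_, iz] <- G[iz, is_]
      G[ip, is_] <- stats$Sphis[oth, , drop = FALSE]
      G[is_, ip] <- t(G[ip, is_, drop = FALSE])
      G[is_, is_] <- stats$SS
      G[is_, ic] <- stats$Ssum
      G[ic, is_] <- stats$Ssum
    }
    rhs <- numeric(p)
    rhs[iz] <- stats$Szz_cross[mrow, mrow]
    rhs[ip] <- stats$Szphi_cross[mrow, oth]
    if (K > 0) rhs[is_] <- stats$Sms[mrow, ]
    rhs[ic] <- stats$Sm_cur[mrow]
    beta <- .solve_ridge(G, rhs, ridge = lambda)
    A[mrow] <- beta[iz]
    W[mrow, oth] <- beta[ip]
    if (K > 0) C[mrow, ] <- beta[is_]
    h[mrow] <- beta[ic]
    # expected squared transition residual for this row
    Sig[mrow] <- stats$Szz_cur[mrow, mrow] - 2 * sum(beta * rhs) +
      drop(t(beta) %*% G %*% beta)
  }
  mu0 <- stats$m1 - if (K > 0) drop(C %*% stats$s1) else 0
  Sigma <- if (update_sigma) {
    pmax((Sig + diag(stats$V1)) / T, 1e-8)
  } else NULL
  list(A = A, W = W, C = C, h = h, mu0 = mu0, Sigma = Sigma)
}
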