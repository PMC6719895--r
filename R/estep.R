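# Global Laplace / MAP state inference.
#
# The joint log-density of (X, Z) is, for any fixed configuration Omega of
# active (z > 0) units, a quadratic in the stacked state vector
# z = (z_11..z_M1, ..., z_1T..z_MT)'.  It is assembled here as
#   Q(z) = -1/2 z' P(d) z + z' v(d) + const,
#   P(d) = U0 + D U1 + U1' D + D U2 D + UH,
#   v(d) = v0 + d * v1 + vH,
# with D = diag(d) the 0/1 active-region indicator.  U0 collects the
# region-independent precision blocks of the latent process and the
# (region-independent) HRF-convolved observation precision enters through
# UH = H' blockdiag(B' Gamma^-1 B) H; region-dependent pieces (the W phi
# coupling, and for the Gaussian decoder the B phi observation term) sit
# in U1/U2/v1.  All matrices are sparse block-banded, so MAP solves and
# covariance extraction scale linearly in T.

#' Assemble the piecewise-quadratic MAP objective
#'
#' Builds the sparse components of the stacked quadratic form for a data
#' set under the given latent and observation parameters.  For any fixed
#' active set the resulting quadratic reproduces the joint log-density up
#' to a z-independent constant (verified in the tests against direct
#' evaluation).
#'
#' @param params a [plrnn_params()] object.
#' @param obs an [obs_gaussian()] or [obs_bold()] object.
#' @param X T x N observation matrix.
#' @param S optional T x K input matrix.
#' @param R optional T x P nuisance matrix (BOLD).
#' @return a `plrnn_qf` list of sparse matrices and vectors.
#' @export
assemble_quadratic <- function(params, obs, X, S = NULL, R = NULL) {
  X <- as.matrix(X)
  T <- nrow(X); N <- ncol(X); M <- length(params$A)
  .assert(T >= 2, "need at least two time points")
  .assert(ncol(obs$B) == M, "obs model dimension mismatch")
  .assert(nrow(obs$B) == N, "obs model dimension mismatch")
  if (!is.null(S)) { S <- as.matrix(S); .assert(nrow(S) == T, "S/X length mismatch") }
  if (!is.null(R)) { R <- as.matrix(R); .assert(nrow(R) == T, "R/X length mismatch") }

  Si <- 1 / params$Sigma                      # Sigma^-1 (diagonal)
  A <- params$A; W <- params$W
  Gi <- 1 / obs$Gamma
  BtGiB <- crossprod(obs$B * sqrt(Gi))        # B' Gamma^-1 B
  BtGi <- t(obs$B * Gi)                       # M x N

  IT <- Matrix::Diagonal(T)
  Dkeep <- Matrix::Diagonal(T, x = c(rep(1, T - 1), 0))
  Sh <- Matrix::bandSparse(T, T, k = -1, diagonals = list(rep(1, T - 1)))

  SiA <- Matrix::Diagonal(M, Si * A)          # Sigma^-1 A (diagonal)
  ASiA <- Matrix::Diagonal(M, Si * A^2)
  WtSi <- t(W) * rep(Si, each = M)            # W' Sigma^-1
  WtSiA <- WtSi %*% diag(A, M)
  WtSiW <- t(W) %*% (W * Si)

  U0 <- Matrix::kronecker(IT, Matrix::Diagonal(M, Si)) +
    Matrix::kronecker(Dkeep, ASiA) -
    Matrix::kronecker(Sh, SiA) -
    Matrix::kronecker(Matrix::t(Sh), SiA)
  U1 <- Matrix::kronecker(Dkeep, WtSiA) -
    Matrix::kronecker(Matrix::t(Sh), WtSi)
  U2 <- Matrix::kronecker(Dkeep, WtSiW)

  # linear terms from the latent process
  hC <- matrix(params$h, T, M, byrow = TRUE)  # h + C s_t per t
  if (!is.null(params$C) && !is.null(S)) hC <- hC + S %*% t(params$C)
  mu1 <- params$mu0 + if (!is.null(params$C) && !is.null(S))
    drop(params$C %*% S[1, ]) else 0
  v0m <- matrix(0, T, M)
  v0m[1, ] <- Si * mu1
  v0m[2:T, ] <- v0m[2:T, ] + hC[2:T, , drop = FALSE] * rep(Si, each = T - 1)
  v0m[1:(T - 1), ] <- v0m[1:(T - 1), ] -
    hC[2:T, , drop = FALSE] * rep(Si * A, each = T - 1)
  v1m <- matrix(0, T, M)
  v1m[1:(T - 1), ] <- -(hC[2:T, , drop = FALSE] * rep(Si, each = T - 1)) %*% W

  bold <- inherits(obs, "obs_bold")
  UH <- NULL; vH <- NULL
  kernel_len <- 1L
  if (!bold) {
    # Gaussian decoder: x_t = B phi(z_t) -> region-dependent pieces
    U2 <- U2 + Matrix::kronecker(IT, BtGiB)
    v1m <- v1m + X %*% t(BtGi)
  } else {
    kernel_len <- length(obs$hrf)
    Xr <- X
    if (!is.null(obs$J)) {
      .assert(!is.null(R), "BOLD model with J needs nuisance matrix R")
      Xr <- X - R %*% t(obs$J)
    }
    H <- build_hrf_operator(T, M, obs$hrf)
    U3 <- Matrix::kronecker(IT, BtGiB)
    UHfull <- Matrix::t(H) %*% U3 %*% H
    vHfull <- as.numeric(Matrix::t(H) %*% as.numeric(t(Xr %*% t(BtGi))))
    if (obs$convolve_activation) {
      U2 <- U2 + UHfull
      v1m <- v1m + matrix(vHfull, T, M, byrow = TRUE)
    } else {
      UH <- UHfull
      vH <- vHfull
    }
  }

  structure(list(U0 = Matrix::forceSymmetric(U0),
                 U1 = U1,
                 U2 = Matrix::forceSymmetric(U2),
                 UH = if (!is.null(UH)) Matrix::forceSymmetric(UH) else NULL,
                 v0 = as.numeric(t(v0m)), v1 = as.numeric(t(v1m)),
                 vH = vH,
                 T = T, M = M, N = N,
                 linear = params$linear,
                 kernel_len = kernel_len,
                 mu1 = mu1, hC = hC,
                 params = params, obs = obs, X = X, S = S, R = R),
            class = "plrnn_qf")
}

# Precision matrix and linear term for a fixed active-region indicator d.
qf_precision <- function(qf, d) {
  D <- Matrix::Diagonal(length(d), x = d)
  DU1 <- D %*% qf$U1
  P <- qf$U0 + DU1 + Matrix::t(DU1) + D %*% qf$U2 %*% D
  if (!is.null(qf$UH)) P <- P + qf$UH
  Matrix::forceSymmetric(P)
}

qf_linear <- function(qf, d) {
  v <- qf$v0 + d * qf$v1
  if (!is.null(qf$vH)) v <- v + qf$vH
  v
}

# Objective value (constants omitted; they do not depend on z or Omega).
qf_value <- function(qf, z, d) {
  P <- qf_precision(qf, d)
  v <- qf_linear(qf, d)
  -0.5 * sum(z * as.numeric(P %*% z)) + sum(z * v)
}

.solve_spd <- function(P, v) {
  tryCatch(
    as.numeric(Matrix::solve(P, v)),
    error = function(e) {
      Pj <- P + Matrix::Diagonal(nrow(P), 1e-8)
      as.numeric(Matrix::solve(Pj, v))
    })
}

# Exact maximizer of -1/2 z'Pz + z'v over the closed region cell of the
# indicator d (z_i >= 0 where d_i = 1, z_i <= 0 otherwise), by a primal
# active-set method on the sign-flipped nonnegative formulation.  P must
# be the (positive definite) precision for this cell.  This is the
# "quadratic programming step" finisher: interior bit-flip solutions are
# already cell maxima, but when the global optimum sits exactly on a
# region boundary no interior-consistent configuration exists and the
# constrained solve is what attains it.
.qp_cell_max <- function(P, v, d, z_start = NULL, max_iter = 60) {
  n <- length(v)
  s <- ifelse(d > 0, 1, -1)
  Ps <- Matrix::Diagonal(n, s) %*% P %*% Matrix::Diagonal(n, s)
  vs <- s * v
  # minimize 1/2 y' Ps y - y' vs subject to y >= 0
  y <- if (is.null(z_start)) rep(0, n) else pmax(s * z_start, 0)
  free <- y > 0 | vs > 0
  for (it in seq_len(max_iter)) {
    if (!any(free)) { y <- rep(0, n) } else {
      yf <- tryCatch(
        as.numeric(Matrix::solve(Ps[free, free, drop = FALSE], vs[free])),
        error = function(e)
          as.numeric(Matrix::solve(Ps[free, free, drop = FALSE] +
                                     Matrix::Diagonal(sum(free), 1e-10),
                                   vs[free])))
      if (any(yf < -1e-12)) {
        # step from current y toward yf until the first bound is hit
        ycur <- y[free]
        dir <- yf - ycur
        bad <- which(dir < 0)
        alpha <- min(1, suppressWarnings(min(-ycur[bad] / dir[bad])))
        ynew <- ycur + alpha * dir
        ynew[ynew < 1e-14] <- 0
        y[free] <- ynew
        free[free][y[free] == 0] <- FALSE
        next
      }
      y[free] <- yf
      y[!free] <- 0
    }
    g <- as.numeric(Ps %*% y) - vs          # KKT: g_i >= 0 on the bound
    viol <- which(!free & g < -1e-10)
    if (!length(viol)) break
    free[viol[which.max(-g[viol])]] <- TRUE
  }
  s * y
}

#' MAP latent path by the fixed-point bit-flip iteration
#'
#' Alternates between solving the quadratic for a fixed active-region
#' indicator `d` and flipping the entries of `d` that are inconsistent
#' with the solution's sign pattern (active iff \eqn{z > 0}, strictly).
#' At convergence the solution is a true stationary point of the
#' piecewise-quadratic objective.  If a configuration repeats, the single
#' most strongly violated bit is flipped instead; if that configuration
#' was also visited the iteration stops.  Because the surface can have
#' several consistent configurations — and its global maximum may sit
#' exactly on a region boundary, where no interior-consistent
#' configuration exists — the search is run from `n_starts` initial
#' indicator configurations, and any non-interior winner is polished by
#' an exact box-constrained QP within its region cell.  Linear parameter
#' sets need a single solve.
#'
#' @param qf quadratic form from [assemble_quadratic()].
#' @param z_init optional warm-start stacked state; when supplied (as in
#'   EM iterations after the first) only that start is used, plus the QP
#'   polish when needed.
#' @param max_rounds flip-iteration cap per start (default 100).
#' @param n_starts number of cold-start configurations (all-inactive,
#'   all-active, plus seeded random indicators; default 6).
#' @return list with `z` (T x M MAP path), `z_map` (stacked MT-vector),
#'   `d_omega`, `n_rounds` (total linear solves), `converged`, `Q`
#'   (objective up to constant).
#' @export
solve_map <- function(qf, z_init = NULL, max_rounds = 100, n_starts = 6) {
  MT <- qf$T * qf$M
  if (qf$linear) {
    d <- rep(1, MT)
    z <- .solve_spd(qf_precision(qf, d), qf_linear(qf, d))
    return(list(z = matrix(z, qf$T, qf$M, byrow = TRUE), z_map = z,
                d_omega = d, n_rounds = 1L, converged = TRUE,
                Q = qf_value(qf, z, d)))
  }
  starts <- if (!is.null(z_init)) {
    list(as.numeric(z_init > 0))
  } else {
    st <- list(rep(0, MT), rep(1, MT))
    if (n_starts > 2)
      st <- c(st, with_seed(917, lapply(seq_len(n_starts - 2), function(i)
        as.numeric(runif(MT) > 0.5))))
    st
  }
  visited <- new.env(parent = emptyenv())
  key <- function(d) paste0("k", paste(which(d > 0), collapse = ","))
  total_rounds <- 0L
  any_converged <- FALSE
  cands <- list()
  for (d in starts) {
    rounds <- 0L
    sbest <- NULL
    while (rounds < max_rounds) {
      rounds <- rounds + 1L
      z <- .solve_spd(qf_precision(qf, d), qf_linear(qf, d))
      seen <- exists(key(d), envir = visited)
      assign(key(d), TRUE, envir = visited)
      dnew <- as.numeric(z > 0)
      consistent <- all(dnew == d)
      if (consistent) any_converged <- TRUE
      # score by the true piecewise objective at z (the quadratic piece
      # the point actually lies in, not the piece it was solved under)
      Q <- qf_value(qf, z, dnew)
      if (is.null(sbest) || Q > sbest$Q)
        sbest <- list(z = z, Q = Q, consistent = consistent)
      if (consistent || (seen && rounds > 1L)) break
      if (exists(key(dnew), envir = visited)) {
        viol <- abs(z) * (dnew != d)
        dflip <- d
        i <- which.max(viol)
        dflip[i] <- 1 - dflip[i]
        if (exists(key(dflip), envir = visited)) break
        d <- dflip
      } else d <- dnew
    }
    total_rounds <- total_rounds + rounds
    cands[[length(cands) + 1L]] <- sbest
  }
  ord <- order(-vapply(cands, `[[`, 0, "Q"))
  best <- cands[[ord[1]]]
  # QP polish: an interior-consistent solution is already the maximum of
  # its cell, but the global optimum may sit exactly on a region boundary
  # where no interior-consistent configuration exists.  Ascend from the
  # leading non-interior candidates through constrained cell maxima and
  # adjacent cells until no neighboring cell improves (a true local
  # maximum of the continuous piecewise objective).
  # On small problems ascend from the leading candidates (consistent or
  # not) over all single-coordinate cell flips — each accepted move is a
  # constrained cell maximum, so the end point is a local maximum of the
  # continuous objective over its whole cell neighborhood.  On large
  # instances restrict to non-interior winners and near-boundary flips,
  # where a single constrained solve is what matters.
  small <- MT <= 120
  polish <- ord[seq_len(min(3L, length(ord)))]
  if (!small)
    polish <- polish[!vapply(cands[polish], `[[`, TRUE, "consistent")]
  n_sweeps <- if (MT <= 500) 20L else 1L
  for (ci in polish) {
    zb <- cands[[ci]]$z
    Qb <- cands[[ci]]$Q
    for (sweep in seq_len(n_sweeps)) {
      dcell <- as.numeric(zb > 0)
      zq <- .qp_cell_max(qf_precision(qf, dcell), qf_linear(qf, dcell),
                         dcell, z_start = zb)
      Qq <- qf_value(qf, zq, dcell)  # valid: zq lies in the closed cell
      improved <- Qq > Qb + 1e-12
      if (Qq >= Qb) { zb <- zq; Qb <- Qq }
      bnd <- if (small) order(abs(zb)) else {
        b <- which(abs(zb) < 0.3)
        utils::head(b[order(abs(zb[b]))], 12L)
      }
      for (i in bnd) {
        dn <- as.numeric(zb > 0); dn[i] <- 1 - dn[i]
        zn <- .qp_cell_max(qf_precision(qf, dn), qf_linear(qf, dn), dn,
                           z_start = zb)
        Qn <- qf_value(qf, zn, dn)
        if (Qn > Qb + 1e-12) { zb <- zn; Qb <- Qn; improved <- TRUE; break }
      }
      if (!improved) break
    }
    if (Qb > best$Q) best <- list(z = zb, Q = Qb, consistent = FALSE)
  }
  list(z = matrix(best$z, qf$T, qf$M, byrow = TRUE), z_map = best$z,
       d_omega = as.numeric(best$z > 0), n_rounds = total_rounds,
       converged = any_converged, Q = best$Q)
}

#' Block-banded posterior covariance
#'
#' Approximates the state covariance as the inverse of the negative
#' Hessian at the MAP path.  Only the block-tridiagonal part of the
#' inverse (in time chunks matching the precision bandwidth) is computed,
#' via the standard forward-Schur/backward-substitution recursion for
#' block-tridiagonal matrices, so the full \eqn{MT \times MT} inverse is
#' never formed and cost stays linear in `T`.
#'
#' @param qf quadratic form from [assemble_quadratic()].
#' @param d_omega active-region indicator at the MAP.
#' @return list with `Vtt` (M x M x T marginal covariances), `Clag`
#'   (list; `Clag[[j]]` is M x M x (T-j) with `Cov(z_t, z_{t+j})`), and
#'   `floored` flag set when a jitter was needed for positive
#'   definiteness.
#' @export
posterior_covariance <- function(qf, d_omega) {
  T <- qf$T; M <- qf$M
  P <- qf_precision(qf, d_omega)
  bw <- max(1L, qf$kernel_len - 1L)           # bandwidth in time blocks
  cs <- min(bw, T)                            # chunk size (time points)
  nc <- ceiling(T / cs)
  idx <- function(k) {                        # stacked indices of chunk k
    t0 <- (k - 1L) * cs + 1L
    t1 <- min(k * cs, T)
    ((t0 - 1L) * M + 1L):(t1 * M)
  }
  Dk <- vector("list", nc); Ek <- vector("list", nc - 1L)
  for (k in seq_len(nc)) {
    Dk[[k]] <- as.matrix(P[idx(k), idx(k), drop = FALSE])
    if (k < nc) Ek[[k]] <- as.matrix(P[idx(k), idx(k + 1L), drop = FALSE])
  }
  floored <- FALSE
  inv_spd <- function(Smat) {
    out <- tryCatch(chol2inv(chol(Smat)), error = function(e) NULL)
    if (is.null(out)) {
      floored <<- TRUE
      ev <- eigen(Smat, symmetric = TRUE)
      lam <- pmax(ev$values, 1e-8)
      out <- ev$vectors %*% (t(ev$vectors) / lam)
    }
    out
  }
  Sinv <- vector("list", nc)
  Scur <- Dk[[1]]
  Sinv[[1]] <- inv_spd(Scur)
  for (k in 2:max(nc, 2)) {
    if (k > nc) break
    Scur <- Dk[[k]] - crossprod(Ek[[k - 1]], Sinv[[k - 1]] %*% Ek[[k - 1]])
    Sinv[[k]] <- inv_spd((Scur + t(Scur)) / 2)
  }
  Vkk <- vector("list", nc); Vko <- vector("list", nc - 1L)
  Vkk[[nc]] <- Sinv[[nc]]
  if (nc > 1) for (k in (nc - 1L):1L) {
    G <- Sinv[[k]] %*% Ek[[k]]
    Vkk[[k]] <- Sinv[[k]] + G %*% Vkk[[k + 1L]] %*% t(G)
    Vko[[k]] <- -G %*% Vkk[[k + 1L]]
  }
  # extract per-time blocks for lags 0..cs
  Vtt <- array(0, c(M, M, T))
  Clag <- lapply(seq_len(cs), function(j)
    if (T - j >= 1) array(0, c(M, M, T - j)) else NULL)
  tloc <- function(t) {            # (chunk, offset within chunk)
    k <- (t - 1L) %/% cs + 1L
    c(k, t - (k - 1L) * cs)
  }
  block <- function(t1, t2) {      # Cov(z_{t1}, z_{t2}), t2 >= t1
    a <- tloc(t1); b <- tloc(t2)
    ri <- ((a[2] - 1L) * M + 1L):(a[2] * M)
    ci <- ((b[2] - 1L) * M + 1L):(b[2] * M)
    if (a[1] == b[1]) Vkk[[a[1]]][ri, ci, drop = FALSE]
    else Vko[[a[1]]][ri, ci, drop = FALSE]
  }
  for (t in seq_len(T)) {
    Vtt[, , t] <- (block(t, t) + t(block(t, t))) / 2
    for (j in seq_len(cs)) {
      if (t + j <= T) Clag[[j]][, , t] <- block(t, t + j)
    }
  }
  list(Vtt = Vtt, Clag = Clag, floored = floored)
}

#' Run a full E-step
#'
#' Assembles the objective, finds the MAP path, extracts the block-banded
#' posterior covariance, and computes the ReLU-moment expectations needed
#' by the M-step.
#'
#' @inheritParams assemble_quadratic
#' @param z_init warm start for the MAP search (T x M matrix or stacked
#'   vector), typically the previous EM iteration's path.
#' @param max_rounds bit-flip iteration cap.
#' @return a `plrnn_posterior` list: MAP path `z` (T x M), `d_omega`,
#'   `Vtt`, `Clag`, moment arrays (see `posterior_moments`), flip count
#'   and convergence flag.
#' @export
estep <- function(params, obs, X, S = NULL, R = NULL, z_init = NULL,
                  max_rounds = 100) {
  qf <- assemble_quadratic(params, obs, X, S, R)
  if (!is.null(z_init)) z_init <- as.numeric(t(as.matrix(z_init)))
  mp <- solve_map(qf, z_init = z_init, max_rounds = max_rounds)
  pc <- posterior_covariance(qf, mp$d_omega)
  Ct <- if (qf$T > 1) pc$Clag[[1]] else array(0, c(qf$M, qf$M, 1))
  mom <- posterior_moments(mp$z, pc$Vtt, Ct, linear = params$linear)
  structure(c(list(z = mp$z, z_map = mp$z_map, d_omega = mp$d_omega,
                   Vtt = pc$Vtt, Clag = pc$Clag, Ct = Ct,
                   n_rounds = mp$n_rounds, converged = mp$converged,
                   Q = mp$Q, floored = pc$floored, qf = qf),
              mom),
            class = "plrnn_posterior")
}

#' Expected joint log-likelihood under the posterior
#'
#' Evaluates \eqn{E_q[\log p(X, Z | \theta)]} by plugging the posterior
#' expectations into the quadratic joint log-density, including all
#' Gaussian normalization constants.  This is the EM convergence monitor.
#' With `rescale_sigma = TRUE` the process covariance is replaced by the
#' identity before evaluation, which makes values comparable across
#' annealing steps that shrink \eqn{\Sigma}.
#'
#' @param params,obs model parameter objects.
#' @param post posterior from [estep()].
#' @param X,S,R data matrices, as used in the E-step.
#' @param rescale_sigma logical (default `FALSE`).
#' @return scalar expected joint log-likelihood.
#' @export
expected_joint_loglik <- function(params, obs, post, X, S = NULL, R = NULL,
                                  rescale_sigma = FALSE) {
  X <- as.matrix(X)
  T <- nrow(X); M <- length(params$A); N <- ncol(X)
  Sigma <- if (rescale_sigma) rep(1, M) else params$Sigma
  Si <- 1 / Sigma
  A <- params$A; W <- params$W
  m <- post$z; Vtt <- post$Vtt
  hC <- matrix(params$h, T, M, byrow = TRUE)
  if (!is.null(params$C) && !is.null(S)) hC <- hC + as.matrix(S) %*% t(params$C)
  mu1 <- params$mu0 + if (!is.null(params$C) && !is.null(S))
    drop(params$C %*% as.matrix(S)[1, ]) else 0

  msl <- function(arr, t) matrix(arr[, , t], M, M)   # M = 1 safe slice

  # initial state term
  r1 <- m[1, ] - mu1
  ll <- -0.5 * sum(Si * (r1^2 + diag(msl(Vtt, 1)))) -
    0.5 * sum(log(2 * pi * Sigma))

  # transitions: E[(z_t - A z_{t-1} - W phi(z_{t-1}) - h - C s_t)' Si (.)]
  if (T > 1) for (t in 2:T) {
    mt <- m[t, ]; mp_ <- m[t - 1, ]
    Ezz_t <- msl(Vtt, t) + tcrossprod(mt)
    Ezz_p <- msl(Vtt, t - 1) + tcrossprod(mp_)
    Ezz_c <- msl(post$Czz, t - 1)         # E[z_t z_{t-1}']
    Ezphi_c <- msl(post$Czphi, t - 1)     # E[z_t phi(z_{t-1})']
    Ezphi_p <- msl(post$Ezphi, t - 1)     # E[z_{t-1} phi(z_{t-1})']
    Epp_p <- msl(post$Ephiphi, t - 1)
    Ephi_p <- post$Ephi[t - 1, ]
    b <- hC[t, ]
    Am <- A                                # diagonal
    q <- diag(Ezz_t) -
      2 * Am * diag(Ezz_c) -
      2 * rowSums(W * Ezphi_c) -
      2 * mt * b +
      Am^2 * diag(Ezz_p) +
      2 * Am * rowSums(W * Ezphi_p) +
      2 * Am * mp_ * b +
      rowSums((W %*% Epp_p) * W) +
      2 * (W %*% Ephi_p) * b +
      b^2
    ll <- ll - 0.5 * sum(Si * q) - 0.5 * sum(log(2 * pi * Sigma))
  }

  # observation term
  Gi <- 1 / obs$Gamma
  B <- obs$B
  if (inherits(obs, "obs_gaussian")) {
    for (t in seq_len(T)) {
      Ephi_t <- post$Ephi[t, ]
      Epp_t <- msl(post$Ephiphi, t)
      r <- X[t, ] - drop(B %*% Ephi_t)
      covterm <- Epp_t - tcrossprod(Ephi_t)
      ll <- ll - 0.5 * sum(Gi * r^2) -
        0.5 * sum(diag(B %*% covterm %*% (t(B) * Gi)))
    }
  } else {
    st <- .bold_design_stats(post, obs)
    Xr <- X
    if (!is.null(obs$J)) Xr <- X - as.matrix(R) %*% t(obs$J)
    for (t in seq_len(T)) {
      r <- Xr[t, ] - drop(B %*% st$Ew[t, ])
      covterm <- msl(st$Eww, t) - tcrossprod(st$Ew[t, ])
      ll <- ll - 0.5 * sum(Gi * r^2) -
        0.5 * sum(diag(B %*% covterm %*% (t(B) * Gi)))
    }
  }
  ll - 0.5 * T * sum(log(2 * pi * obs$Gamma))
}
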