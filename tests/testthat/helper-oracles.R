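# Independent oracles used across the suite.  These deliberately share no
# code with the package internals they check.

# Direct evaluation of the joint log-density (up to additive constants the
# quadratic form also omits) for a Gaussian decoder.
direct_joint_logdens <- function(params, obs, X, Z, S = NULL) {
  T <- nrow(X); M <- length(params$A)
  Si <- 1 / params$Sigma; Gi <- 1 / obs$Gamma
  phi <- function(z) if (params$linear) z else pmax(z, 0)
  hC <- matrix(params$h, T, M, byrow = TRUE)
  if (!is.null(params$C) && !is.null(S)) hC <- hC + S %*% t(params$C)
  mu1 <- params$mu0 +
    if (!is.null(params$C) && !is.null(S)) drop(params$C %*% S[1, ]) else 0
  q <- -0.5 * sum(Si * (Z[1, ] - mu1)^2)
  if (T > 1) for (t in 2:T) {
    pred <- params$A * Z[t - 1, ] + drop(params$W %*% phi(Z[t - 1, ])) + hC[t, ]
    q <- q - 0.5 * sum(Si * (Z[t, ] - pred)^2)
  }
  for (t in seq_len(T))
    q <- q - 0.5 * sum(Gi * (X[t, ] - drop(obs$B %*% phi(Z[t, ])))^2)
  q
}

# Textbook Kalman filter + RTS smoother for the LDS
#   z_1 ~ N(mu1, Q); z_t = F z_{t-1} + b_t + w, w ~ N(0, Q)
#   x_t = Hm z_t + v, v ~ N(0, Rm)
# Returns smoothed means, covariances, lag-one covariances and the exact
# marginal log-likelihood.
kalman_smoother <- function(F, b, Q, Hm, Rm, mu1, X) {
  T <- nrow(X); M <- nrow(F)
  if (is.vector(b)) b <- matrix(b, T, M, byrow = TRUE)
  xp <- matrix(0, T, M); Pp <- array(0, c(M, M, T))
  xf <- matrix(0, T, M); Pf <- array(0, c(M, M, T))
  ll <- 0
  for (t in seq_len(T)) {
    if (t == 1) { xpt <- mu1; Ppt <- Q }
    else {
      xpt <- drop(F %*% xf[t - 1, ]) + b[t, ]
      Ppt <- F %*% Pf[, , t - 1] %*% t(F) + Q
    }
    S <- Hm %*% Ppt %*% t(Hm) + Rm
    innov <- X[t, ] - drop(Hm %*% xpt)
    Sinv <- solve(S)
    K <- Ppt %*% t(Hm) %*% Sinv
    xf[t, ] <- xpt + drop(K %*% innov)
    Pf[, , t] <- Ppt - K %*% Hm %*% Ppt
    xp[t, ] <- xpt; Pp[, , t] <- Ppt
    ll <- ll - 0.5 * (length(innov) * log(2 * pi) +
                        determinant(S)$modulus +
                        drop(t(innov) %*% Sinv %*% innov))
  }
  xs <- xf; Ps <- Pf
  Cs <- array(0, c(M, M, max(T - 1, 1)))   # Cov(z_t, z_{t+1} | X)
  if (T > 1) for (t in (T - 1):1) {
    J <- Pf[, , t] %*% t(F) %*% solve(Pp[, , t + 1])
    xs[t, ] <- xf[t, ] + drop(J %*% (xs[t + 1, ] - xp[t + 1, ]))
    Ps[, , t] <- Pf[, , t] + J %*% (Ps[, , t + 1] - Pp[, , t + 1]) %*% t(J)
    Cs[, , t] <- J %*% Ps[, , t + 1]       # Cov(z_t, z_{t+1})
  }
  list(mean = xs, cov = Ps, lag1 = Cs, loglik = as.numeric(ll))
}

# Random small LDS instance (linear PLRNN parametrization + Gaussian obs)
random_lds_instance <- function(M = 3, N = 2, T = 30, seed = 1) {
  set.seed(seed)
  A <- runif(M, 0.2, 0.8)
  W <- matrix(rnorm(M * M, 0, 0.2 / sqrt(M)), M, M); diag(W) <- 0
  params <- plrnn_params(A = A, W = W, h = rnorm(M, 0, 0.3),
                         mu0 = rnorm(M, 0, 0.5),
                         Sigma = runif(M, 0.3, 1.5), linear = TRUE)
  obs <- obs_gaussian(matrix(rnorm(N * M), N, M), runif(N, 0.3, 1.5))
  Z <- plrnn_generate(params, T, seed = seed + 1)
  X <- emit(obs, Z, noise = TRUE, seed = seed + 2, linear = TRUE)
  list(params = params, obs = obs, Z = Z, X = X)
}

# Benettin-style two-trajectory Lyapunov oracle with renormalization:
# independent of the package's regression-on-log-distance estimator.
benettin_lyapunov <- function(step, x0, d0 = 1e-8, n_steps = 20000,
                              renorm_every = 10, dt = 0.01, seed = 1) {
  set.seed(seed)
  D <- length(x0)
  v <- rnorm(D); v <- v / sqrt(sum(v^2))
  xa <- x0; xb <- x0 + d0 * v
  acc <- 0; count <- 0
  for (i in seq_len(n_steps)) {
    xa <- step(xa); xb <- step(xb)
    if (i %% renorm_every == 0) {
      d <- sqrt(sum((xa - xb)^2))
      acc <- acc + log(d / d0)
      count <- count + renorm_every
      xb <- xa + (xb - xa) * (d0 / d)
    }
  }
  acc / (count * dt)
}

rk4_lorenz_step <- function(dt = 0.01, s = 10, r = 28, b = 8 / 3) {
  f <- function(u) c(s * (u[2] - u[1]),
                     u[1] * (r - u[3]) - u[2],
                     u[1] * u[2] - b * u[3])
  function(u) {
    k1 <- f(u); k2 <- f(u + dt / 2 * k1)
    k3 <- f(u + dt / 2 * k2); k4 <- f(u + dt * k3)
    u + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
}
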