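# The E-step is checked against three independent oracles: direct
# evaluation of the joint log-density (quadratic-form assembly), a
# textbook Kalman smoother (linear limit, including HRF cases), and a
# generic multi-start optimizer (MAP quality).

test_that("assembled quadratic reproduces the joint log-density", {
  set.seed(7)
  M <- 3; T <- 12; N <- 2
  W <- matrix(rnorm(9, 0, 0.3), 3, 3); diag(W) <- 0
  p <- plrnn_params(A = runif(M, 0.3, 0.8), W = W, h = rnorm(M, 0, 0.5),
                    mu0 = rnorm(M), Sigma = runif(M, 0.5, 2))
  ob <- obs_gaussian(matrix(rnorm(N * M), N, M), runif(N, 0.5, 2))
  X <- matrix(rnorm(T * N), T, N)
  qf <- assemble_quadratic(p, ob, X)
  # the difference to the direct evaluation must be a Z-independent const
  consts <- vapply(1:6, function(i) {
    Z <- matrix(rnorm(T * M, 0, 2), T, M)
    z <- as.numeric(t(Z))
    plrnnssm:::qf_value(qf, z, as.numeric(z > 0)) -
      direct_joint_logdens(p, ob, X, Z)
  }, 0)
  expect_lt(max(consts) - min(consts), 1e-8)
})

test_that("assembled quadratic covers inputs and the BOLD decoder", {
  set.seed(8)
  M <- 2; T <- 15; N <- 3; K <- 2; P <- 2
  W <- matrix(rnorm(4, 0, 0.3), 2, 2); diag(W) <- 0
  p <- plrnn_params(A = runif(M, 0.3, 0.8), W = W, h = rnorm(M),
                    mu0 = rnorm(M), Sigma = runif(M, 0.5, 2),
                    C = matrix(rnorm(M * K, 0, 0.5), M, K))
  S <- matrix(rbinom(T * K, 1, 0.3), T, K)
  R <- matrix(rnorm(T * P), T, P)
  X <- matrix(rnorm(T * N), T, N)
  k <- c(1, 0.6, 0.2)
  ob <- obs_bold(matrix(rnorm(N * M), N, M), runif(N, 0.5, 2), hrf = k,
                 J = matrix(rnorm(N * P, 0, 0.5), N, P))
  # direct evaluation with convolved raw states and nuisance
  direct_bold <- function(Z) {
    q <- 0
    Si <- 1 / p$Sigma; Gi <- 1 / ob$Gamma
    hC <- matrix(p$h, T, M, byrow = TRUE) + S %*% t(p$C)
    mu1 <- p$mu0 + drop(p$C %*% S[1, ])
    q <- q - 0.5 * sum(Si * (Z[1, ] - mu1)^2)
    for (t in 2:T) {
      pred <- p$A * Z[t - 1, ] + drop(p$W %*% pmax(Z[t - 1, ], 0)) + hC[t, ]
      q <- q - 0.5 * sum(Si * (Z[t, ] - pred)^2)
    }
    Wc <- hrf_convolve(Z, k)
    for (t in 1:T) {
      r <- X[t, ] - drop(ob$B %*% Wc[t, ]) - drop(ob$J %*% R[t, ])
      q <- q - 0.5 * sum(Gi * r^2)
    }
    q
  }
  qf <- assemble_quadratic(p, ob, X, S = S, R = R)
  consts <- vapply(1:5, function(i) {
    Z <- matrix(rnorm(T * M, 0, 2), T, M)
    z <- as.numeric(t(Z))
    plrnnssm:::qf_value(qf, z, as.numeric(z > 0)) - direct_bold(Z)
  }, 0)
  expect_lt(max(consts) - min(consts), 1e-8)
})

test_that("Hessian matches finite differences on a tiny instance", {
  # M = 1, T = 2, all scalars; fixed active region d = (1, 1)
  p <- plrnn_params(A = 0.5, W = matrix(0, 1, 1), h = 0.2, mu0 = 0.1,
                    Sigma = 0.7)
  ob <- obs_gaussian(matrix(1.5, 1, 1), 0.9)
  X <- matrix(c(1, 2), 2, 1)
  qf <- assemble_quadratic(p, ob, X)
  d <- c(1, 1)
  P <- as.matrix(plrnnssm:::qf_precision(qf, d))
  f <- function(z) plrnnssm:::qf_value(qf, z, d)
  z0 <- c(0.5, 0.4)           # strictly inside the active region
  eps <- 1e-5
  Hfd <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    ei <- ej <- c(0, 0); ei[i] <- eps; ej[j] <- eps
    Hfd[i, j] <- (f(z0 + ei + ej) - f(z0 + ei) - f(z0 + ej) + f(z0)) / eps^2
  }
  expect_equal(-Hfd, P, tolerance = 1e-4)
})

test_that("linear-limit E-step equals the Kalman smoother", {
  for (s in 1:3) {
    inst <- random_lds_instance(M = 3, N = 2, T = 40, seed = s)
    p <- inst$params
    Fm <- diag(p$A) + p$W
    ks <- kalman_smoother(Fm, p$h, diag(p$Sigma), inst$obs$B,
                          diag(inst$obs$Gamma), p$mu0, inst$X)
    post <- estep(p, inst$obs, inst$X)
    expect_lt(max(abs(post$z - ks$mean)), 1e-6)
    expect_lt(max(abs(post$Vtt - ks$cov)), 1e-6)
    expect_lt(max(abs(post$Ct - ks$lag1)), 1e-6)
  }
})

test_that("HRF E-step equals an augmented-state Kalman smoother", {
  set.seed(5)
  M <- 2; T <- 25
  inst <- random_lds_instance(M = M, N = 2, T = T, seed = 5)
  p <- inst$params
  k <- c(1, 0.5)
  obb <- obs_bold(inst$obs$B, inst$obs$Gamma, hrf = k)
  post <- estep(p, obb, inst$X)
  Fm <- diag(p$A) + p$W
  Fa <- rbind(cbind(Fm, matrix(0, M, M)), cbind(diag(M), matrix(0, M, M)))
  Qa <- rbind(cbind(diag(p$Sigma), matrix(0, M, M)),
              cbind(matrix(0, M, M), diag(1e-10, M)))
  Ha <- cbind(k[1] * obb$B, k[2] * obb$B)
  ks <- kalman_smoother(Fa, matrix(c(p$h, rep(0, M)), T, 2 * M, byrow = TRUE),
                        Qa, Ha, diag(obb$Gamma), c(p$mu0, rep(0, M)), inst$X)
  expect_lt(max(abs(post$z - ks$mean[, 1:M])), 1e-6)
  expect_lt(max(abs(post$Vtt - ks$cov[1:M, 1:M, ])), 1e-6)
})

test_that("solve_map beats or matches a multi-start generic optimizer", {
  skipped <- 0
  for (s in 1:10) {
    set.seed(s)
    M <- 2; T <- 5; N <- 2
    W <- matrix(rnorm(4, 0, 0.8), 2, 2); diag(W) <- 0
    p <- plrnn_params(A = runif(M, -0.5, 0.9), W = W, h = rnorm(M),
                      mu0 = rnorm(M), Sigma = runif(M, 0.3, 1.5))
    ob <- obs_gaussian(matrix(rnorm(N * M), N, M), runif(N, 0.3, 1.5))
    X <- matrix(rnorm(T * N), T, N)
    qf <- assemble_quadratic(p, ob, X)
    mp <- solve_map(qf)
    negQ <- function(z) {
      Z <- matrix(z, T, M, byrow = TRUE)
      -direct_joint_logdens(p, ob, X, Z)
    }
    best <- Inf
    for (r in 1:20) {
      o <- optim(rnorm(T * M, 0, 2), negQ, method = "BFGS",
                 control = list(maxit = 500))
      best <- min(best, o$value)
    }
    # compare on the direct-evaluation scale
    expect_gte(direct_joint_logdens(p, ob, X, mp$z), -best - 1e-6)
  }
})

test_that("uninformative observations give the prior-mode path", {
  set.seed(11)
  M <- 2; T <- 20
  W <- matrix(c(0, 0.3, -0.2, 0), 2, 2)
  p <- plrnn_params(A = c(0.6, 0.7), W = W, h = c(0.4, -0.1),
                    mu0 = c(1, -1), Sigma = c(0.5, 0.5))
  ob <- obs_gaussian(diag(2), rep(1e12, 2))   # Gamma -> infinity
  X <- matrix(rnorm(T * 2), T, 2)
  post <- estep(p, ob, X)
  Zdet <- plrnn_generate(p, T, z1 = p$mu0, noise = FALSE)
  expect_lt(max(abs(post$z - Zdet)), 1e-4)
})

test_that("posterior variance follows the scalar precision formula", {
  # M = 1, T = 2, both states active: precision from the three quadratic
  # terms of the objective, inverted by hand
  A <- 0.5; s2 <- 0.7; b <- 1.3; g <- 0.9
  p <- plrnn_params(A = A, W = matrix(0, 1, 1), h = 0.4, mu0 = 0.2,
                    Sigma = s2)
  ob <- obs_gaussian(matrix(b, 1, 1), g)
  X <- matrix(c(2, 3), 2, 1)            # pushes both states positive
  qf <- assemble_quadratic(p, ob, X)
  pc <- posterior_covariance(qf, c(1, 1))
  Phand <- matrix(c(1 / s2 + A^2 / s2 + b^2 / g, -A / s2,
                    -A / s2, 1 / s2 + b^2 / g), 2, 2)
  Vhand <- solve(Phand)
  expect_equal(pc$Vtt[1, 1, 1], Vhand[1, 1], tolerance = 1e-10)
  expect_equal(pc$Vtt[1, 1, 2], Vhand[2, 2], tolerance = 1e-10)
  expect_equal(pc$Clag[[1]][1, 1, 1], Vhand[1, 2], tolerance = 1e-10)
})

test_that("extra observations never inflate marginal variances (linear)", {
  inst <- random_lds_instance(M = 2, N = 2, T = 15, seed = 9)
  qf1 <- assemble_quadratic(inst$params, inst$obs, inst$X)
  ob2 <- inst$obs; ob2$Gamma <- ob2$Gamma / 4    # sharper observations
  qf2 <- assemble_quadratic(inst$params, ob2, inst$X)
  d <- rep(1, 30)
  V1 <- posterior_covariance(qf1, d)$Vtt
  V2 <- posterior_covariance(qf2, d)$Vtt
  for (t in 1:15)
    expect_true(all(diag(V2[, , t]) <= diag(V1[, , t]) + 1e-12))
})

test_that("expected joint log-lik at a point mass equals direct evaluation", {
  set.seed(13)
  M <- 2; T <- 8
  W <- matrix(c(0, 0.4, -0.3, 0), 2, 2)
  p <- plrnn_params(A = c(0.5, 0.6), W = W, h = c(0.2, -0.2),
                    mu0 = c(0, 0), Sigma = c(0.8, 1.1))
  ob <- obs_gaussian(matrix(rnorm(2 * M), 2, M), c(0.7, 1.3))
  X <- matrix(rnorm(T * 2), T, 2)
  Z <- matrix(rnorm(T * M), T, M)
  eps <- 1e-16
  Vtt <- array(diag(eps, M), c(M, M, T))
  Ct <- array(0, c(M, M, T - 1))
  mom <- posterior_moments(Z, Vtt, Ct, linear = FALSE)
  post <- structure(c(list(z = Z, Vtt = Vtt, Ct = Ct,
                           Clag = list(Ct)), mom),
                    class = "plrnn_posterior")
  ll <- expected_joint_loglik(p, ob, post, X)
  const <- -0.5 * T * sum(log(2 * pi * p$Sigma)) -
    0.5 * T * sum(log(2 * pi * ob$Gamma))
  expect_equal(ll, direct_joint_logdens(p, ob, X, Z) + const,
               tolerance = 1e-6)
})

test_that("solve_map terminates and returns a consistent configuration", {
  for (s in 1:5) {
    set.seed(100 + s)
    M <- 3; T <- 30
    W <- matrix(rnorm(9, 0, 0.5), 3, 3); diag(W) <- 0
    p <- plrnn_params(A = runif(M, 0, 0.9), W = W, h = rnorm(M),
                      mu0 = rnorm(M), Sigma = runif(M, 0.3, 1.5))
    ob <- obs_gaussian(matrix(rnorm(2 * M), 2, M), runif(2, 0.3, 1.5))
    X <- matrix(rnorm(T * 2), T, 2)
    qf <- assemble_quadratic(p, ob, X)
    mp <- solve_map(qf)
    expect_lte(mp$n_rounds, 100 * 6)     # per-start cap times starts
    # the returned indicator always matches the returned path; a fully
    # interior-consistent configuration need not exist (the optimum can
    # sit on a region boundary), in which case the best polished
    # boundary solution is returned instead
    expect_equal(as.numeric(mp$z_map > 0), mp$d_omega)
    expect_true(is.finite(mp$Q))
  }
})

test_that("E-step runtime scales roughly linearly in T", {
  set.seed(17)
  M <- 4
  W <- matrix(rnorm(16, 0, 0.2), 4, 4); diag(W) <- 0
  p <- plrnn_params(A = runif(M, 0.3, 0.8), W = W, h = rnorm(M),
                    Sigma = rep(0.5, M))
  ob <- obs_gaussian(matrix(rnorm(3 * M), 3, M), rep(0.5, 3))
  tm <- vapply(c(100, 400), function(T) {
    X <- matrix(rnorm(T * 3), T, 3)
    st <- proc.time()
    estep(p, ob, X, max_rounds = 5)
    (proc.time() - st)[3]
  }, 0)
  # 4x the data should cost clearly less than ~16x (quadratic) time;
  # generous bound to stay robust on loaded machines
  expect_lt(tm[2], max(8 * tm[1], tm[1] + 2))
})
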