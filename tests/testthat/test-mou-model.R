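test_that("Jacobian encodes leakage and the source-to-target convention", {
  # single region: leakage only
  expect_equal(jacobian(mou(matrix(0, 1, 1), tau = 2)), -0.5,
               ignore_attr = TRUE)
  # connection 1 -> 2 appears at J[2, 1]
  m <- mou(matrix(c(0, 0.3, 0, 0), 2, 2, byrow = TRUE), tau = 1)
  expect_equal(unname(jacobian(m)), matrix(c(-1, 0.3, 0, -1), 2, 2))
  # column sums of J = column sums of t(C) minus 1/tau
  m5 <- rand_mou(5, seed = 11)
  expect_equal(colSums(jacobian(m5)), colSums(t(m5$ec)) - 1 / m5$tau,
               ignore_attr = TRUE)
})

test_that("stability is decided by the Jacobian spectrum", {
  m0 <- mou(matrix(0, 3, 3), tau = 4)
  st <- is_stable(m0)
  expect_true(st)
  expect_equal(attr(st, "margin"), -0.25)
  # reciprocal weight 2 at tau = 1: eigenvalues -1 +- 2, unstable
  m2 <- mou(matrix(c(0, 2, 2, 0), 2, 2), tau = 1)
  st2 <- is_stable(m2)
  expect_false(st2)
  expect_equal(attr(st2, "margin"), 1, tolerance = 1e-12)
  expect_true(is_stable(rand_mou(8, seed = 2)))
  expect_error(stationary_cov(m2), "unstable")
})

test_that("stationary covariance solves the Lyapunov equation", {
  # scalar closed form Q0 = sigma^2 tau / 2
  expect_equal(stationary_cov(mou(matrix(0, 1, 1), sigma = 1, tau = 2)),
               matrix(1), ignore_attr = TRUE)
  # decoupled regions: Q0 = diag(sigma_ii tau / 2)
  sig <- c(1, 2, 0.5)
  Q0 <- stationary_cov(mou(matrix(0, 3, 3), sigma = sig, tau = 3))
  expect_equal(unname(Q0), diag(sig * 3 / 2))
  # residual property over random instances
  for (s in 1:20) {
    m <- rand_mou(6, seed = s, sigma = runif(6, 0.5, 2))
    J <- jacobian(m)
    Q <- stationary_cov(m)
    res <- norm(J %*% Q + Q %*% t(J) + m$sigma, "F") / norm(m$sigma, "F")
    expect_lte(res, 1e-10)
    expect_gt(min(eigen(Q, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("stationary covariance matches the quadrature integral oracle", {
  # independent route: Q0 = integral of expm(J s) Sigma expm(J' s) ds
  # by Simpson quadrature with Matrix::expm
  m <- rand_mou(6, seed = 5, sigma = runif(6, 0.5, 2))
  J <- jacobian(m)
  upper <- 60 * m$tau
  ns <- 4000
  h <- upper / ns
  acc <- matrix(0, 6, 6)
  for (k in 0:ns) {
    E <- as.matrix(Matrix::expm(Matrix::Matrix(J * (k * h))))
    wk <- if (k == 0 || k == ns) 1 else if (k %% 2 == 1) 4 else 2
    acc <- acc + wk * (E %*% m$sigma %*% t(E))
  }
  Q_quad <- acc * h / 3
  Q0 <- stationary_cov(m)
  expect_lt(norm(Q0 - Q_quad, "F") / norm(Q_quad, "F"), 1e-6)
})

test_that("lagged covariance decays correctly", {
  m <- rand_mou(6, seed = 3)
  expect_equal(lagged_cov(m, 0), stationary_cov(m))
  # scalar: Q_lag = Q0 exp(-lag/tau)
  m1 <- mou(matrix(0, 1, 1), sigma = 1, tau = 2)
  expect_equal(lagged_cov(m1, 2), matrix(exp(-1)), ignore_attr = TRUE)
  # uncoupled autocovariance exactly Q0_ii exp(-lag/tau) at lags 0, tau, 2 tau
  mu <- mou(matrix(0, 4, 4), sigma = c(1, 2, 3, 4), tau = 3)
  Q0 <- stationary_cov(mu)
  for (lag in c(0, 3, 6))
    expect_equal(diag(lagged_cov(mu, lag)), diag(Q0) * exp(-lag / 3),
                 tolerance = 1e-12)
  # vanishing at long lags
  expect_lt(norm(lagged_cov(m, 50 * m$tau), "F"), 1e-8 * norm(stationary_cov(m), "F"))
  expect_error(lagged_cov(m, -1), "nonnegative")
})

test_that("simulation is reproducible and near-noiseless when sigma -> 0", {
  m <- rand_mou(4, seed = 9)
  s1 <- simulate(m, nsim = 50, seed = 123, tr = 2)
  s2 <- simulate(m, nsim = 50, seed = 123, tr = 2)
  expect_identical(s1$data, s2$data)
  s3 <- simulate(m, nsim = 50, seed = 124, tr = 2)
  expect_false(identical(s1$data, s3$data))
  mq <- mou(m$ec, sigma = rep(1e-12, 4), tau = m$tau)
  sq <- simulate(mq, nsim = 20, seed = 1, tr = 2)
  expect_lt(max(abs(sq$data)), 1e-4)
  expect_error(simulate(m, nsim = 50, tr = 2, dt = 1), "dt")
})

test_that("simulated covariances converge to the theoretical ones", {
  m <- rand_mou(6, seed = 4)
  sess <- simulate(m, nsim = 2e4, seed = 7, tr = 2)
  emp <- empirical_covariances(sess)
  Q0 <- stationary_cov(m)
  Q1 <- lagged_cov(m, 2)
  expect_lt(norm(emp$q0 - Q0, "F") / norm(Q0, "F"), 0.07)
  expect_lt(norm(emp$q1 - Q1, "F") / norm(Q1, "F"), 0.12)
})

test_that("model validation rejects malformed parameters", {
  expect_error(mou(matrix(c(0, -0.1, 0, 0), 2, 2), tau = 1), "nonnegative")
  expect_error(mou(matrix(c(0.1, 0, 0, 0), 2, 2), tau = 1), "diagonal")
  expect_error(mou(matrix(0, 2, 2), tau = -1), "positive")
  expect_error(mou(matrix(0, 2, 2), sigma = c(1, -1), tau = 1), "positive")
  bad_sig <- matrix(c(1, 2, 2, 1), 2, 2)  # indefinite
  expect_error(mou(matrix(0, 2, 2), sigma = bad_sig, tau = 1), "semidefinite")
})
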