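test_that("communicability vanishes at t = 0, for empty networks, and at long times", {
  m <- rand_mou(6, seed = 10)
  tg <- seq(0, 50 * m$tau, length.out = 21)
  ft <- dynamic_communicability(m, t_grid = tg)
  expect_equal(unclass(ft)[, , 1], matrix(0, 6, 6), ignore_attr = TRUE)
  expect_lt(max(abs(unclass(ft)[, , 21])), 1e-10)
  m0 <- mou(matrix(0, 6, 6), tau = 2)
  ft0 <- dynamic_communicability(m0, t_grid = c(0, 1, 5))
  expect_equal(max(abs(ft0)), 0)
})

test_that("small-t communicability matches its Taylor expansion", {
  # (expm(J t) - expm(J0 t)) = t (J - J0) + t^2 (J^2 - J0^2)/2 + O(t^3);
  # at t = 0.01 tau the remainder is far below 1e-4 relative
  m <- rand_mou(6, seed = 12)
  t_small <- 0.01 * m$tau
  ft <- dynamic_communicability(m, t_grid = c(0, t_small))
  J <- jacobian(m)
  J0 <- diag(-1 / m$tau, 6)
  taylor <- t(t_small * (J - J0) +
                t_small^2 * (J %*% J - J0 %*% J0) / 2) / (6 / m$tau)
  expect_lt(max(abs(unclass(ft)[, , 2] - taylor)) / max(abs(taylor)), 1e-4)
})

test_that("flow reduces to communicability for unit input and scales with sqrt(Sigma)", {
  m <- rand_mou(5, seed = 13)
  tg <- seq(0, 10, by = 1)
  comm <- dynamic_communicability(m, t_grid = tg)
  flow <- dynamic_flow(m, t_grid = tg)
  expect_identical(unclass(flow)[, , ], unclass(comm)[, , ])
  m4 <- mou(m$ec, sigma = 4, tau = m$tau)
  flow4 <- dynamic_flow(m4, t_grid = tg)
  expect_equal(unclass(flow4)[, , ], 2 * unclass(comm)[, , ])
  # silencing a source zeroes its row at all times
  sig <- rep(1, 5); sig[3] <- 1e-300
  m0 <- mou(m$ec, sigma = sig, tau = m$tau)
  flow0 <- dynamic_flow(m0, t_grid = tg)
  expect_lt(max(abs(unclass(flow0)[3, , ])), 1e-140)
})

test_that("total flow of a single link matches the 2x2 analytic form", {
  # 1 -> 2 with weight w: J lower-triangular with equal diagonal, so
  # expm(J t) = exp(-t/tau) [[1, 0], [w t, 1]] and
  # total flow(t) = tau w t exp(-t/tau) / 2
  w <- 0.4; tau <- 2
  m <- mou(matrix(c(0, w, 0, 0), 2, 2, byrow = TRUE), tau = tau)
  tg <- seq(0, 10, by = 0.5)
  ft <- dynamic_communicability(m, t_grid = tg)
  expect_equal(as.numeric(total_flow(ft)), tau * w * tg * exp(-tg / tau) / 2,
               tolerance = 1e-10)
  # all the interaction is sourced at 1 and received at 2
  io <- input_output_flow(ft)
  expect_equal(io$output[2, ], rep(0, length(tg)), ignore_attr = TRUE)
  expect_equal(io$input[1, ], rep(0, length(tg)), ignore_attr = TRUE)
})

test_that("input and output flows conserve the total flow", {
  m <- rand_mou(7, seed = 14, sigma = runif(7, 0.5, 2))
  ft <- dynamic_flow(m, t_grid = seq(0, 20, by = 2))
  io <- input_output_flow(ft)
  tot <- total_flow(ft)
  expect_lt(max(abs(colSums(io$input) - tot)), 1e-12)
  expect_lt(max(abs(colSums(io$output) - tot)), 1e-12)
  # permutation equivariance
  p <- c(3, 1, 7, 2, 6, 4, 5)
  mp <- mou(m$ec[p, p], sigma = diag(m$sigma)[p], tau = m$tau)
  iop <- input_output_flow(dynamic_flow(mp, t_grid = seq(0, 20, by = 2)))
  expect_equal(iop$input, io$input[p, ], ignore_attr = TRUE)
  expect_equal(iop$output, io$output[p, ], ignore_attr = TRUE)
})

test_that("flow diversity behaves like a coefficient of variation", {
  n <- 4
  mk <- function(M) structure(array(M, c(n, n, 1)), t_grid = 0,
                              kind = "flow", norm_constant = 1,
                              class = "flow_tensor")
  expect_equal(as.numeric(flow_diversity(mk(matrix(2, n, n)))), 0)
  one_hot <- matrix(0, n, n); one_hot[2, 3] <- 5
  expect_equal(as.numeric(flow_diversity(mk(one_hot))), sqrt(n^2 - 1))
  M <- matrix(runif(n^2), n, n)
  expect_equal(as.numeric(flow_diversity(mk(M))),
               as.numeric(flow_diversity(mk(10 * M))))
  expect_true(is.na(flow_diversity(mk(matrix(0, n, n)))))
})

test_that("planted two-block structure is recovered exactly", {
  m <- two_block_mou(seed = 20)
  ft <- dynamic_flow(m, t_grid = seq(0, 8, by = 1))
  part <- detect_communities(ft, t = 2, n_runs = 10, seed = 0)
  expect_equal(length(unique(part)), 2L)
  expect_equal(length(unique(part[1:5])), 1L)
  expect_equal(length(unique(part[6:10])), 1L)
  # relabeled input gives the same partition up to renaming
  p <- c(6:10, 1:5)
  mp <- mou(m$ec[p, p], sigma = 1, tau = m$tau)
  ftp <- dynamic_flow(mp, t_grid = seq(0, 8, by = 1))
  partp <- detect_communities(ftp, t = 2, n_runs = 10, seed = 0)
  agree <- outer(part, part, `==`) == outer(partp[order(p)], partp[order(p)], `==`)
  expect_true(all(agree))
})

test_that("degenerate flow matrices are rejected for community detection", {
  m0 <- mou(matrix(0, 4, 4), tau = 2)
  ft0 <- dynamic_communicability(m0, t_grid = c(0, 1))
  expect_error(detect_communities(ft0, t = 1), "homogeneous")
  m <- rand_mou(4, seed = 1)
  ft <- dynamic_communicability(m, t_grid = c(0, 1))
  expect_error(detect_communities(ft, t = 0.37), "t_grid")
})

test_that("coparticipation counts shared community membership", {
  p1 <- setNames(c(1L, 1L, 2L, 2L), paste0("ROI", 1:4))
  p2 <- setNames(c(1L, 2L, 2L, 2L), paste0("ROI", 1:4))
  cr <- coparticipation(list(p1, p1))
  expect_true(all(cr$coparticipation %in% c(0, 1)))
  expect_equal(diag(cr$coparticipation), rep(1, 4), ignore_attr = TRUE)
  cr2 <- coparticipation(list(p1, p2))
  expect_equal(cr2$coparticipation["ROI1", "ROI2"], 0.5)
  expect_error(coparticipation(list(p1, p2[c(2, 1, 3, 4)])), "same region set")
})

test_that("coparticipation across noisy subjects separates the planted blocks", {
  parts <- lapply(1:20, function(s) {
    m <- two_block_mou(seed = 100 + s, jitter = 0.3)
    ft <- dynamic_flow(m, t_grid = c(0, 2))
    detect_communities(ft, t = 2, n_runs = 5, seed = s)
  })
  cr <- coparticipation(parts)
  cp <- cr$coparticipation
  within <- c(cp[1:5, 1:5][upper.tri(cp[1:5, 1:5])],
              cp[6:10, 6:10][upper.tri(cp[6:10, 6:10])])
  between <- cp[1:5, 6:10]
  expect_gt(mean(within), mean(between))
})

test_that("communities merge as integration time grows", {
  m <- two_block_mou(seed = 30, jitter = 0.2)
  # weak cross-block coupling so late-time flow globalizes
  C <- m$ec
  C[1, 6] <- C[6, 1] <- 0.05
  repeat {
    mm <- mou(C, sigma = 1, tau = m$tau)
    if (is_stable(mm)) break
    C <- C * 0.8
  }
  tg <- c(0, 0.5 * mm$tau, 10 * mm$tau)
  ft <- dynamic_flow(mm, t_grid = tg)
  early <- detect_communities(ft, t = 0.5 * mm$tau, n_runs = 10, seed = 0)
  late <- detect_communities(ft, t = 10 * mm$tau, n_runs = 10, seed = 0)
  expect_lte(length(unique(late)), length(unique(early)))
})
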