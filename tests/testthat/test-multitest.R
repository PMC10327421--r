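test_that("normal transform: analytic identities and stability", {
  expect_equal(normal_transform(0, 3), 0)
  expect_equal(normal_transform(c(0, 0), 7), c(0, 0))
  # M = 1: N = |z| exactly for zeta = z^2
  z <- c(0.3, 1.7, 2.9)
  expect_equal(normal_transform(z^2, 1), z, tolerance = 1e-10)
  # chi-square median maps to the upper quartile of the normal
  med <- qchisq(0.5, df = 4)
  expect_equal(normal_transform(med, 4), qnorm(0.25, lower.tail = FALSE),
               tolerance = 1e-10)
  # very large statistics stay finite and ordered
  big <- normal_transform(c(500, 1000, 5000), 3)
  expect_true(all(is.finite(big)) && all(diff(big) > 0))
})

test_that("threshold search reproduces the closed-form examples", {
  # q = 100, all statistics at 10: condition first holds at Phibar^{-1}(0.05)
  out <- find_threshold(rep(10, 100), alpha = 0.1)
  expect_equal(out$t_hat, qnorm(0.05, lower.tail = FALSE), tolerance = 1e-10)
  expect_length(out$rejected, 100)
  expect_true(out$attained)
  # all zeros: no qualifying t, fall back to sqrt(2 log q), nothing rejected
  out0 <- find_threshold(rep(0, 50), alpha = 0.1)
  expect_false(out0$attained)
  expect_equal(out0$t_hat, sqrt(2 * log(50)))
  expect_length(out0$rejected, 0)
})

test_that("threshold is nonincreasing in alpha and matches a dense grid search", {
  set.seed(90)
  N <- abs(rnorm(200)) + c(rep(3, 12), rep(0, 188))
  alphas <- c(0.02, 0.05, 0.1, 0.2, 0.4)
  ths <- sapply(alphas, function(a) find_threshold(N, a)$t_hat)
  expect_true(all(diff(ths) <= 1e-12))
  # dense grid equivalence
  q <- length(N)
  t_q <- sqrt(2 * log(q) - 2 * log(log(q)))
  grid <- seq(0, t_q, length.out = 400000)
  Ns <- sort(N)
  R_grid <- q - findInterval(grid, Ns, left.open = TRUE)  # #{N >= t}
  for (a in c(0.05, 0.2)) {
    ok <- grid[2 * q * pnorm(grid, lower.tail = FALSE) /
                 pmax(R_grid, 1) <= a]
    t_grid <- if (length(ok)) min(ok) else sqrt(2 * log(q))
    expect_equal(find_threshold(N, a)$t_hat, t_grid,
                 tolerance = 2 * t_q / 400000 + 1e-9)
  }
})

test_that("BH comparator searches an unbounded range", {
  N <- rep(10, 100)
  expect_equal(bh_threshold(N, 0.1), qnorm(0.05, lower.tail = FALSE),
               tolerance = 1e-10)
  # the capped rule falls back while BH still finds a huge threshold
  N2 <- rep(0, 50)
  expect_true(is.finite(bh_threshold(N2, 0.1)))
  expect_gt(bh_threshold(N2, 0.1), sqrt(2 * log(50)))
})

test_that("error metrics count false and true discoveries with the R v 1 guard", {
  H <- 2:51
  expect_equal(error_metrics(integer(0), 2:11, H), list(fdp = 0, power = 0))
  expect_equal(error_metrics(2:11, 2:11, H), list(fdp = 0, power = 1))
  expect_equal(error_metrics(2:11, 3:11, H)$fdp, 0.1)
})

test_that("null-contrast statistics cancel identical folds and stay nonnegative", {
  d <- 5; M <- 2; q <- 4
  U <- array(rnorm(d * M * q), c(d, M, q))
  proj <- list(list(U = U, targets = 2:5), list(U = U, targets = 2:5))
  s2k <- list(list(xi_t = rnorm(d), H_t = diag(d), J_t = diag(d)),
              list(xi_t = rnorm(d), H_t = diag(d), J_t = diag(d)))
  s2 <- list(s2k, s2k)  # identical folds
  B <- matrix(rnorm(M * d), M, d)
  zn <- null_statistics(list(B, B), proj, s2, n_m = c(40, 60),
                        sigma_hat = matrix(1, M, q))
  expect_equal(zn, rep(0, q), tolerance = 1e-12)
  # odd K rejected
  expect_error(null_statistics(list(B), proj[1], s2[1], c(40, 60),
                               matrix(1, M, q)), "even")
  # generic inputs: nonnegative
  s2b <- s2; s2b[[2]][[1]]$xi_t <- s2b[[2]][[1]]$xi_t + 1
  zb <- null_statistics(list(B, B), proj, s2b, c(40, 60),
                        matrix(1, M, q))
  expect_true(all(zb >= 0))
})

test_that("radius selection rejects overdispersed null statistics", {
  # the tail criterion heavily penalises radii whose null-centred
  # statistics overshoot the chi-square tail; among candidates without
  # tail excess it is conservative (ties resolve to the smaller radius)
  q <- 400; M <- 3
  set.seed(91)
  calibrated <- qchisq(runif(q), df = M)
  deflated <- calibrated * 0.2
  inflated <- calibrated * 5
  nz <- list("0.1" = inflated, "0.2" = calibrated, "0.4" = deflated)
  sel <- select_tau(nz, M = M, H_grid = 10)
  expect_true(sel$chosen != 0.1)
  expect_gt(sel$d_hat[1], max(sel$d_hat[-1]))
  expect_length(sel$d_hat, 3)
  # single-point grid returns that radius
  expect_equal(select_tau(list("0.7" = calibrated), M)$chosen, 0.7)
  # ties break toward the smaller radius
  nz2 <- list("0.5" = deflated, "0.3" = deflated)
  expect_equal(select_tau(nz2, M)$chosen, 0.3)
})

test_that("d_hat implements the tail-averaged squared calibration error", {
  M <- 2; q <- 50
  zeta <- c(rep(30, 3), rep(0.1, q - 3))
  x_top <- pnorm(sqrt(2 * log(q)), lower.tail = FALSE)
  x_h <- x_top * (1:10) / 10
  Fb <- pchisq(zeta, df = M, lower.tail = FALSE)
  manual <- mean(sapply(x_h, function(x) (sum(Fb <= 2 * x) / (2 * q * x) - 1)^2))
  sel <- select_tau(list("1" = zeta), M = M, H_grid = 10)
  expect_equal(sel$d_hat, manual)
})
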