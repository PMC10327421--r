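make_summaries <- function(dat, k = 1, Kp = 3, seed = 9, lambda = 0.05) {
  M <- length(dat$studies)
  plans <- lapply(seq_len(M), function(m)
    make_folds(length(dat$studies[[m]]$Y), 2, Kp, seed + m))
  lapply(seq_len(M), function(m)
    summary_step1(dat$studies[[m]], plans[[m]], k, dat$family, lambda))
}

test_that("penalties at or above lambda_max null every covariate group", {
  dat <- make_linear_fed(M = 3, n = 90, p = 8, s = 3, seed = 51)
  sums <- make_summaries(dat)
  lmax <- group_lambda_max(sums)
  B <- fit_group_lasso(sums, lmax * 1.0001)
  expect_true(all(B[, -1] == 0))
  # intercepts solve the per-study scalar quadratics xi_1 / H_11
  for (m in 1:3) {
    expect_equal(B[m, 1], sums[[m]]$xi[1] / sums[[m]]$H[1, 1],
                 tolerance = 1e-8)
  }
  # just below lambda_max at least one group activates
  B2 <- fit_group_lasso(sums, lmax * 0.95)
  expect_gt(sum(B2[, -1] != 0), 0)
})

test_that("single study at lambda = 0 solves the normal equations", {
  dat <- make_linear_fed(M = 1, n = 80, p = 6, s = 2, seed = 52)
  sums <- make_summaries(dat)
  B <- fit_group_lasso(sums, 0, tol = 1e-10)
  direct <- drop(solve(sums[[1]]$H, sums[[1]]$xi))
  expect_equal(B[1, ], direct, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("group KKT conditions hold at the solution", {
  dat <- make_linear_fed(M = 3, n = 90, p = 8, s = 3, seed = 53)
  sums <- make_summaries(dat)
  lam <- 0.5 * group_lambda_max(sums)
  B <- fit_group_lasso(sums, lam, tol = 1e-9)
  nw <- vapply(sums, `[[`, 0, "n_used"); wbar <- nw / sum(nw)
  G <- sapply(seq_along(sums), function(m)
    2 * wbar[m] * drop(sums[[m]]$H %*% B[m, ] - sums[[m]]$xi))
  gn <- sqrt(rowSums(G^2))
  active <- setdiff(which(colSums(B != 0) > 0), 1L)
  inactive <- setdiff(2:ncol(B), active)
  expect_true(all(gn[inactive] <= lam + 1e-6))
  for (j in active) {
    # gradient must equal -lam * B_j / ||B_j||
    expect_equal(G[j, ], -lam * B[, j] / sqrt(sum(B[, j]^2)),
                 tolerance = 1e-5)
  }
  # intercept stationarity (unpenalised)
  expect_true(all(abs(G[1, ]) < 1e-7))
})

test_that("solution is invariant to study ordering", {
  dat <- make_linear_fed(M = 3, n = 90, p = 8, s = 3, seed = 54)
  sums <- make_summaries(dat)
  lam <- 0.4 * group_lambda_max(sums)
  B <- fit_group_lasso(sums, lam, tol = 1e-9)
  Bp <- fit_group_lasso(sums[c(3, 1, 2)], lam, tol = 1e-9)
  expect_equal(Bp, B[c(3, 1, 2), ], tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("summary-statistic fit equals the pooled individual-level fit (linear family)", {
  # with phiddot = 1 the Step-1 moments are exact sufficient statistics,
  # so no information is lost to the data-sharing constraint
  dat <- make_linear_fed(M = 2, n = 120, p = 10, s = 3, seed = 55)
  k <- 1
  plans <- lapply(1:2, function(m) make_folds(120, 2, 3, 9 + m))
  sums <- lapply(1:2, function(m)
    summary_step1(dat$studies[[m]], plans[[m]], k, "linear", 0.05))
  lam <- 0.3 * group_lambda_max(sums)
  B <- fit_group_lasso(sums, lam, tol = 1e-10)
  Xs <- lapply(1:2, function(m)
    dat$studies[[m]]$X[plans[[m]]$outer != k, ])
  Ys <- lapply(1:2, function(m)
    dat$studies[[m]]$Y[plans[[m]]$outer != k])
  B_or <- oracle_pooled_group_lasso(Xs, Ys, lam)
  expect_lt(oracle_pooled_objective(Xs, Ys, t(B), lam) -
              oracle_pooled_objective(Xs, Ys, B_or, lam), 1e-6)
  expect_equal(t(B), B_or, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("GIC degrees of freedom: identity at lambda = 0 and dense oracle", {
  dat <- make_linear_fed(M = 2, n = 80, p = 5, s = 2, seed = 56)
  sums <- make_summaries(dat)
  B <- fit_group_lasso(sums, 0, tol = 1e-10)
  g0 <- gic(sums, B, 0)
  expect_equal(g0$df, sum(B != 0), tolerance = 1e-6)
  # beta = 0: Dev = 0
  gz <- gic(sums, matrix(0, 2, 6), 0.1)
  expect_equal(gz$dev, 0)
  # dense-matrix oracle at lambda > 0
  lam <- 0.3 * group_lambda_max(sums)
  B1 <- fit_group_lasso(sums, lam, tol = 1e-10)
  g1 <- gic(sums, B1, lam)
  act <- which(t(B1) != 0, arr.ind = TRUE)  # (j, m)
  nact <- nrow(act)
  nw <- vapply(sums, `[[`, 0, "n_used"); wbar <- nw / sum(nw)
  A <- matrix(0, nact, nact); P <- matrix(0, nact, nact)
  for (a in seq_len(nact)) for (b in seq_len(nact)) {
    if (act[a, 2] == act[b, 2])
      A[a, b] <- 2 * wbar[act[a, 2]] * sums[[act[a, 2]]]$H[act[a, 1], act[b, 1]]
    ja <- act[a, 1]
    if (ja == act[b, 1] && ja > 1) {
      r <- sqrt(sum(B1[, ja]^2))
      P[a, b] <- lam * ((act[a, 2] == act[b, 2]) / r -
                          B1[act[a, 2], ja] * B1[act[b, 2], ja] / r^3)
    }
  }
  expect_equal(g1$df, sum(diag(solve(A + P, A))), tolerance = 1e-8)
})

test_that("penalty selection returns grid bookkeeping and screens the support", {
  one <- make_linear_fed(M = 2, n = 100, p = 8, s = 2, mu = 1.2, seed = 57)
  sums <- make_summaries(one)
  # single-point grid
  sel1 <- select_lambda(sums, grid = 0.05)
  expect_equal(sel1$lambda, 0.05)
  sel <- select_lambda(sums)
  expect_equal(nrow(sel$path), 25)
  expect_true(all(diff(sel$path$lambda) < 0))
  # strong signals: the selected support covers the truth
  active <- which(colSums(sel$B[, -1, drop = FALSE] != 0) > 0) + 1L
  expect_true(all(one$truth$support %in% active))
})

test_that("integrative estimation error decreases with sample size", {
  errs <- sapply(c(80, 400), function(n) {
    dat <- make_linear_fed(M = 2, n = n, p = 10, s = 3, mu = 0.8, seed = 58)
    sums <- lapply(1:2, function(m)
      summary_step1(dat$studies[[m]], make_folds(n, 2, 4, 60 + m), 1,
                    "linear", 0.5 * sqrt(log(10) / n)))
    sel <- select_lambda(sums)
    sum(sqrt(colSums((t(sel$B) - t(dat$truth$B))^2)))
  })
  expect_lt(errs[2], errs[1])
})
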