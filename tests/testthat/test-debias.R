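test_that("identity Hessians give the analytic projection directions", {
  H <- replicate(2, diag(3), simplify = FALSE)
  r <- solve_group_dantzig(H, j = 2, tau = 0.1, tol = 1e-9, feas_tol = 1e-9)
  # symmetric optimum: u_j = 1 - tau/sqrt(M) in each study, zeros elsewhere
  expect_equal(r$objective, 1 - 0.1 / sqrt(2), tolerance = 1e-6)
  expect_equal(r$U[2, 1, 1], 1 - 0.1 / sqrt(2), tolerance = 1e-6)
  expect_equal(r$U[c(1, 3), , 1], matrix(0, 2, 2), tolerance = 1e-7)
  # tau >= sqrt(M): the zero vector is feasible and optimal
  r0 <- solve_group_dantzig(H, j = 2, tau = sqrt(2) + 1e-9, tol = 1e-9)
  expect_equal(r0$objective, 0, tolerance = 1e-9)
  expect_true(all(r0$U == 0))
})

test_that("solutions match independent convex-solver reference objectives", {
  for (ref in dantzig_reference) {
    H <- dantzig_test_instance(ref$seed, ref$d, ref$M)
    r <- solve_group_dantzig(H, j = ref$j, tau = ref$tau,
                             tol = 1e-9, feas_tol = 1e-9, maxit = 200000)
    expect_lt(abs(r$objective - ref$obj), 1e-6)
    # certificate re-checked outside the solver
    resid <- sapply(seq_len(ref$d), function(l) {
      sqrt(sum(sapply(seq_len(ref$M), function(m) {
        (sum(H[[m]][l, ] * r$U[, m, 1]) - (l == ref$j))^2
      })))
    })
    expect_lt(max(resid), ref$tau + 1e-7)
  }
})

test_that("objective is nonincreasing in tau", {
  H <- dantzig_test_instance(99, 6, 2)
  objs <- sapply(c(0.2, 0.35, 0.5, 0.8), function(tau) {
    solve_group_dantzig(H, j = 3, tau = tau, tol = 1e-8,
                        feas_tol = 1e-8)$objective
  })
  expect_true(all(diff(objs) <= 1e-6))
})

test_that("results do not depend on target ordering and reuse one factorisation", {
  H <- dantzig_test_instance(101, 8, 2)
  r_all <- solve_group_dantzig(H, j = 2:6, tau = 0.4, tol = 1e-8)
  r_rev <- solve_group_dantzig(H, j = 6:2, tau = 0.4, tol = 1e-8)
  expect_equal(r_all$U[, , 1], r_rev$U[, , 5], tolerance = 1e-5)
  expect_equal(sort(r_all$objective), sort(r_rev$objective), tolerance = 1e-6)
})

test_that("infeasible radii raise the typed condition", {
  # rank-deficient Hessian: e_j outside the attainable range for tiny tau
  x <- c(1, 0.5, 0.25)
  H <- list(tcrossprod(x))  # rank 1
  expect_error(solve_group_dantzig(H, j = 2, tau = 1e-4, maxit = 3000),
               class = "dsilt_dantzig_infeasible")
})

test_that("debiased coefficients: exact identities", {
  # noiseless linear data, beta_tilde = beta_0: corrections vanish
  dat <- make_linear_fed(M = 2, n = 60, p = 5, s = 2, seed = 71, noise_sd = 0)
  plans <- lapply(1:2, function(m) make_folds(60, 2, 3, 80 + m))
  B0 <- dat$truth$B
  s2 <- lapply(1:2, function(k) lapply(1:2, function(m)
    summary_step2(dat$studies[[m]], plans[[m]], k, B0[m, ], "linear")))
  d <- 6; q <- 5
  U <- array(0, c(d, 2, q))
  for (jj in 1:q) U[jj + 1, , jj] <- 1  # u = e_j rows
  proj <- lapply(1:2, function(k) list(U = U, targets = 2:6))
  bb <- debias_coefficients(list(B0, B0), proj, s2)
  expect_equal(bb, B0[, 2:6], tolerance = 1e-10, ignore_attr = TRUE)
  # u = e_j extracts the plain coordinate correction
  Bw <- B0; Bw[, 2] <- Bw[, 2] + 0.3   # wrong coefficient
  bb2 <- debias_coefficients(list(Bw, Bw), proj, lapply(1:2, function(k)
    lapply(1:2, function(m)
      summary_step2(dat$studies[[m]], plans[[m]], k, Bw[m, ], "linear"))))
  manual <- sapply(1:2, function(m) {
    mean(sapply(1:2, function(k) {
      s <- summary_step2(dat$studies[[m]], plans[[m]], k, Bw[m, ], "linear")
      Bw[m, 2] + (s$xi_t - drop(s$H_t %*% Bw[m, ]))[2]
    }))
  })
  expect_equal(bb2[, 1], manual, tolerance = 1e-10)
})

test_that("variance estimates: unit-vector identity, positivity, floor", {
  d <- 4; q <- 2
  U <- array(0, c(d, 1, q)); U[2, 1, 1] <- 1; U[3, 1, 2] <- 1
  J1 <- diag(c(1, 2, 3, 4)); J2 <- diag(c(2, 4, 6, 8))
  s2 <- list(list(list(J_t = J1)), list(list(J_t = J2)))
  proj <- list(list(U = U), list(U = U))
  v <- estimate_variance(proj, s2)
  expect_equal(v[1, ], c(mean(c(2, 4)), mean(c(3, 6))))
  # zero directions are floored with a warning
  U0 <- array(0, c(d, 1, 1))
  expect_warning(
    v0 <- estimate_variance(list(list(U = U0)), list(list(list(J_t = J1)))),
    "floored")
  expect_equal(v0[1, 1], 1e-12)
})

test_that("group statistics: zeros, sum of ones, and positivity", {
  expect_equal(group_statistic(matrix(0, 3, 4), matrix(1, 3, 4), c(10, 20, 30)),
               rep(0, 4))
  # n_m * (b/s)^2 = 1 per study -> zeta = M
  b <- matrix(1 / sqrt(c(10, 20, 30)), 3, 2)
  s <- matrix(1, 3, 2)
  expect_equal(group_statistic(b, s, c(10, 20, 30)), rep(3, 2))
  expect_error(group_statistic(b, -s, c(10, 20, 30)))
})
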