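test_that("fold plans partition, balance, and respect the even-K rule", {
  plan <- make_folds(10, 2, 5, seed = 1)
  expect_equal(sort(tabulate(plan$outer)), c(5, 5))
  for (k in 1:2) {
    inner <- plan$inner[[k]]
    expect_equal(which(is.na(inner)), which(plan$outer == k))
    expect_equal(sort(tabulate(inner[!is.na(inner)])), rep(1, 5))
  }
  plan2 <- make_folds(11, 2, 2, seed = 2)
  expect_equal(sort(tabulate(plan2$outer)), c(5, 6))
  # inner folds of every k partition the complement
  for (k in 1:2) {
    expect_setequal(which(!is.na(plan2$inner[[k]])), which(plan2$outer != k))
  }
  expect_error(make_folds(30, 3, 2, seed = 1), "even")
  expect_identical(make_folds(40, 4, 2, seed = 7), make_folds(40, 4, 2, seed = 7))
})

test_that("local lasso: full shrinkage, least-squares limit, and KKT", {
  set.seed(20)
  n <- 80; p <- 6
  X <- cbind(1, matrix(rnorm(n * p), n))
  beta0 <- c(0.3, 1, -0.8, rep(0, p - 2))
  Y <- rbinom(n, 1, plogis(drop(X %*% beta0)))
  # lambda -> infinity: null fit with intercept at logit(mean(Y))
  b_inf <- dsilt:::local_lasso_at(X, Y, ds_family("logistic"), 50)
  expect_true(all(b_inf[-1] == 0))
  expect_equal(b_inf[1], qlogis(mean(Y)), tolerance = 1e-5)
  # linear family, lambda = 0: least squares
  Yl <- drop(X %*% beta0) + rnorm(n)
  b0 <- dsilt:::local_lasso_at(X, Yl, ds_family("linear"), 1e-8)
  ols <- drop(solve(crossprod(X), crossprod(X, Yl)))
  expect_equal(b0, ols, tolerance = 1e-4, ignore_attr = TRUE)
  # KKT at an interior lambda (logistic): |score_j| <= lam off-support,
  # = lam * sign on the active set
  lam <- 0.05
  b <- dsilt:::local_lasso_at(X, Y, ds_family("logistic"), lam)
  score <- drop(crossprod(X, Y - plogis(drop(X %*% b)))) / n
  act <- which(b[-1] != 0) + 1L
  if (length(act)) {
    expect_true(all(abs(score[act] - lam * sign(b[act])) < 1e-5))
  }
  inact <- setdiff(2:(p + 1), act)
  expect_true(all(abs(score[inact]) <= lam + 1e-5))
  # CV wrapper returns a coefficient vector with its selected penalty
  bcv <- fit_local_lasso(X, Y, "logistic", cv_folds = 4, seed = 3)
  expect_length(bcv, p + 1)
  expect_true(attr(bcv, "lambda") > 0)
})

test_that("Step-1 summaries: linear-family exactness and noiseless identity", {
  dat <- make_linear_fed(M = 1, n = 60, p = 5, s = 2, seed = 31, noise_sd = 0)
  st <- dat$studies[[1]]
  plan <- make_folds(60, 2, 3, seed = 4)
  s1 <- summary_step1(st, plan, 1, "linear", lambda = 1e-6)
  idx <- which(plan$outer != 1)
  # linear family: H is the plain second moment of X on I_{-k}, averaged
  # per inner fold (equal fold sizes here make it the pooled moment)
  expect_equal(s1$H, crossprod(st$X[idx, ]) / length(idx), tolerance = 1e-12)
  # noiseless Y = X beta0: xi = H beta0 exactly
  expect_equal(s1$xi, drop(s1$H %*% dat$truth$B[1, ]), tolerance = 1e-8)
  expect_equal(s1$n_used, length(idx))
})

test_that("Step-1 summaries match the explicit double-loop oracle (logistic)", {
  set.seed(33)
  n <- 30
  X <- cbind(1, matrix(rnorm(2 * n), n))
  Y <- rbinom(n, 1, plogis(0.5 * X[, 2]))
  st <- dsilt:::new_study_data(X, Y)
  plan <- make_folds(n, 2, 3, seed = 5)
  fam <- ds_family("logistic")
  s1 <- summary_step1(st, plan, 2, fam, lambda = 0.15)
  or <- oracle_step1(st, plan, 2, fam, lambda = 0.15)
  expect_equal(s1$xi, or$xi, tolerance = 1e-10)
  expect_equal(s1$H, or$H, tolerance = 1e-10)
})

test_that("Step-2 summaries: noiseless identity, PSD, and brute-force match", {
  dat <- make_linear_fed(M = 1, n = 60, p = 5, s = 2, seed = 32, noise_sd = 0)
  st <- dat$studies[[1]]
  plan <- make_folds(60, 2, 3, seed = 6)
  b0 <- dat$truth$B[1, ]
  s2 <- summary_step2(st, plan, 1, b0, "linear")
  # noiseless with beta_tilde = beta_0: correction term vanishes
  expect_equal(s2$xi_t - drop(s2$H_t %*% b0), rep(0, 6), tolerance = 1e-10)
  expect_true(all(eigen(s2$J_t, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-10))
  # logistic tiny instance against explicit summation
  set.seed(34)
  Xl <- cbind(1, rnorm(20))
  Yl <- rbinom(20, 1, 0.5)
  stl <- dsilt:::new_study_data(Xl, Yl)
  pl <- make_folds(20, 2, 2, seed = 7)
  bt <- c(0.2, -0.4)
  s2l <- summary_step2(stl, pl, 2, bt, "logistic")
  idx <- which(pl$outer == 2)
  fam <- ds_family("logistic")
  xi_o <- 0; H_o <- 0; J_o <- 0
  for (i in idx) {
    th <- sum(Xl[i, ] * bt); w <- fam$phiddot(th)
    xb <- sqrt(w) * Xl[i, ]
    yb <- (Yl[i] - fam$phidot(th) + w * th) / sqrt(w)
    xi_o <- xi_o + xb * yb
    H_o <- H_o + tcrossprod(xb)
    J_o <- J_o + tcrossprod(Xl[i, ]) * (Yl[i] - fam$phidot(th))^2
  }
  expect_equal(s2l$xi_t, xi_o / length(idx), tolerance = 1e-12)
  expect_equal(s2l$H_t, H_o / length(idx), tolerance = 1e-12)
  expect_equal(s2l$J_t, J_o / length(idx), tolerance = 1e-12)
})

test_that("summary payloads round-trip through the message archive", {
  dat <- simulate_federated(ds_design("ar1", p = 5), ds_signal(1, 2, 0.5),
                            "logistic", n_m = 60, seed = 45)
  plan <- make_folds(60, 2, 3, seed = 9)
  s1 <- summary_step1(dat$studies[[1]], plan, 1, "logistic", 0.1)
  dir <- tempfile()
  write_summary(s1, dir, study = 1, k = 1)
  back <- read_summary(dir, study = 1, k = 1)
  expect_identical(back, s1)
  unlink(dir, recursive = TRUE)
})

test_that("summaries depend only on the study's own rows (data-shielding audit)", {
  dat <- simulate_federated(ds_design("ar1", p = 6), ds_signal(2, 2, 0.5),
                            "logistic", n_m = 60, seed = 44)
  plan <- make_folds(60, 2, 3, seed = 8)
  base <- summary_step1(dat$studies[[1]], plan, 1, "logistic", 0.1)
  mutated <- dat
  mutated$studies[[2]]$Y <- rev(mutated$studies[[2]]$Y)
  mutated$studies[[2]]$X[, 2] <- -mutated$studies[[2]]$X[, 2]
  after <- summary_step1(mutated$studies[[1]], plan, 1, "logistic", 0.1)
  expect_identical(base, after)
  b2 <- summary_step2(dat$studies[[1]], plan, 1, rep(0, 7), "logistic")
  a2 <- summary_step2(mutated$studies[[1]], plan, 1, rep(0, 7), "logistic")
  expect_identical(b2, a2)
})
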