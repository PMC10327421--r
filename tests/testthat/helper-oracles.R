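# Independent oracles used by the tests.  These deliberately re-derive
# quantities by the most literal route available (explicit loops, exact
# enumeration, generic first-order solvers) so they share no code with the
# implementation under test.

# per-observation summation of the loss
oracle_loss <- function(beta, X, Y, fam) {
  tot <- 0
  for (i in seq_len(nrow(X))) {
    th <- sum(X[i, ] * beta)
    tot <- tot + fam$phi(th) - Y[i] * th
  }
  tot / nrow(X)
}

# explicit double loop over inner folds for the Step-1 summaries
oracle_step1 <- function(study, plan, k, fam, lambda) {
  inner <- plan$inner[[k]]
  d <- ncol(study$X)
  xi <- numeric(d); H <- matrix(0, d, d)
  for (kp in seq_len(plan$Kp)) {
    train <- which(!is.na(inner) & inner != kp)
    eval_ <- which(!is.na(inner) & inner == kp)
    lam_kp <- lambda * sqrt(plan$n / length(train))
    bh <- dsilt:::local_lasso_at(study$X[train, , drop = FALSE],
                                 study$Y[train], fam, lam_kp)
    xs <- numeric(d); Hs <- matrix(0, d, d)
    for (i in eval_) {
      th <- sum(study$X[i, ] * bh)
      w <- fam$phiddot(th)
      xb <- sqrt(w) * study$X[i, ]
      yb <- (study$Y[i] - fam$phidot(th) + w * th) / sqrt(w)
      xs <- xs + xb * yb
      Hs <- Hs + tcrossprod(xb)
    }
    xi <- xi + xs / length(eval_)
    H <- H + Hs / length(eval_)
  }
  list(xi = xi / plan$Kp, H = H / plan$Kp)
}

# exact adjacent-column correlation of the binary hidden-Markov design by
# enumeration of the 4-state (hidden, observed) pair chain
oracle_hmm_adjacent_cor <- function(trans, emit) {
  joint <- 0
  for (h1 in 0:1) for (h2 in 0:1) for (o1 in 0:1) for (o2 in 0:1) {
    p <- 0.5 *
      (if (h2 == h1) 1 - trans else trans) *
      (if (o1 == h1) 1 - emit else emit) *
      (if (o2 == h2) 1 - emit else emit)
    joint <- joint + p * o1 * o2
  }
  (joint - 0.25) / 0.25
}

# proximal-gradient solver for the pooled individual-level group lasso on
# the linear family (exact sufficiency oracle); B is d x M
oracle_pooled_group_lasso <- function(Xs, Ys, lam, iters = 20000) {
  M <- length(Xs)
  d <- ncol(Xs[[1]])
  n <- vapply(Xs, nrow, 1L)
  w <- n / sum(n)
  B <- matrix(0, d, M)
  L <- 0
  for (m in seq_len(M)) {
    L <- max(L, 2 * w[m] * max(eigen(crossprod(Xs[[m]]) / n[m],
                                     symmetric = TRUE,
                                     only.values = TRUE)$values))
  }
  step <- 1 / L
  for (it in seq_len(iters)) {
    G <- matrix(0, d, M)
    for (m in seq_len(M)) {
      r <- Xs[[m]] %*% B[, m] - Ys[[m]]
      G[, m] <- 2 * w[m] * crossprod(Xs[[m]], r) / n[m]
    }
    V <- B - step * G
    Bn <- V
    for (j in 2:d) {
      nr <- sqrt(sum(V[j, ]^2))
      Bn[j, ] <- if (nr <= step * lam) 0 else V[j, ] * (1 - step * lam / nr)
    }
    if (max(abs(Bn - B)) < 1e-12) { B <- Bn; break }
    B <- Bn
  }
  B
}

# objective of the pooled linear-family group lasso (2x mean squared loss
# parameterisation, matching the quadratic summary objective up to a
# beta-free constant)
oracle_pooled_objective <- function(Xs, Ys, B, lam) {
  M <- length(Xs)
  n <- vapply(Xs, nrow, 1L)
  w <- n / sum(n)
  v <- 0
  for (m in seq_len(M)) {
    f <- Xs[[m]] %*% B[, m]
    v <- v + w[m] * mean(f^2 - 2 * Ys[[m]] * f)
  }
  v + lam * sum(sqrt(rowSums(B[-1, , drop = FALSE]^2)))
}

# deterministic small PSD instances for the projection-direction tests;
# reference objectives frozen from independent generic solvers (SLSQP /
# HiGHS LP) run on the same matrices
dantzig_test_instance <- function(seed, d, M) {
  set.seed(seed)
  lapply(seq_len(M), function(m) {
    A <- matrix(rnorm(d * d), d)
    crossprod(A) / d + 0.5 * diag(d)
  })
}
dantzig_reference <- list(
  list(seed = 42, d = 3, M = 2, j = 2, tau = 0.3,  obj = 1.0119456),
  list(seed = 7,  d = 4, M = 3, j = 3, tau = 0.5,  obj = 0.5063058),
  list(seed = 13, d = 5, M = 1, j = 2, tau = 0.25, obj = 1.0338462)
)

# small federated linear dataset with exactly equal fold sizes
make_linear_fed <- function(M = 2, n = 120, p = 12, s = 4, mu = 0.6,
                            seed = 5, noise_sd = 1) {
  simulate_federated(ds_design("ar1", p = p, rho = 0.4),
                     ds_signal(M, s, mu), "linear",
                     n_m = n, seed = seed, noise_sd = noise_sd)
}
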