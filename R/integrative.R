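summaries_to_cube <- function(summaries) {
  d <- length(summaries[[1]]$xi)
  M <- length(summaries)
  H <- array(0, c(d, d, M))
  xi <- matrix(0, d, M)
  n_used <- numeric(M)
  for (m in seq_len(M)) {
    s <- summaries[[m]]
    stopifnot(length(s$xi) == d, all(dim(s$H) == d))
    H[, , m] <- (s$H + t(s$H)) / 2
    xi[, m] <- s$xi
    n_used[m] <- s$n_used
  }
  list(H = H, xi = xi, n_used = n_used, wbar = n_used / sum(n_used),
       d = d, M = M)
}

check_psd <- function(H, tol = 1e-8) {
  ev <- min(eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -tol * max(1, abs(max(diag(H)))))
    stop("summary Hessian is not positive semidefinite (min eigenvalue ",
         format(ev), ")", call. = FALSE)
  invisible(ev)
}

#' Rate-based penalty grid for the integrative group lasso
#'
#' The group penalty must dominate the group \eqn{\ell_2} norm of the
#' gradient noise, which scales as
#' \eqn{(2/M)\sqrt{(M + \log p)/\bar n}} for \eqn{M} studies with average
#' per-study sample size \eqn{\bar n} (the factor 2 reflects the quadratic
#' deviance parameterisation).  The grid is \code{length} log-spaced
#' multiples of this rate over \code{range}.
#'
#' @param M,p studies and covariate count.
#' @param n_bar average per-study sample size entering the fit.
#' @param length,range grid size and multiplicative span.
#' @return decreasing numeric vector.
#' @export
group_lambda_grid <- function(M, p, n_bar, length = 25L,
                              range = c(0.05, 2)) {
  rate <- 2 * sqrt((M + log(p)) / n_bar) / M
  sort(exp(seq(log(range[1]), log(range[2]), length.out = length)) * rate,
       decreasing = TRUE)
}

#' Integrative group-lasso estimator from summary statistics
#'
#' Given the per-study summaries \eqn{(\hat\xi^{(m)}, \hat{H}^{(m)})} and
#' their sample sizes, minimises the aggregated quadratic quasi-likelihood
#' \deqn{|\mathcal{I}|^{-1} \sum_m |\mathcal{I}^{(m)}| \left(
#'   \beta^{(m)\top}\hat{H}^{(m)}\beta^{(m)} -
#'   2\beta^{(m)\top}\hat\xi^{(m)}\right) + \lambda\sum_{j\ge 2}
#'   \|\beta_j\|_2,}
#' where \eqn{\beta_j} collects coefficient \eqn{j} across the M studies.
#' The group penalty induces a shared support; the intercept group is
#' unpenalised.  Solved by cyclic block coordinate descent with an exact
#' groupwise update (the per-group subproblem reduces to a scalar
#' fixed-point equation because the curvatures differ across studies);
#' the objective is monotone nonincreasing across sweeps.
#'
#' @param summaries list over studies of Step-1 summaries
#'   (\code{n_used}, \code{xi}, \code{H}), see [summary_step1()].
#' @param lam penalty \eqn{\lambda \ge 0}.
#' @param init optional M x (p+1) warm-start coefficient matrix.
#' @param tol convergence tolerance on the largest coefficient update.
#' @param maxit maximum number of sweeps.
#' @param check_psd_tol tolerance for rejecting an indefinite Hessian.
#' @return M x (p+1) coefficient matrix with attributes \code{objective},
#'   \code{sweeps}, \code{converged}.
#' @export
fit_group_lasso <- function(summaries, lam, init = NULL, tol = 1e-7,
                            maxit = 5000L, check_psd_tol = 1e-6) {
  stopifnot(lam >= 0)
  sc <- summaries_to_cube(summaries)
  for (m in seq_len(sc$M)) check_psd(sc$H[, , m], check_psd_tol)
  B0 <- if (is.null(init)) matrix(0, sc$d, sc$M) else {
    stopifnot(nrow(init) == sc$M, ncol(init) == sc$d)
    t(init)
  }
  fit <- bcd_group_lasso_cpp(sc$H, sc$xi, sc$wbar, lam, B0, tol,
                             as.integer(maxit))
  if (!fit$converged)
    warning("group lasso did not converge in ", maxit,
            " sweeps; returning last iterate", call. = FALSE)
  B <- t(fit$B)
  attr(B, "objective") <- fit$objective
  attr(B, "sweeps") <- fit$sweeps
  attr(B, "converged") <- fit$converged
  B
}

#' @rdname fit_group_lasso
#' @param B an M x (p+1) coefficient matrix.
#' @return \code{group_lasso_objective}: the penalised objective value.
#' @export
group_lasso_objective <- function(summaries, B, lam) {
  sc <- summaries_to_cube(summaries)
  group_lasso_objective_cpp(sc$H, sc$xi, sc$wbar, lam, t(B))
}

#' Smallest penalty nulling every covariate group
#'
#' With all non-intercept groups at zero and intercepts at their per-study
#' optima, returns the largest group gradient norm, i.e. the smallest
#' \eqn{\lambda} for which the all-null fit is stationary.
#'
#' @inheritParams fit_group_lasso
#' @export
group_lambda_max <- function(summaries) {
  sc <- summaries_to_cube(summaries)
  grad <- matrix(0, sc$d, sc$M)
  for (m in seq_len(sc$M)) {
    b1 <- sc$xi[1, m] / sc$H[1, 1, m]
    grad[, m] <- 2 * sc$wbar[m] * (sc$H[, 1, m] * b1 - sc$xi[, m])
  }
  max(sqrt(rowSums(grad^2)[-1]))
}

#' Generalized information criterion for the integrative fit
#'
#' \eqn{GIC(\lambda) = Dev + \gamma\,DF}, where Dev is the quadratic
#' deviance of the summary-statistic objective and DF is the trace of
#' \eqn{[\partial^2_{\hat{S}}(Dev + \lambda\|\cdot\|_{2,1})]^{-1}
#' [\partial^2_{\hat{S}} Dev]} restricted to the nonzero coefficients
#' \eqn{\hat{S}} — an effective degrees of freedom that accounts for the
#' groupwise shrinkage.  At \eqn{\lambda = 0} with a full active set, DF
#' equals \eqn{|\hat{S}|}.
#'
#' @inheritParams group_lasso_objective
#' @param gamma scaling of the DF penalty; default is the BIC choice
#'   \eqn{\log(n_{tot})/n_{tot}} with \eqn{n_{tot}} the total sample size
#'   behind the summaries.
#' @return list with \code{dev}, \code{df}, \code{gamma}, \code{value}.
#' @export
gic <- function(summaries, B, lam, gamma = NULL) {
  sc <- summaries_to_cube(summaries)
  ntot <- sum(sc$n_used)
  if (is.null(gamma)) gamma <- log(ntot) / ntot
  Bt <- t(B)  # d x M
  dev <- 0
  for (m in seq_len(sc$M)) {
    b <- Bt[, m]
    dev <- dev + sc$wbar[m] *
      (drop(crossprod(b, sc$H[, , m] %*% b)) - 2 * sum(b * sc$xi[, m]))
  }
  act <- which(Bt != 0, arr.ind = TRUE)  # (j, m) pairs, j in 1..d
  df <- 0
  if (nrow(act)) {
    nact <- nrow(act)
    A <- matrix(0, nact, nact)   # restricted Hessian of Dev
    P <- matrix(0, nact, nact)   # restricted Hessian of the penalty
    for (a in seq_len(nact)) {
      ja <- act[a, 1]; ma <- act[a, 2]
      same_m <- which(act[, 2] == ma)
      A[a, same_m] <- 2 * sc$wbar[ma] * sc$H[ja, act[same_m, 1], ma]
    }
    if (lam > 0) {
      for (j in unique(act[, 1])) {
        if (j == 1L) next  # intercept group unpenalised
        rows <- which(act[, 1] == j)
        bj <- Bt[j, act[rows, 2]]
        r <- sqrt(sum(Bt[j, ]^2))
        P[rows, rows] <- lam * (diag(length(rows)) / r -
                                  tcrossprod(bj) / r^3)
      }
    }
    K <- A + P
    ratio <- tryCatch(solve(K, A), error = function(e) {
      warning("singular restricted Hessian in GIC; ridge-stabilised",
              call. = FALSE)
      solve(K + diag(1e-8 * max(diag(K)), nact), A)
    })
    df <- sum(diag(ratio))
  }
  list(dev = dev, df = df, gamma = gamma, value = dev + gamma * df)
}

#' GIC-based selection of the integrative penalty
#'
#' Fits the group lasso along a decreasing penalty grid with warm starts
#' and returns the GIC minimiser.  Ties are broken toward the larger
#' penalty (the sparser model).
#'
#' @inheritParams fit_group_lasso
#' @param grid penalty grid; defaults to [group_lambda_grid()] at the
#'   summaries' dimensions.
#' @param gamma DF scaling passed to [gic()].
#' @return list with \code{lambda}, \code{B} (the selected fit),
#'   \code{path} (data.frame of lambda, dev, df, gic, active groups).
#' @export
select_lambda <- function(summaries, grid = NULL, gamma = NULL) {
  sc <- summaries_to_cube(summaries)
  if (is.null(grid)) {
    grid <- group_lambda_grid(sc$M, sc$d - 1L, mean(sc$n_used))
  }
  if (!length(grid)) stop("empty lambda grid", call. = FALSE)
  grid <- sort(grid, decreasing = TRUE)
  fits <- vector("list", length(grid))
  path <- data.frame(lambda = grid, dev = NA_real_, df = NA_real_,
                     gic = NA_real_, active = NA_integer_)
  init <- NULL
  for (i in seq_along(grid)) {
    B <- fit_group_lasso(summaries, grid[i], init = init)
    init <- B
    g <- gic(summaries, B, grid[i], gamma)
    fits[[i]] <- B
    path$dev[i] <- g$dev; path$df[i] <- g$df; path$gic[i] <- g$value
    path$active[i] <- sum(colSums(B[, -1, drop = FALSE] != 0) > 0)
  }
  best <- which.min(path$gic)  # first index = largest lambda on ties
  list(lambda = grid[best], B = fits[[best]], path = path)
}
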