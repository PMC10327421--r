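#' Theoretical rate of the debiasing feasibility radius
#'
#' The group Dantzig constraint can be satisfied with a radius of order
#' \eqn{\sqrt{(M + \log p)/n}}, the size of the sampling noise in the
#' fold-level Hessian; the pipeline scans a small grid of multiples of this
#' rate and picks one by the null-calibration criterion ([select_tau()]).
#'
#' @param M number of studies; \code{p} covariate count; \code{n} per-study
#'   sample size entering the Hessian estimate.
#' @export
tau_rate <- function(M, p, n) sqrt((M + log(p)) / n)

#' Group Dantzig-selector projection directions
#'
#' For each tested coordinate \eqn{j}, finds per-study directions
#' \eqn{u_j^{(m)}} minimising the worst-study \eqn{\ell_1} norm
#' \eqn{\max_m \|u^{(m)}\|_1} subject to the groupwise constraint that for
#' every coordinate \eqn{\ell}, the M-vector of Hessian residuals
#' \eqn{(\tilde{H}^{(m)} u^{(m)} - e_j)_\ell} has Euclidean norm at most
#' \eqn{\tau}.  The directions project the refreshed score onto coordinate
#' \eqn{j}, removing the first-order bias of the regularised estimator.
#'
#' The program is a second-order cone problem, solved by a two-block ADMM
#' whose per-study linear systems are factorised once and shared across all
#' targets, radii and warm starts; the block-diagonal structure over
#' studies is never materialised.  The returned directions carry an
#' independently recomputed feasibility certificate.
#'
#' @param H_blocks list of M symmetric PSD matrices
#'   (\eqn{\tilde{H}^{(m)}}), all of the same dimension.
#' @param j integer vector of target coordinates (1-based, intercept = 1).
#' @param tau feasibility radius \eqn{\tau > 0}.
#' @param warm optional solver state from a previous call with the same
#'   \code{H_blocks} and targets (e.g. a neighbouring \code{tau}).
#' @param tol ADMM tolerance on the splitting residuals.
#' @param feas_tol allowed certificate slack above \code{tau}.
#' @param maxit iteration cap.
#' @param plateau_tol when positive, a target is also accepted once its
#'   certificate is feasible and its objective has stopped moving (relative
#'   change below \code{plateau_tol} between convergence checks).  Used by
#'   the large statistical runs, where slight suboptimality of a feasible
#'   direction only perturbs the variance estimate; leave at 0 for exact
#'   solves.
#' @return list with \code{U} (array \code{d x M x q} of directions),
#'   \code{objective}, \code{feasibility} (certificate residuals),
#'   \code{converged}, \code{tau}, and \code{state} for warm starts.
#'   If no target converges to a feasible point the radius is reported as
#'   too small via a condition of class \code{dsilt_dantzig_infeasible}.
#' @export
solve_group_dantzig <- function(H_blocks, j, tau, warm = NULL,
                                tol = 1e-6, feas_tol = 1e-7,
                                maxit = 20000L, plateau_tol = 0) {
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  d <- nrow(H_blocks[[1]])
  M <- length(H_blocks)
  H <- array(0, c(d, d, M))
  for (m in seq_len(M)) {
    stopifnot(all(dim(H_blocks[[m]]) == d))
    H[, , m] <- (H_blocks[[m]] + t(H_blocks[[m]])) / 2
  }
  targets <- as.integer(j) - 1L
  stopifnot(all(targets >= 0), all(targets < d))
  res <- group_dantzig_admm(H, targets, tau, warm = warm, maxit = maxit,
                            tol = tol, feas_tol = feas_tol,
                            plateau_tol = plateau_tol)
  q <- length(j)
  U <- array(res$U, c(d, M, q))
  feas_ok <- res$feasibility <= tau + max(feas_tol, 1e-7) * (1 + tau)
  if (!any(feas_ok)) {
    cond <- structure(
      class = c("dsilt_dantzig_infeasible", "error", "condition"),
      list(message = sprintf(
        "group Dantzig selector found no feasible direction at tau = %g; try a larger tau",
        tau), call = sys.call()))
    stop(cond)
  }
  list(U = U, objective = as.numeric(res$objective),
       feasibility = as.numeric(res$feasibility),
       iterations = as.integer(res$iterations),
       converged = as.logical(res$converged), tau = tau, targets = j,
       state = res$state)
}

#' Cross-fitted debiased coefficients
#'
#' Averages over the K outer folds the one-step corrected estimates
#' \deqn{\breve\beta_j^{(m)} = K^{-1}\sum_k s_k\left\{
#'   \tilde\beta_{j,[-k]}^{(m)} + u_{j,[k]}^{(m)\top}
#'   (\tilde\xi_{[k]}^{(m)} - \tilde{H}_{[k]}^{(m)}
#'    \tilde\beta_{[-k]}^{(m)})\right\},}
#' with fold signs \eqn{s_k = +1} (the estimator) or the
#' half-contrast signs \eqn{s_k = (-1)^{1\{k > K/2\}}} (the null-centred
#' device used for radius calibration, see [select_tau()]).
#'
#' @param beta_tilde_per_fold list over k of M x (p+1) integrative
#'   coefficients fit without fold k.
#' @param proj_per_fold list over k of direction sets from
#'   [solve_group_dantzig()] (or their \code{U} arrays).
#' @param step2_per_fold list over k of per-study Step-2 summaries
#'   ([summary_step2()]).
#' @param signs optional per-fold signs (defaults to all +1).
#' @return M x q matrix of debiased coefficients, columns ordered as the
#'   targets of the projections.
#' @export
debias_coefficients <- function(beta_tilde_per_fold, proj_per_fold,
                                step2_per_fold, signs = NULL) {
  K <- length(beta_tilde_per_fold)
  stopifnot(length(proj_per_fold) == K, length(step2_per_fold) == K)
  if (is.null(signs)) signs <- rep(1, K)
  stopifnot(length(signs) == K)
  U1 <- if (is.list(proj_per_fold[[1]]) && !is.null(proj_per_fold[[1]]$U))
    proj_per_fold[[1]]$U else proj_per_fold[[1]]
  d <- dim(U1)[1]; M <- dim(U1)[2]; q <- dim(U1)[3]
  targets <- if (is.list(proj_per_fold[[1]]) &&
                 !is.null(proj_per_fold[[1]]$targets))
    proj_per_fold[[1]]$targets else seq_len(q)
  out <- matrix(0, M, q)
  for (k in seq_len(K)) {
    U <- if (is.list(proj_per_fold[[k]]) && !is.null(proj_per_fold[[k]]$U))
      proj_per_fold[[k]]$U else proj_per_fold[[k]]
    Bk <- beta_tilde_per_fold[[k]]
    if (!all(dim(U)[c(1, 2)] == c(d, M)) || nrow(Bk) != M || ncol(Bk) != d)
      stop("misaligned folds in debias_coefficients", call. = FALSE)
    for (m in seq_len(M)) {
      s2 <- step2_per_fold[[k]][[m]]
      corr <- drop(s2$xi_t - s2$H_t %*% Bk[m, ])
      # u_j' correction for every target j at once
      out[m, ] <- out[m, ] + signs[k] *
        (Bk[m, targets] + colSums(U[, m, ] * corr))
    }
  }
  out / K
}

#' Variance estimates of the debiased coefficients
#'
#' \eqn{(\hat\sigma_j^{(m)})^2 = K^{-1}\sum_k u_{j,[k]}^{(m)\top}
#' \tilde{J}_{[k]}^{(m)} u_{j,[k]}^{(m)}}, the cross-fitted sandwich
#' quadratic form in the raw-residual second-moment matrix.  Values are
#' floored at \code{1e-12} (with a warning) to keep downstream statistics
#' finite.
#'
#' @inheritParams debias_coefficients
#' @return M x q matrix of variances.
#' @export
estimate_variance <- function(proj_per_fold, step2_per_fold) {
  K <- length(proj_per_fold)
  U1 <- if (is.list(proj_per_fold[[1]]) && !is.null(proj_per_fold[[1]]$U))
    proj_per_fold[[1]]$U else proj_per_fold[[1]]
  d <- dim(U1)[1]; M <- dim(U1)[2]; q <- dim(U1)[3]
  out <- matrix(0, M, q)
  for (k in seq_len(K)) {
    U <- if (is.list(proj_per_fold[[k]]) && !is.null(proj_per_fold[[k]]$U))
      proj_per_fold[[k]]$U else proj_per_fold[[k]]
    for (m in seq_len(M)) {
      J <- step2_per_fold[[k]][[m]]$J_t
      out[m, ] <- out[m, ] + colSums(U[, m, ] * (J %*% U[, m, ]))
    }
  }
  out <- out / K
  if (any(out < 1e-12)) {
    warning("variance estimates floored at 1e-12", call. = FALSE)
    out <- pmax(out, 1e-12)
  }
  out
}

#' Chi-square group statistics
#'
#' The overall effect of covariate \eqn{j} across studies is tested with
#' \eqn{\breve\zeta_j = \sum_m n_m \{\breve\beta_j^{(m)} /
#' \hat\sigma_j^{(m)}\}^2}, asymptotically \eqn{\chi^2_M} under the group
#' null \eqn{\beta_{0,j} = 0}.
#'
#' @param beta_breve,sigma_hat M x q matrices from
#'   [debias_coefficients()] and \code{sqrt} of [estimate_variance()].
#' @param n_m per-study sample sizes.
#' @return length-q vector of nonnegative statistics.
#' @export
group_statistic <- function(beta_breve, sigma_hat, n_m) {
  stopifnot(all(dim(beta_breve) == dim(sigma_hat)), all(sigma_hat > 0),
            length(n_m) == nrow(beta_breve))
  colSums(n_m * (beta_breve / sigma_hat)^2)
}
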