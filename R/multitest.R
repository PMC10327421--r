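#' Normal-quantile transform of chi-square group statistics
#'
#' \eqn{\mathcal{N}_j = \bar\Phi^{-1}\{\bar{F}_{\chi^2_M}(\breve\zeta_j)/2\}},
#' mapping a \eqn{\chi^2_M} variable to the absolute value of a standard
#' normal.  Survival functions are evaluated on the log scale so the
#' transform stays accurate for very large statistics.
#'
#' @param zeta nonnegative statistics.
#' @param M chi-square degrees of freedom (number of studies).
#' @return transformed statistics, same length as \code{zeta}.
#' @export
normal_transform <- function(zeta, M) {
  stopifnot(all(zeta >= 0))
  logF <- stats::pchisq(zeta, df = M, lower.tail = FALSE, log.p = TRUE)
  stats::qnorm(logF - log(2), lower.tail = FALSE, log.p = TRUE)
}

#' FDR-controlling threshold for transformed statistics
#'
#' Finds \deqn{\hat t = \inf\{0 \le t \le t_q :
#'   2q\bar\Phi(t) / (R(t) \vee 1) \le \alpha\},\qquad
#'   t_q = (2\log q - 2\log\log q)^{1/2},}
#' where \eqn{R(t)} is the number of statistics at least \eqn{t}: the
#' number of false positives is estimated by \eqn{2q\bar\Phi(t)}, which is
#' only a consistent estimate for \eqn{t \le t_q}.  If no qualifying
#' threshold exists in the range, \eqn{\hat t = (2\log q)^{1/2}}; stopping
#' at \eqn{t_q} instead would not control the error rate.
#'
#' The infimum is computed exactly: on each interval where \eqn{R} is
#' constant the condition reduces to \eqn{t \ge \bar\Phi^{-1}(\alpha
#' (R\vee 1)/(2q))}, so the infimum is attained either at such a Gaussian
#' quantile or at an order statistic.
#'
#' @param N transformed statistics (length \eqn{q \ge 2}).
#' @param alpha nominal FDR level in (0, 1).
#' @return object of class \code{ds_test_outcome}: list with \code{N},
#'   \code{t_hat}, \code{rejected} (indices into \code{N}), \code{t_q},
#'   \code{alpha}, and \code{attained} (whether the infimum existed in
#'   range).
#' @export
find_threshold <- function(N, alpha) {
  q <- length(N)
  stopifnot(q >= 2, alpha > 0, alpha < 1)
  t_q <- sqrt(2 * log(q) - 2 * log(log(q)))
  t_max <- sqrt(2 * log(q))
  # interval breakpoints: [0, v_1], (v_1, v_2], ..., (v_r, Inf)
  v <- sort(unique(N[N > 0]))
  lows <- c(0, v)
  t_hat <- NA_real_
  for (i in seq_along(lows)) {
    lo <- lows[i]
    hi <- if (i < length(lows)) lows[i + 1] else Inf
    R <- sum(N > lo)    # R(t) = #{N_j >= t} is constant on (lo, hi]
    arg <- alpha * max(R, 1) / (2 * q)
    t_R <- if (arg >= 0.5) 0 else stats::qnorm(arg, lower.tail = FALSE)
    cand <- max(lo, t_R)
    if (cand <= min(hi, t_q)) { t_hat <- cand; break }
  }
  attained <- !is.na(t_hat)
  if (!attained) t_hat <- t_max
  structure(list(N = N, t_hat = t_hat, rejected = which(N >= t_hat),
                 t_q = t_q, alpha = alpha, attained = attained),
            class = "ds_test_outcome")
}

#' @export
print.ds_test_outcome <- function(x, ...) {
  cat(sprintf(
    "Multiple-testing outcome: q = %d, alpha = %.3g, t_hat = %.4f%s, %d rejections\n",
    length(x$N), x$alpha, x$t_hat,
    if (x$attained) "" else " (range fallback)", length(x$rejected)))
  if (!is.null(x$fdp)) cat(sprintf("  FDP = %.3f, power = %.3f\n",
                                   x$fdp, x$power))
  invisible(x)
}

#' Benjamini-Hochberg-style comparator threshold
#'
#' The unbounded-range analogue
#' \eqn{\hat t_{BH} = \inf\{t \ge 0 : 2q\bar\Phi(t)/(R(t)\vee 1) \le
#' \alpha\}} provided for diagnostics only: without the \eqn{t_q} cap the
#' false-positive count estimate degrades in the far tail and the FDP is
#' not guaranteed to be controlled.
#'
#' @inheritParams find_threshold
#' @return the threshold (possibly \code{Inf} when no t qualifies).
#' @export
bh_threshold <- function(N, alpha) {
  q <- length(N)
  v <- sort(unique(N[N > 0]))
  lows <- c(0, v)
  for (i in seq_along(lows)) {
    lo <- lows[i]
    hi <- if (i < length(lows)) lows[i + 1] else Inf
    R <- sum(N > lo)
    arg <- alpha * max(R, 1) / (2 * q)
    t_R <- if (arg >= 0.5) 0 else stats::qnorm(arg, lower.tail = FALSE)
    cand <- max(lo, t_R)
    if (cand <= hi) return(cand)
  }
  Inf
}

#' Empirical false discovery proportion and power
#'
#' @param rejected indices rejected.
#' @param truth_support indices with a truly nonzero group effect.
#' @param H_index the tested index set.
#' @return list with \code{fdp} = false rejections over total rejections
#'   (0 when nothing is rejected) and \code{power} = detected fraction of
#'   the true signals within the tested set.
#' @export
error_metrics <- function(rejected, truth_support, H_index) {
  stopifnot(all(rejected %in% H_index))
  truth_in <- intersect(truth_support, H_index)
  fdp <- length(setdiff(rejected, truth_in)) / max(length(rejected), 1)
  power <- length(intersect(rejected, truth_in)) / max(length(truth_in), 1)
  list(fdp = fdp, power = power)
}

#' Null-centred group statistics for radius calibration
#'
#' Re-combines the per-fold debiased terms with signs \eqn{+1} on the first
#' \eqn{K/2} folds and \eqn{-1} on the rest, so any true signal cancels and
#' the resulting statistics \eqn{\breve\zeta_{j,null}(\tau) = \sum_m n_m
#' \{\breve\beta_{j,null}^{(m)}(\tau)/\hat\sigma_j^{(m)}\}^2} behave as
#' draws from the complete null.  The ordinary variance estimates are
#' reused.  Requires an even number of folds.
#'
#' @inheritParams debias_coefficients
#' @param n_m per-study sample sizes.
#' @param sigma_hat M x q matrix of standard errors (from the non-null
#'   pipeline at the same radius).
#' @return length-q vector of null-centred statistics.
#' @export
null_statistics <- function(beta_tilde_per_fold, proj_per_fold,
                            step2_per_fold, n_m, sigma_hat) {
  K <- length(beta_tilde_per_fold)
  if (K %% 2L != 0L) stop("K must be even for the null contrast",
                          call. = FALSE)
  signs <- rep(c(1, -1), each = K / 2)
  b_null <- debias_coefficients(beta_tilde_per_fold, proj_per_fold,
                                step2_per_fold, signs = signs)
  group_statistic(b_null, sigma_hat, n_m)
}

#' Choose the debiasing radius by null calibration
#'
#' For each candidate radius \eqn{\tau}, the empirical count of
#' null-centred statistics exceeding a threshold,
#' \eqn{\hat{R}_{0,null}(t \mid \tau) = \sum_j I[\bar{F}_{\chi^2_M}
#' \{\breve\zeta_{j,null}(\tau)\} \le 2\bar\Phi(t)]}, is compared with its
#' ideal value \eqn{2q\bar\Phi(t)} on the evaluation points
#' \eqn{x_h = \bar\Phi\{(2\log q)^{1/2}\}\, h/H,\ h = 1..H}:
#' \deqn{\hat d(\tau) = H^{-1}\sum_{h}
#'   \left[\hat{R}_{0,null}\{\bar\Phi^{-1}(x_h) \mid \tau\}/(2qx_h) -
#'   1\right]^2.}
#' The radius minimising \eqn{\hat d} is returned; ties break toward the
#' smaller radius.  The evaluation grid concentrates where the threshold
#' search operates — deep in the tail — so the chosen radius is the one
#' whose null statistics are best calibrated exactly where miscalibration
#' would distort the FDR.
#'
#' @param null_zeta_by_tau named list (by radius) of null-centred statistic
#'   vectors, one per candidate \eqn{\tau} (see [null_statistics()]).
#' @param M chi-square degrees of freedom.
#' @param H_grid number of evaluation points (default 10).
#' @return list with \code{grid}, \code{d_hat}, \code{chosen} (the radius),
#'   \code{index}.
#' @export
select_tau <- function(null_zeta_by_tau, M, H_grid = 10L) {
  if (!length(null_zeta_by_tau)) stop("empty tau grid", call. = FALSE)
  taus <- as.numeric(names(null_zeta_by_tau))
  q <- length(null_zeta_by_tau[[1]])
  x_top <- stats::pnorm(sqrt(2 * log(q)), lower.tail = FALSE)
  x_h <- x_top * seq_len(H_grid) / H_grid
  d_hat <- vapply(null_zeta_by_tau, function(zeta) {
    Fbar <- stats::pchisq(zeta, df = M, lower.tail = FALSE)
    mean(vapply(x_h, function(x) {
      (sum(Fbar <= 2 * x) / (2 * q * x) - 1)^2
    }, 0))
  }, 0)
  ord <- order(d_hat, taus)  # ties -> smaller tau
  idx <- ord[1]
  list(grid = taus, d_hat = unname(d_hat), chosen = taus[idx], index = idx)
}
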