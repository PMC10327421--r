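#' Nested cross-fitting fold plan
#'
#' Partitions the \code{n} observations of one study into \code{K} outer
#' folds \eqn{\mathcal{I}_k}, and each outer complement
#' \eqn{\mathcal{I}_{-k}} into \code{Kp} inner folds
#' \eqn{\mathcal{I}_{-k,k'}}.  The outer folds separate estimation from
#' debiasing; the inner folds separate the local lasso fit from the moments
#' it is evaluated on.  \code{K} must be even: the null-calibration device
#' used for choosing the debiasing radius contrasts the first \code{K/2}
#' outer folds against the last \code{K/2}, which requires an even split.
#'
#' Fold sizes differ by at most one; assignments are deterministic given
#' \code{seed}.
#'
#' @param n number of observations.
#' @param K even number of outer folds, \eqn{\ge 2}.
#' @param Kp number of inner folds, \eqn{\ge 2}.
#' @param seed integer seed.
#' @return an object of class \code{ds_folds}: list with \code{K},
#'   \code{Kp}, \code{outer} (length-n fold labels), and \code{inner} (list
#'   of length K; element k is a length-n vector with inner-fold labels on
#'   \eqn{\mathcal{I}_{-k}} and NA on \eqn{\mathcal{I}_k}).
#' @export
make_folds <- function(n, K, Kp, seed) {
  K <- as.integer(K); Kp <- as.integer(Kp); n <- as.integer(n)
  if (K < 2L || K %% 2L != 0L)
    stop("K must be an even number >= 2 (the null-contrast device pairs ",
         "the first and second half of the outer folds)", call. = FALSE)
  if (Kp < 2L) stop("Kp must be >= 2", call. = FALSE)
  if (n < K * Kp) stop("n must be at least K * Kp", call. = FALSE)
  with_seed(seed, {
    outer <- sample(rep_len(seq_len(K), n))
    inner <- lapply(seq_len(K), function(k) {
      idx <- which(outer != k)
      lab <- rep(NA_integer_, n)
      lab[idx] <- sample(rep_len(seq_len(Kp), length(idx)))
      lab
    })
    structure(list(K = K, Kp = Kp, outer = outer, inner = inner, n = n),
              class = "ds_folds")
  })
}
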