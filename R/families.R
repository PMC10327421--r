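#' Outcome families for federated M-estimation
#'
#' A family bundles the cumulant-type function \eqn{\phi} and its first two
#' derivatives, which define the per-observation loss
#' \eqn{f(x, y) = \phi(x) - yx} and the conditional mean model
#' \eqn{E(Y \mid X) = \dot\phi(X^\top\beta)}.  Three families are provided:
#' \describe{
#'   \item{\code{logistic}}{\eqn{\phi(x) = \log(1 + e^x)}; binary outcomes,
#'     or probability scores in \eqn{[0,1]} (quasi-binomial).}
#'   \item{\code{linear}}{\eqn{\phi(x) = x^2/2}; continuous outcomes, the
#'     loss is half the squared error up to a constant.}
#'   \item{\code{poisson_log}}{\eqn{\phi(x) = e^x}; non-negative counts with
#'     a log link.  Included for completeness; count residuals are not
#'     sub-Gaussian, so the testing theory behind the pipeline does not
#'     cover this family and it is excluded from the calibration studies.}
#' }
#'
#' Evaluations are overflow-guarded: linear predictors are clipped to
#' \eqn{\pm 30} inside exponentials, far outside the range where logistic or
#' Poisson fits are numerically meaningful.
#'
#' @param name one of \code{"logistic"}, \code{"linear"}, \code{"poisson_log"}.
#' @return an object of class \code{ds_family}: a list with elements
#'   \code{name}, \code{phi}, \code{phidot}, \code{phiddot} (vectorised
#'   scalar maps) and \code{simulate(theta, ...)} drawing outcomes from the
#'   conditional law at linear predictor \code{theta}.
#' @examples
#' fam <- ds_family("logistic")
#' fam$phi(0)      # log(2)
#' fam$phiddot(0)  # 1/4
#' @export
ds_family <- function(name = c("logistic", "linear", "poisson_log")) {
  name <- match.arg(name)
  clip <- function(x) pmin(pmax(x, -30), 30)
  fam <- switch(name,
    logistic = list(
      name = "logistic",
      # log(1 + e^x) computed stably for large |x|
      phi = function(x) ifelse(x > 30, x, log1p(exp(clip(x)))),
      phidot = function(x) stats::plogis(x),
      phiddot = function(x) {
        p <- stats::plogis(clip(x))
        p * (1 - p)
      },
      simulate = function(theta, rng = NULL) {
        stats::rbinom(length(theta), 1L, stats::plogis(theta))
      }
    ),
    linear = list(
      name = "linear",
      phi = function(x) x^2 / 2,
      phidot = function(x) x,
      phiddot = function(x) rep(1, length(x)),
      simulate = function(theta, noise_sd = 1) {
        theta + stats::rnorm(length(theta), sd = noise_sd)
      }
    ),
    poisson_log = list(
      name = "poisson_log",
      phi = function(x) exp(clip(x)),
      phidot = function(x) exp(clip(x)),
      phiddot = function(x) exp(clip(x)),
      simulate = function(theta, rng = NULL) {
        stats::rpois(length(theta), exp(clip(theta)))
      }
    )
  )
  class(fam) <- "ds_family"
  fam
}

as_ds_family <- function(family) {
  if (inherits(family, "ds_family")) return(family)
  if (is.character(family)) return(ds_family(family))
  stop("`family` must be a ds_family object or a family name", call. = FALSE)
}

#' Empirical loss of a coefficient vector
#'
#' Computes \eqn{n^{-1} \sum_i \{\phi(X_i^\top\beta) - Y_i X_i^\top\beta\}},
#' the sample average of the per-observation loss defining the M-estimation
#' problem.  For the logistic family this is the average negative
#' log-likelihood; at \eqn{\beta = 0} it equals \eqn{\log 2} for any data.
#'
#' @param beta coefficient vector, length \code{ncol(X)}.
#' @param X design matrix (first column the intercept, by convention).
#' @param Y outcome vector.
#' @param family a [ds_family()] or family name.
#' @return scalar loss value.
#' @export
ds_loss <- function(beta, X, Y, family) {
  family <- as_ds_family(family)
  stopifnot(length(beta) == ncol(X), length(Y) == nrow(X))
  theta <- drop(X %*% beta)
  mean(family$phi(theta) - Y * theta)
}

#' Heteroscedasticity-adjusted responses and covariates
#'
#' At a working coefficient \eqn{\beta} with linear predictor
#' \eqn{\theta = X^\top\beta}, forms
#' \deqn{Y_\beta = \ddot\phi^{-1/2}(\theta)\{Y - \dot\phi(\theta) +
#'   \ddot\phi(\theta)\theta\}, \qquad X_\beta = \ddot\phi^{1/2}(\theta) X.}
#' These are the working response and covariates of the locally linearised
#' model, rescaled so the residual variance is (approximately) constant; for
#' the logistic family at the true coefficient,
#' \eqn{\mathrm{Var}(Y_\beta \mid X_\beta) = 1}.  All summary statistics
#' exchanged between sites are moments of \eqn{(X_\beta, Y_\beta)}.
#'
#' For the linear family \eqn{\ddot\phi \equiv 1} and the transform is the
#' identity for any \eqn{\beta}.
#'
#' @inheritParams ds_loss
#' @return list with elements \code{Xb}, \code{Yb}, \code{theta}.
#' @export
ds_adjust <- function(X, Y, beta, family) {
  family <- as_ds_family(family)
  stopifnot(length(beta) == ncol(X), length(Y) == nrow(X))
  theta <- drop(X %*% beta)
  w <- family$phiddot(theta)
  if (any(w <= 0)) {
    bad <- which(w <= 0)
    stop(sprintf(
      "degenerate adjustment weights (phiddot <= 0) at rows: %s",
      paste(utils::head(bad, 10L), collapse = ", ")
    ), call. = FALSE)
  }
  sw <- sqrt(w)
  list(
    Xb = X * sw,
    Yb = (Y - family$phidot(theta) + w * theta) / sw,
    theta = theta
  )
}
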