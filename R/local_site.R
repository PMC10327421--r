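glmnet_family <- function(family) {
  switch(as_ds_family(family)$name,
    logistic = "binomial",
    linear = "gaussian",
    poisson_log = "poisson")
}

#' Rate-based lasso penalty grid
#'
#' Log-spaced grid of multiples of the lasso rate
#' \eqn{\sqrt{\log p / n}}, the order at which the local penalty must scale
#' for the estimation error of the study-level fit to be negligible in the
#' downstream summaries.
#'
#' @param n,p local sample size and covariate count.
#' @param length grid length.
#' @param range multiplicative range around the rate.
#' @return decreasing numeric vector.
#' @export
lasso_lambda_grid <- function(n, p, length = 30L, range = c(0.05, 4)) {
  rate <- sqrt(log(p) / n)
  sort(exp(seq(log(range[1]), log(range[2]), length.out = length)) * rate,
       decreasing = TRUE)
}

#' Cross-validated local lasso
#'
#' Fits the study-level \eqn{\ell_1}-penalised M-estimator
#' \eqn{\arg\min_\beta \hat{P}f(X^\top\beta, Y) + \lambda\|\beta_{-1}\|_1}
#' (intercept unpenalised) with \code{glmnet}, tuning \eqn{\lambda} by
#' \code{cv_folds}-fold cross-validated deviance over \code{lam_grid}.
#'
#' @param X design matrix including the intercept column of ones.
#' @param Y outcome vector.
#' @param family a [ds_family()] or name.
#' @param lam_grid decreasing penalty grid; defaults to
#'   [lasso_lambda_grid()].
#' @param cv_folds number of CV folds (default 5).
#' @param seed seed fixing the CV fold assignment.
#' @param rule \code{"min"} for the CV-minimising penalty, \code{"1se"} for
#'   the one-standard-error rule (sparser; used for estimators that are
#'   debiased directly, where overfit local coefficients translate into
#'   debiasing bias).
#' @return the fitted coefficient vector of length \code{ncol(X)} with
#'   attribute \code{lambda}, the selected penalty.
#' @export
fit_local_lasso <- function(X, Y, family, lam_grid = NULL, cv_folds = 5L,
                            seed = 1L, rule = c("min", "1se")) {
  family <- as_ds_family(family)
  rule <- match.arg(rule)
  n <- nrow(X); p <- ncol(X) - 1L
  if (is.null(lam_grid)) lam_grid <- lasso_lambda_grid(n, p)
  if (!length(lam_grid)) stop("empty lambda grid", call. = FALSE)
  foldid <- with_seed(seed, sample(rep_len(seq_len(cv_folds), n)))
  cv <- glmnet::cv.glmnet(X[, -1, drop = FALSE], Y,
                          family = glmnet_family(family),
                          lambda = lam_grid, foldid = foldid,
                          type.measure = "deviance", standardize = FALSE,
                          thresh = 1e-10)
  s <- if (rule == "min") cv$lambda.min else cv$lambda.1se
  beta <- unname(drop(as.matrix(stats::coef(cv, s = s))))
  attr(beta, "lambda") <- s
  beta
}

# Single-lambda lasso fit at a fixed penalty (used inside cross-fitting).
# A short decreasing path ending at `lambda` is used for warm starts.
local_lasso_at <- function(X, Y, family, lambda) {
  path <- lambda * c(16, 8, 4, 2, 1)
  fit <- glmnet::glmnet(X[, -1, drop = FALSE], Y,
                        family = glmnet_family(family),
                        lambda = path, standardize = FALSE, thresh = 1e-10)
  unname(drop(as.matrix(stats::coef(fit, s = lambda, exact = FALSE))))
}

#' Study-level summary statistics for the integrative fit
#'
#' On the outer complement \eqn{\mathcal{I}_{-k}} of one study, computes the
#' cross-fitted first- and second-moment summaries
#' \deqn{\hat\xi_{[-k]} = K'^{-1}\sum_{k'} \hat{P}_{\mathcal{I}_{-k,k'}}
#'   X_{\hat\beta} Y_{\hat\beta}, \qquad
#'   \hat{H}_{[-k]} = K'^{-1}\sum_{k'} \hat{P}_{\mathcal{I}_{-k,k'}}
#'   X_{\hat\beta} X_{\hat\beta}^\top,}
#' where for each inner fold \eqn{k'} the adjustment coefficient
#' \eqn{\hat\beta} is the local lasso trained on the other inner folds
#' \eqn{\mathcal{I}_{-k} \setminus \mathcal{I}_{-k,k'}}.  The inner
#' rotation removes the dependence between the fitted coefficient and the
#' observations it is evaluated on.  Only these moments (never rows of
#' data) leave the study.
#'
#' @param study a study (list with \code{X}, \code{Y}).
#' @param plan a [make_folds()] plan for this study.
#' @param k outer fold index in \code{1:K}.
#' @param family a [ds_family()] or name.
#' @param lambda local lasso penalty \eqn{\lambda^{(m)}} (typically CV-tuned
#'   once per study via [fit_local_lasso()]).
#' @return list with \code{n_used} (\eqn{|\mathcal{I}_{-k}|}), \code{xi}
#'   (length p+1), \code{H} ((p+1) x (p+1), symmetric PSD).
#' @export
summary_step1 <- function(study, plan, k, family, lambda) {
  family <- as_ds_family(family)
  stopifnot(inherits(plan, "ds_folds"), k >= 1, k <= plan$K,
            plan$n == nrow(study$X))
  inner <- plan$inner[[k]]
  d <- ncol(study$X)
  xi <- numeric(d); H <- matrix(0, d, d)
  for (kp in seq_len(plan$Kp)) {
    train <- which(!is.na(inner) & inner != kp)
    eval_ <- which(!is.na(inner) & inner == kp)
    # the penalty is tuned at the full study size; rescale it to the
    # sqrt(log p / n) rate of the inner training subset
    lam_kp <- lambda * sqrt(plan$n / length(train))
    beta_hat <- local_lasso_at(study$X[train, , drop = FALSE],
                               study$Y[train], family, lam_kp)
    adj <- ds_adjust(study$X[eval_, , drop = FALSE], study$Y[eval_],
                     beta_hat, family)
    xi <- xi + colMeans(adj$Xb * adj$Yb)
    H <- H + crossprod(adj$Xb) / length(eval_)
  }
  list(n_used = sum(!is.na(inner)), xi = xi / plan$Kp, H = H / plan$Kp)
}

#' Serialize summary payloads
#'
#' Writes/reads the per-(study, fold) message exchanged between a study
#' site and the central node as a compressed archive (one file per
#' message, gzip-compressed, schema-versioned).  The payload is dense —
#' the Hessian makes the message \eqn{O(p^2)} — which is the
#' communication cost of the procedure, not an implementation detail.
#'
#' @param summary a [summary_step1()] or [summary_step2()] payload.
#' @param dir directory for the archive.
#' @param study,k study index and outer fold index naming the message.
#' @return \code{write_summary} returns the file path invisibly;
#'   \code{read_summary} returns the payload.
#' @export
write_summary <- function(summary, dir, study, k) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, sprintf("summary_m%d_k%d.rds", study, k))
  saveRDS(list(schema = 1L, study = study, k = k, payload = summary),
          path, compress = "gzip")
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary <- function(dir, study, k) {
  path <- file.path(dir, sprintf("summary_m%d_k%d.rds", study, k))
  obj <- readRDS(path)
  if (!identical(obj$schema, 1L))
    stop("unknown summary payload schema: ", obj$schema, call. = FALSE)
  obj$payload
}

#' Updated summary statistics on the held-out fold
#'
#' After the integrative coefficient \eqn{\tilde\beta_{[-k]}} (fit without
#' fold k) is returned to the study, the study computes on its held-out
#' fold \eqn{\mathcal{I}_k} the refreshed moments
#' \eqn{\tilde\xi_{[k]} = \hat{P}_{\mathcal{I}_k} X_{\tilde\beta}
#' Y_{\tilde\beta}}, \eqn{\tilde{H}_{[k]} = \hat{P}_{\mathcal{I}_k}
#' X_{\tilde\beta} X_{\tilde\beta}^\top}, and the variance kernel
#' \eqn{\tilde{J}_{[k]} = \hat{P}_{\mathcal{I}_k} X X^\top \{Y -
#' \dot\phi(X^\top\tilde\beta)\}^2}, which uses the raw covariates and
#' squared raw residuals.  These feed the debiasing step and the variance
#' estimates.
#'
#' @inheritParams summary_step1
#' @param beta_tilde the integrative coefficient for this study, estimated
#'   without fold \code{k}.
#' @return list with \code{n_used} (\eqn{|\mathcal{I}_k|}), \code{xi_t},
#'   \code{H_t}, \code{J_t}.
#' @export
summary_step2 <- function(study, plan, k, beta_tilde, family) {
  family <- as_ds_family(family)
  stopifnot(inherits(plan, "ds_folds"), k >= 1, k <= plan$K,
            plan$n == nrow(study$X))
  idx <- which(plan$outer == k)
  X <- study$X[idx, , drop = FALSE]; Y <- study$Y[idx]
  adj <- ds_adjust(X, Y, beta_tilde, family)
  resid <- Y - family$phidot(adj$theta)
  list(
    n_used = length(idx),
    xi_t = colMeans(adj$Xb * adj$Yb),
    H_t = crossprod(adj$Xb) / length(idx),
    J_t = crossprod(X * resid) / length(idx)
  )
}
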