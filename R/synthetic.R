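#' Design specifications for the synthetic generator
#'
#' Two covariate designs mirror the structure of multi-cohort genetic
#' association data: a Gaussian first-order autoregressive design with
#' correlation \code{rho} between adjacent covariates, and a binary
#' hidden-Markov design in which a latent binary chain of length \code{p}
#' flips with probability \code{trans} between positions and each observed
#' bit flips its latent bit with probability \code{emit}.
#'
#' @param kind \code{"ar1"} or \code{"hmm"}.
#' @param p number of covariates (excluding the intercept), at least 2.
#' @param rho AR(1) correlation in \eqn{[0, 1)} (ar1 only).
#' @param trans,emit flip probabilities in \eqn{(0, 1)} (hmm only).
#' @return an object of class \code{ds_design}.
#' @export
ds_design <- function(kind = c("ar1", "hmm"), p, rho = 0.5,
                      trans = 0.2, emit = 0.2) {
  kind <- match.arg(kind)
  p <- as.integer(p)
  if (p < 2L) stop("p must be at least 2", call. = FALSE)
  out <- if (kind == "ar1") {
    if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
    list(kind = kind, p = p, rho = rho)
  } else {
    if (trans <= 0 || trans >= 1 || emit <= 0 || emit >= 1)
      stop("trans and emit must lie in (0, 1)", call. = FALSE)
    list(kind = kind, p = p, trans = trans, emit = emit)
  }
  structure(out, class = "ds_design")
}

#' Signal specification: shared-support heterogeneous coefficients
#'
#' Coefficients across the \code{M} studies share one support of size
#' \code{s} but vary in magnitude: the coefficient of signal covariate
#' \eqn{j} in study \eqn{m} is \eqn{\mu(\nu_j^{(m)} + 1)\psi_j}, where the
#' signs \eqn{\psi_j} are drawn once from \eqn{\{-1, +1\}} and shared across
#' studies, and the study-level perturbations \eqn{\nu_j^{(m)}} are drawn
#' independently from \eqn{N(0, (\mu \cdot \code{nu_sd_factor})^2)}.  With
#' the default factor \eqn{1/2}, a signal coefficient flips sign in a given
#' study with probability \eqn{\Phi(-2) \approx 0.023}.
#'
#' @param M number of studies.
#' @param s support size.
#' @param mu overall signal strength \eqn{\mu \ge 0}.
#' @param nu_sd_factor ratio of \eqn{sd(\nu)} to \eqn{\mu}; default 1/2.
#' @return an object of class \code{ds_signal}.
#' @export
ds_signal <- function(M, s, mu, nu_sd_factor = 0.5) {
  stopifnot(M >= 1, s >= 0, mu >= 0, nu_sd_factor >= 0)
  structure(list(M = as.integer(M), s = as.integer(s), mu = mu,
                 nu_sd_factor = nu_sd_factor),
            class = "ds_signal")
}

#' Gaussian AR(1) design matrix
#'
#' Rows are i.i.d. mean-zero multivariate normal with covariance
#' \eqn{\Sigma_{jk} = \rho^{|j-k|}}, generated by the exact autoregressive
#' recursion so the cost is \eqn{O(np)}.
#'
#' @param n,p dimensions.
#' @param rho adjacent-column correlation in \eqn{[0, 1)}.
#' @param seed integer seed; the same arguments always return the same
#'   matrix.
#' @return an \code{n x p} numeric matrix.
#' @export
make_ar1_design <- function(n, p, rho, seed) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  stopifnot(n >= 1, p >= 1)
  with_seed(seed, {
    X <- matrix(0, n, p)
    X[, 1] <- stats::rnorm(n)
    if (p > 1L) {
      sd_innov <- sqrt(1 - rho^2)
      for (j in 2:p) {
        X[, j] <- rho * X[, j - 1] + sd_innov * stats::rnorm(n)
      }
    }
    X
  })
}

#' Binary hidden-Markov design matrix
#'
#' Each row carries a latent binary chain of length \code{p} started from
#' its stationary distribution \eqn{(1/2, 1/2)} with symmetric flip
#' probability \code{trans}; the observed entry flips the latent bit with
#' probability \code{emit}.  Marginally every column is Bernoulli(1/2);
#' adjacent columns are positively correlated unless \code{emit = 1/2}.
#'
#' @inheritParams make_ar1_design
#' @param trans,emit flip probabilities in \eqn{(0, 1)}.
#' @return an \code{n x p} matrix with entries in \{0, 1\}.
#' @export
make_hmm_design <- function(n, p, trans, emit, seed) {
  if (trans <= 0 || trans >= 1 || emit <= 0 || emit >= 1)
    stop("trans and emit must lie in (0, 1)", call. = FALSE)
  stopifnot(n >= 1, p >= 1)
  with_seed(seed, {
    H <- matrix(0L, n, p)
    H[, 1] <- stats::rbinom(n, 1L, 0.5)
    if (p > 1L) {
      for (j in 2:p) {
        flip <- stats::rbinom(n, 1L, trans)
        H[, j] <- bitwXor(H[, j - 1], flip)
      }
    }
    E <- matrix(stats::rbinom(n * p, 1L, emit), n, p)
    X <- matrix(as.double(bitwXor(H, E)), n, p)
    X
  })
}

#' Draw shared-support heterogeneous coefficients
#'
#' @param spec a [ds_signal()] specification.
#' @param p number of covariates excluding the intercept; \code{spec$s <= p}.
#' @param seed integer seed.
#' @return an \code{M x (p+1)} matrix of true coefficients whose first
#'   column (the intercept) is 0; columns \code{2..(s+1)} carry the signal,
#'   the rest are exactly 0.  Attribute \code{support} gives the signal
#'   column indices (in 1-based coefficient coordinates, intercept = 1).
#' @export
make_coefficients <- function(spec, p, seed) {
  stopifnot(inherits(spec, "ds_signal"))
  if (spec$s > p) stop("support size s exceeds p", call. = FALSE)
  M <- spec$M; s <- spec$s; mu <- spec$mu
  B <- matrix(0, M, p + 1L)
  if (s > 0 && mu > 0) {
    with_seed(seed, {
      psi <- sample(c(-1, 1), s, replace = TRUE)
      nu <- matrix(stats::rnorm(M * s, sd = mu * spec$nu_sd_factor), M, s)
      B[, 2:(s + 1L)] <- mu * (nu + 1) * rep(psi, each = M)
    })
  }
  attr(B, "support") <- if (s > 0 && mu > 0) seq.int(2L, s + 1L) else integer(0)
  B
}

new_study_data <- function(X, Y) {
  stopifnot(nrow(X) == length(Y), all(X[, 1] == 1))
  structure(list(X = X, Y = Y), class = "ds_study")
}

#' Simulate a federated dataset
#'
#' Draws \code{M} independent studies: covariates from the chosen design
#' (with a prepended intercept column), outcomes from the family's
#' conditional law at the study's true coefficients.  The true coefficient
#' matrix and support are stored so that downstream error metrics can be
#' computed.
#'
#' @param design a [ds_design()].
#' @param coef a [ds_signal()]; \code{coef$M} studies are generated.
#' @param family a [ds_family()] or name.
#' @param n_m integer vector of study sample sizes (recycled to length M).
#' @param seed master seed; per-study child seeds are derived with
#'   [derive_seed()].
#' @param noise_sd residual standard deviation for the linear family.
#' @return an object of class \code{ds_federated}: list with \code{studies}
#'   (list of study data, each \code{$X} of size \eqn{n_m \times (p+1)} with
#'   an all-ones first column and \code{$Y}), \code{truth} (coefficients and
#'   support), \code{family}, \code{p}.
#' @examples
#' dat <- simulate_federated(ds_design("ar1", p = 20), ds_signal(3, 4, 0.5),
#'                           "logistic", n_m = 100, seed = 7)
#' sapply(dat$studies, function(s) dim(s$X))
#' @export
simulate_federated <- function(design, coef, family, n_m, seed,
                               noise_sd = 1) {
  stopifnot(inherits(design, "ds_design"), inherits(coef, "ds_signal"))
  family <- as_ds_family(family)
  M <- coef$M
  n_m <- rep_len(as.integer(n_m), M)
  p <- design$p
  B <- make_coefficients(coef, p, derive_seed(seed, 0L))
  studies <- vector("list", M)
  for (m in seq_len(M)) {
    Xraw <- switch(design$kind,
      ar1 = make_ar1_design(n_m[m], p, design$rho, derive_seed(seed, m, 1L)),
      hmm = make_hmm_design(n_m[m], p, design$trans, design$emit,
                            derive_seed(seed, m, 1L))
    )
    X <- cbind(1, Xraw)
    theta <- drop(X %*% B[m, ])
    Y <- with_seed(derive_seed(seed, m, 2L), {
      if (family$name == "linear") family$simulate(theta, noise_sd = noise_sd)
      else family$simulate(theta)
    })
    studies[[m]] <- new_study_data(X, Y)
  }
  structure(
    list(studies = studies,
         truth = list(B = B, support = attr(B, "support")),
         family = family$name, p = p,
         n_m = n_m),
    class = "ds_federated"
  )
}

#' @export
print.ds_federated <- function(x, ...) {
  cat(sprintf(
    "Federated dataset: M = %d studies, p = %d covariates, n_m = %s, family = %s\n",
    length(x$studies), x$p, paste(x$n_m, collapse = "/"), x$family))
  if (!is.null(x$truth))
    cat(sprintf("  true support size: %d\n", length(x$truth$support)))
  invisible(x)
}

#' Write / read a federated dataset as per-study CSV files
#'
#' One headered CSV per study (\code{study1.csv}, ...) with column \code{y}
#' followed by \code{x0} (the intercept column of ones) through \code{xp}.
#' When a truth is available it is written to \code{truth.csv} with one row
#' per (study, coefficient) and a support flag.
#'
#' @param data a \code{ds_federated} object.
#' @param dir output directory (created if needed).
#' @return \code{write_federated} returns \code{dir} invisibly;
#'   \code{read_federated} returns a \code{ds_federated} object (with truth
#'   if \code{truth.csv} is present).
#' @export
write_federated <- function(data, dir) {
  stopifnot(inherits(data, "ds_federated"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in seq_along(data$studies)) {
    st <- data$studies[[m]]
    df <- data.frame(y = st$Y, st$X)
    names(df) <- c("y", paste0("x", seq_len(ncol(st$X)) - 1L))
    utils::write.csv(df, file.path(dir, sprintf("study%d.csv", m)),
                     row.names = FALSE)
  }
  if (!is.null(data$truth)) {
    B <- data$truth$B
    tr <- data.frame(
      study = rep(seq_len(nrow(B)), ncol(B)),
      coef = rep(seq_len(ncol(B)) - 1L, each = nrow(B)),
      beta = as.vector(B),
      in_support = as.integer(rep(seq_len(ncol(B)) %in% data$truth$support,
                                  each = nrow(B)))
    )
    utils::write.csv(tr, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  writeLines(data$family, file.path(dir, "family.txt"))
  invisible(dir)
}

#' @rdname write_federated
#' @param family family name; defaults to the one recorded in the directory.
#' @export
read_federated <- function(dir, family = NULL) {
  files <- sort(list.files(dir, pattern = "^study[0-9]+\\.csv$",
                           full.names = TRUE))
  if (!length(files)) stop("no study CSV files found in ", dir, call. = FALSE)
  ord <- order(as.integer(sub("^study([0-9]+)\\.csv$", "\\1",
                              basename(files))))
  files <- files[ord]
  studies <- lapply(files, function(f) {
    df <- utils::read.csv(f)
    new_study_data(as.matrix(df[, -1, drop = FALSE]), df$y)
  })
  p <- ncol(studies[[1]]$X) - 1L
  if (is.null(family)) {
    ff <- file.path(dir, "family.txt")
    family <- if (file.exists(ff)) readLines(ff, n = 1L) else "logistic"
  }
  truth <- NULL
  tf <- file.path(dir, "truth.csv")
  if (file.exists(tf)) {
    tr <- utils::read.csv(tf)
    M <- max(tr$study)
    B <- matrix(0, M, p + 1L)
    B[cbind(tr$study, tr$coef + 1L)] <- tr$beta
    truth <- list(B = B, support = sort(unique(tr$coef[tr$in_support == 1L] + 1L)))
  }
  structure(list(studies = studies, truth = truth,
                 family = family, p = p,
                 n_m = vapply(studies, function(s) length(s$Y), 1L)),
            class = "ds_federated")
}
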