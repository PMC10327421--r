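`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pipeline configuration
#'
#' Collects the tuning choices shared by the three testing pipelines.
#' Defaults follow the simulation protocol used throughout: two outer
#' folds, five inner folds, nominal FDR level 0.1, BIC scaling for the
#' integrative penalty selection, a five-point radius grid around the
#' theoretical rate, and ten tail evaluation points for the radius
#' calibration.
#'
#' @param family outcome family name or [ds_family()].
#' @param K even number of outer folds.
#' @param Kp number of inner folds.
#' @param alpha nominal FDR level.
#' @param lambda_grid optional integrative penalty grid (defaults to
#'   [group_lambda_grid()] at the data's dimensions).
#' @param tau_grid_c multiples of [tau_rate()] scanned for the debiasing
#'   radius.
#' @param H_grid evaluation points for [select_tau()].
#' @param cv_folds folds for the study-level lasso cross-validation.
#' @param gic_gamma optional GIC scaling (default BIC, see [gic()]).
#' @param test_set coefficient indices to test; default all non-intercept
#'   coordinates \code{2:(p+1)}.
#' @param seed seed governing fold assignments and CV splits.
#' @param dantzig_tol,dantzig_feas_tol,dantzig_maxit,dantzig_plateau ADMM
#'   controls for [solve_group_dantzig()].
#' @return a \code{ds_config} list.
#' @export
ds_config <- function(family = "logistic", K = 2L, Kp = 5L, alpha = 0.1,
                      lambda_grid = NULL, tau_grid_c = c(0.5, 1, 2, 4),
                      H_grid = 10L, cv_folds = 5L, gic_gamma = NULL,
                      test_set = NULL, seed = 1L,
                      dantzig_tol = 2e-3, dantzig_feas_tol = 1e-6,
                      dantzig_maxit = 2000L, dantzig_plateau = 1e-3) {
  K <- as.integer(K)
  if (K < 2L || K %% 2L != 0L) stop("K must be even and >= 2", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  if (!length(tau_grid_c)) stop("tau grid must be nonempty", call. = FALSE)
  structure(list(family = as_ds_family(family), K = K, Kp = as.integer(Kp),
                 alpha = alpha, lambda_grid = lambda_grid,
                 tau_grid_c = sort(unique(tau_grid_c)),
                 H_grid = as.integer(H_grid), cv_folds = as.integer(cv_folds),
                 gic_gamma = gic_gamma, test_set = test_set,
                 seed = as.integer(seed),
                 dantzig_tol = dantzig_tol,
                 dantzig_feas_tol = dantzig_feas_tol,
                 dantzig_maxit = as.integer(dantzig_maxit),
                 dantzig_plateau = dantzig_plateau),
            class = "ds_config")
}

# Debiasing + radius calibration shared by all three pipelines.
# beta_tilde_per_fold: list k -> M x d; s2_per_fold: list k -> list m.
debias_stage <- function(beta_tilde_per_fold, s2_per_fold, n_m, H_set, cfg) {
  K <- length(s2_per_fold)
  M <- length(n_m)
  d <- ncol(beta_tilde_per_fold[[1]])
  fold_n <- unlist(lapply(s2_per_fold, function(sk)
    vapply(sk, `[[`, 0, "n_used")))
  rate <- tau_rate(M, d - 1L, mean(fold_n))
  taus <- sort(cfg$tau_grid_c * rate, decreasing = TRUE)
  Hb <- lapply(s2_per_fold, function(sk) lapply(sk, `[[`, "H_t"))

  proj_by_tau <- list()
  states <- vector("list", K)
  kept <- character(0)
  for (tau in taus) {
    pk <- vector("list", K)
    ok <- TRUE
    for (k in seq_len(K)) {
      res <- tryCatch(
        solve_group_dantzig(Hb[[k]], H_set, tau, warm = states[[k]],
                            tol = cfg$dantzig_tol,
                            feas_tol = max(cfg$dantzig_feas_tol,
                                           1e-3 * tau),
                            maxit = cfg$dantzig_maxit,
                            plateau_tol = cfg$dantzig_plateau),
        dsilt_dantzig_infeasible = function(e) NULL)
      if (is.null(res)) { ok <- FALSE; break }
      states[[k]] <- res$state
      # a radius only enters the calibration if every tested coordinate
      # obtained a certified-feasible direction on every fold
      if (any(res$feasibility > tau * (1 + 2e-3) + 1e-7)) { ok <- FALSE; break }
      pk[[k]] <- res
    }
    if (ok) {
      key <- format(tau, digits = 12)
      proj_by_tau[[key]] <- pk
      kept <- c(kept, key)
    }
  }
  if (!length(proj_by_tau))
    stop("no feasible debiasing radius in the grid; enlarge tau_grid_c",
         call. = FALSE)

  null_signs <- rep(c(1, -1), each = K / 2)
  stats_by_tau <- lapply(proj_by_tau, function(pk) {
    sig2 <- estimate_variance(pk, s2_per_fold)
    sigma <- sqrt(sig2)
    bb <- debias_coefficients(beta_tilde_per_fold, pk, s2_per_fold)
    bn <- debias_coefficients(beta_tilde_per_fold, pk, s2_per_fold,
                              signs = null_signs)
    list(sigma = sigma, beta_breve = bb, beta_null = bn,
         zeta = group_statistic(bb, sigma, n_m),
         zeta_null = group_statistic(bn, sigma, n_m))
  })
  sel <- select_tau(lapply(stats_by_tau, `[[`, "zeta_null"), M,
                    H_grid = cfg$H_grid)
  chosen_key <- names(stats_by_tau)[sel$index]
  chosen <- stats_by_tau[[chosen_key]]
  list(tau = as.numeric(chosen_key), tau_report = sel,
       beta_breve = chosen$beta_breve, sigma_hat = chosen$sigma,
       zeta = chosen$zeta, zeta_null = chosen$zeta_null,
       beta_null = chosen$beta_null,
       proj = proj_by_tau[[chosen_key]], rate = rate)
}

finish_outcome <- function(stage, data, cfg, H_set, method, extras = list()) {
  M <- length(data$studies)
  N <- normal_transform(stage$zeta, M)
  out <- find_threshold(N, cfg$alpha)
  out$method <- method
  out$H_index <- H_set
  out$coef_rejected <- H_set[out$rejected]
  out$zeta <- stage$zeta
  out$zeta_null <- stage$zeta_null
  out$beta_null <- stage$beta_null
  out$beta_breve <- stage$beta_breve
  out$sigma_hat <- stage$sigma_hat
  out$tau <- stage$tau
  out$tau_report <- stage$tau_report
  out$n_m <- data$n_m
  for (nm in names(extras)) out[[nm]] <- extras[[nm]]
  if (!is.null(data$truth)) {
    em <- error_metrics(out$coef_rejected,
                        intersect(data$truth$support, H_set), H_set)
    out$fdp <- em$fdp
    out$power <- em$power
  }
  out
}

#' Run the data-shielding integrative testing pipeline
#'
#' Executes the full three-step procedure on a federated dataset: (1) for
#' each outer fold, every study computes cross-fitted score/Hessian
#' summaries around its local lasso, and the central node fits the
#' group-lasso integrative estimator with a GIC-selected penalty; (2) each
#' study refreshes its summaries at the integrative coefficients on the
#' held-out fold, and the central node debiases every tested coordinate
#' through group Dantzig-selector projections with a null-calibrated
#' radius; (3) the chi-square group statistics are transformed and
#' thresholded to control the FDR.  Only summary objects cross the study
#' boundary: the estimation and testing code receives moments, never rows.
#'
#' @param data a \code{ds_federated} object (see [simulate_federated()] or
#'   [read_federated()]).
#' @param cfg a [ds_config()].
#' @return a \code{ds_test_outcome} with the rejection set
#'   (\code{coef_rejected}, coefficient indices with intercept = 1), the
#'   statistics and debiased estimates, the selected radius and penalties,
#'   and — when the dataset carries its truth — \code{fdp} and
#'   \code{power}.
#' @export
run_dsilt <- function(data, cfg = ds_config()) {
  stopifnot(inherits(data, "ds_federated"))
  family <- cfg$family
  M <- length(data$studies)
  d <- data$p + 1L
  H_set <- cfg$test_set %||% seq.int(2L, d)
  n_m <- data$n_m

  lam_m <- numeric(M)
  plans <- vector("list", M)
  for (m in seq_len(M)) {
    st <- data$studies[[m]]
    bh <- fit_local_lasso(st$X, st$Y, family,
                          cv_folds = cfg$cv_folds,
                          seed = derive_seed(cfg$seed, m, 11L))
    lam_m[m] <- attr(bh, "lambda")
    plans[[m]] <- make_folds(n_m[m], cfg$K, cfg$Kp,
                             derive_seed(cfg$seed, m, 12L))
  }

  s1 <- lapply(seq_len(cfg$K), function(k)
    lapply(seq_len(M), function(m)
      summary_step1(data$studies[[m]], plans[[m]], k, family, lam_m[m])))

  lambda_k <- numeric(cfg$K)
  beta_tilde <- vector("list", cfg$K)
  for (k in seq_len(cfg$K)) {
    sel <- select_lambda(s1[[k]], grid = cfg$lambda_grid,
                         gamma = cfg$gic_gamma)
    lambda_k[k] <- sel$lambda
    beta_tilde[[k]] <- sel$B
  }

  s2 <- lapply(seq_len(cfg$K), function(k)
    lapply(seq_len(M), function(m)
      summary_step2(data$studies[[m]], plans[[m]], k,
                    beta_tilde[[k]][m, ], family)))

  stage <- debias_stage(beta_tilde, s2, n_m, H_set, cfg)
  finish_outcome(stage, data, cfg, H_set, "dsilt",
                 extras = list(lambda = lambda_k, lambda_local = lam_m,
                               beta_tilde = beta_tilde,
                               payload_bytes = as.numeric(
                                 utils::object.size(s1) +
                                   utils::object.size(s2))))
}

#' One-shot comparator: local debiasing, single transfer
#'
#' Each study fits its own lasso, debiases it locally with the
#' single-study specialisation of the group Dantzig selector (radius
#' calibrated by the single-study analogue of the null-contrast
#' criterion), and transmits only the debiased estimates and standard
#' errors.  The central node forms the same chi-square group statistics
#' and runs the same thresholding step as the integrative pipeline.  There
#' is no integrative estimation round, so no strength is borrowed across
#' studies at the estimation stage.
#'
#' @inheritParams run_dsilt
#' @return a \code{ds_test_outcome}.
#' @export
run_oneshot <- function(data, cfg = ds_config()) {
  stopifnot(inherits(data, "ds_federated"))
  family <- cfg$family
  M <- length(data$studies)
  d <- data$p + 1L
  H_set <- cfg$test_set %||% seq.int(2L, d)
  n_m <- data$n_m
  q <- length(H_set)

  beta_breve <- matrix(0, M, q)
  sigma_hat <- matrix(0, M, q)
  taus <- numeric(M)
  for (m in seq_len(M)) {
    st <- data$studies[[m]]
    plan <- make_folds(n_m[m], cfg$K, cfg$Kp,
                       derive_seed(cfg$seed, m, 12L))
    bt <- vector("list", cfg$K)
    s2 <- vector("list", cfg$K)
    for (k in seq_len(cfg$K)) {
      idx <- which(plan$outer != k)
      # the local lasso is the estimator being debiased here, so its
      # penalty is cross-validated within the very subset it is fit on,
      # with the sparser 1-SE rule: an overfit local fit turns directly
      # into debiasing bias
      bloc <- fit_local_lasso(st$X[idx, , drop = FALSE], st$Y[idx],
                              family, cv_folds = cfg$cv_folds,
                              seed = derive_seed(cfg$seed, m, k, 13L),
                              rule = "1se")
      bt[[k]] <- matrix(as.numeric(bloc), nrow = 1)
      s2[[k]] <- list(summary_step2(st, plan, k, as.numeric(bloc), family))
    }
    stage <- debias_stage(bt, s2, n_m[m], H_set, cfg)
    beta_breve[m, ] <- stage$beta_breve[1, ]
    sigma_hat[m, ] <- stage$sigma_hat[1, ]
    taus[m] <- stage$tau
  }
  zeta <- group_statistic(beta_breve, sigma_hat, n_m)
  stage <- list(tau = taus, tau_report = NULL, beta_breve = beta_breve,
                sigma_hat = sigma_hat, zeta = zeta)
  finish_outcome(stage, data, cfg, H_set, "oneshot")
}

# Individual-level group-lasso fit on the pooled out-of-fold data, by
# proximal Newton: at the current coefficients compute the exact per-study
# adjusted moments, solve the quadratic group-lasso subproblem (penalty by
# GIC), repeat.  For the linear family the quadratic model is exact and one
# iteration suffices.
ilma_group_lasso <- function(data, plans, k, cfg, max_outer = 6L,
                             tol = 1e-6) {
  family <- cfg$family
  M <- length(data$studies)
  d <- data$p + 1L
  B <- matrix(0, M, d)
  lambda <- NA_real_
  for (t in seq_len(max_outer)) {
    sums <- lapply(seq_len(M), function(m) {
      idx <- which(plans[[m]]$outer != k)
      X <- data$studies[[m]]$X[idx, , drop = FALSE]
      Y <- data$studies[[m]]$Y[idx]
      adj <- ds_adjust(X, Y, B[m, ], family)
      list(n_used = length(idx), xi = colMeans(adj$Xb * adj$Yb),
           H = crossprod(adj$Xb) / length(idx))
    })
    sel <- select_lambda(sums, grid = cfg$lambda_grid,
                         gamma = cfg$gic_gamma)
    delta <- max(abs(sel$B - B))
    B <- sel$B
    lambda <- sel$lambda
    if (family$name == "linear" && t >= 1L) break
    if (delta < tol) break
  }
  attr(B, "lambda") <- lambda
  B
}

#' Individual-level meta-analysis comparator
#'
#' The idealised benchmark with all raw data pooled at the central node:
#' the integrative group-lasso estimator is fit directly on individual
#' records (by proximal Newton on the pooled quasi-likelihood), after
#' which the debiasing, radius calibration and thresholding stages are the
#' very same code path as the data-shielding pipeline.  Differences
#' between the two methods therefore isolate the cost of communicating
#' only summaries.
#'
#' @inheritParams run_dsilt
#' @return a \code{ds_test_outcome}.
#' @export
run_ilma <- function(data, cfg = ds_config()) {
  stopifnot(inherits(data, "ds_federated"))
  family <- cfg$family
  M <- length(data$studies)
  d <- data$p + 1L
  H_set <- cfg$test_set %||% seq.int(2L, d)
  n_m <- data$n_m

  plans <- lapply(seq_len(M), function(m)
    make_folds(n_m[m], cfg$K, cfg$Kp, derive_seed(cfg$seed, m, 12L)))

  beta_tilde <- vector("list", cfg$K)
  lambda_k <- numeric(cfg$K)
  for (k in seq_len(cfg$K)) {
    B <- ilma_group_lasso(data, plans, k, cfg)
    beta_tilde[[k]] <- B
    lambda_k[k] <- attr(B, "lambda")
  }
  s2 <- lapply(seq_len(cfg$K), function(k)
    lapply(seq_len(M), function(m)
      summary_step2(data$studies[[m]], plans[[m]], k,
                    beta_tilde[[k]][m, ], family)))
  stage <- debias_stage(beta_tilde, s2, n_m, H_set, cfg)
  finish_outcome(stage, data, cfg, H_set, "ilma",
                 extras = list(lambda = lambda_k, beta_tilde = beta_tilde))
}

run_method <- function(method, data, cfg) {
  switch(method,
         dsilt = run_dsilt(data, cfg),
         oneshot = run_oneshot(data, cfg),
         ilma = run_ilma(data, cfg),
         stop("unknown method: ", method, call. = FALSE))
}

#' Replication study over simulation settings
#'
#' Runs the selected pipelines on matched simulated replicates of each
#' setting (all methods see identical data within a replication) and
#' aggregates the empirical FDR (mean FDP) and power.
#'
#' @param settings data.frame with one row per setting; recognised columns:
#'   \code{design} ("ar1"/"hmm"), \code{p}, \code{rho}, \code{trans},
#'   \code{emit}, \code{M}, \code{n_m}, \code{s}, \code{mu},
#'   \code{family}.  Missing columns fall back to the AR(1), logistic
#'   defaults.
#' @param methods subset of \code{c("dsilt", "oneshot", "ilma")}.
#' @param reps replications per setting.
#' @param seed master seed; replication r of setting i uses
#'   \code{derive_seed(seed, i, r)} for the data and configuration.
#' @param cfg base [ds_config()]; the family is taken from the setting.
#' @return list with \code{per_rep} (one row per setting x method x
#'   replication: fdp, power, rejections, tau, threshold) and
#'   \code{aggregate} (mean FDP = empirical FDR, mean power, and their
#'   Monte-Carlo standard errors).
#' @export
run_experiment <- function(settings, methods = c("dsilt", "oneshot", "ilma"),
                           reps = 10L, seed = 1L, cfg = ds_config()) {
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  for (i in seq_len(nrow(settings))) {
    s <- settings[i, ]
    design <- ds_design(s$design %||% "ar1", p = s$p,
                        rho = s$rho %||% 0.5,
                        trans = s$trans %||% 0.2, emit = s$emit %||% 0.2)
    signal <- ds_signal(s$M, s$s, s$mu)
    fam <- s$family %||% "logistic"
    for (r in seq_len(reps)) {
      rep_seed <- derive_seed(seed, i, r)
      data <- simulate_federated(design, signal, fam, n_m = s$n_m,
                                 seed = rep_seed)
      cfg_r <- cfg
      cfg_r$family <- as_ds_family(fam)
      cfg_r$seed <- derive_seed(rep_seed, 99L)
      for (meth in methods) {
        out <- tryCatch(run_method(meth, data, cfg_r), error = function(e) e)
        if (inherits(out, "error")) {
          warning(sprintf("setting %d rep %d method %s failed: %s",
                          i, r, meth, conditionMessage(out)), call. = FALSE)
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          setting = i, design = design$kind, p = s$p, M = s$M,
          n_m = s$n_m, s = s$s, mu = s$mu, method = meth, rep = r,
          fdp = out$fdp, power = out$power,
          rejections = length(out$rejected), t_hat = out$t_hat)
      }
    }
  }
  per_rep <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(
    split(per_rep, interaction(per_rep$setting, per_rep$method, drop = TRUE)),
    function(g) data.frame(
      setting = g$setting[1], design = g$design[1], p = g$p[1], M = g$M[1],
      n_m = g$n_m[1], s = g$s[1], mu = g$mu[1], method = g$method[1],
      reps = nrow(g), fdr = mean(g$fdp), power = mean(g$power),
      fdr_se = stats::sd(g$fdp) / sqrt(nrow(g)),
      power_se = stats::sd(g$power) / sqrt(nrow(g)))))
  rownames(agg) <- NULL
  list(per_rep = per_rep, aggregate = agg)
}

#' Plot aggregated replication results
#'
#' Empirical FDR and power against the signal strength, one line per
#' method, faceted by error metric and support size.  Requires ggplot2.
#'
#' @param result the list returned by [run_experiment()].
#' @return a ggplot object.
#' @export
plot_experiment <- function(result) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_experiment requires ggplot2", call. = FALSE)
  agg <- result$aggregate
  long <- rbind(
    data.frame(agg[c("mu", "s", "method")], metric = "FDR",
               value = agg$fdr, se = agg$fdr_se),
    data.frame(agg[c("mu", "s", "method")], metric = "power",
               value = agg$power, se = agg$power_se))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mu, y = .data$value,
                                     colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$value - .data$se,
                                        ymax = .data$value + .data$se),
                           width = 0) +
    ggplot2::facet_grid(metric ~ s, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "signal strength mu", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Results table of a testing outcome
#'
#' One row per tested coordinate: the per-study debiased estimates and
#' standard errors, the group statistic, its normal transform, and the
#' rejection flag.
#'
#' @param outcome a \code{ds_test_outcome} from one of the pipelines.
#' @param file optional path; when given the table is written as CSV.
#' @return the data.frame, invisibly when writing.
#' @export
results_table <- function(outcome, file = NULL) {
  M <- nrow(outcome$beta_breve)
  df <- data.frame(coef = outcome$H_index)
  for (m in seq_len(M)) {
    df[[sprintf("beta_breve_%d", m)]] <- outcome$beta_breve[m, ]
    df[[sprintf("se_%d", m)]] <- outcome$sigma_hat[m, ] / sqrt(outcome$n_m[m])
  }
  df$zeta <- outcome$zeta
  df$N <- outcome$N
  df$rejected <- df$coef %in% outcome$coef_rejected
  if (!is.null(file)) {
    utils::write.csv(df, file, row.names = FALSE)
    return(invisible(df))
  }
  df
}
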