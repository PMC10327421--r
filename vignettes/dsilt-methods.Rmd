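---
title: "Federated simultaneous inference with dsilt: models, tuning and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federated simultaneous inference with dsilt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsilt)
```

## The problem

`dsilt` tests, simultaneously for every covariate $j$, whether the covariate
carries any effect on an outcome in *any* of $M$ independent studies, when
the studies cannot pool individual-level records.  Each study $m$ holds
$n_m$ observations $(Y_i^{(m)}, X_i^{(m)})$ with $X^{(m)} \in \mathbb{R}^{p+1}$
(first coordinate the intercept) and a conditional-mean model
$E(Y \mid X) = \dot\phi(X^\top \beta_0^{(m)})$ defined by a convex
per-observation loss $f(x, y) = \phi(x) - yx$ — logistic
($\phi(x) = \log(1+e^x)$), linear ($\phi(x) = x^2/2$), or log-link count
($\phi(x) = e^x$, provided for completeness but outside the calibration
studies because count residuals are not sub-Gaussian).  The hypotheses are
group nulls
$$H_{0,j}: \beta_{0,j} = (\beta_{0,j}^{(1)}, \dots, \beta_{0,j}^{(M)}) = 0,
  \qquad j \in \mathcal{H} \subseteq \{2, \dots, p+1\},$$
and the procedure controls the false discovery rate and proportion over
$\mathcal{H}$ while borrowing strength across studies: the coefficient
vectors are assumed sparse with *similar* (not identical) supports.

Only summary statistics — score-type vectors and Hessian-type matrices of
the per-study data — ever leave a study.  The package enforces this
structurally: the central estimation and testing stages consume only the
summary objects produced by `summary_step1()` / `summary_step2()`, and the
test suite includes an audit that mutating one study's rows leaves every
other study's messages bit-identical.

## The procedure

**Step 1 (integrative estimation).** Each study partitions its rows into
$K$ outer folds; on the complement $\mathcal{I}_{-k}$ of each fold it fits
a local lasso and, rotating over $K'$ inner folds, evaluates the
heteroscedasticity-adjusted moments
$\hat\xi^{(m)} = \hat P[X_\beta Y_\beta]$ and
$\hat H^{(m)} = \hat P[X_\beta X_\beta^\top]$, where
$Y_\beta = \ddot\phi^{-1/2}(\theta)\{Y - \dot\phi(\theta) +
\ddot\phi(\theta)\theta\}$ and $X_\beta = \ddot\phi^{1/2}(\theta)X$
at $\theta = X^\top \hat\beta$.  The inner rotation (train on the other
inner folds, evaluate on this one) removes the correlation between the
plug-in coefficient and the evaluated rows.  The central node then solves
the summary-statistic group lasso
$$\tilde\beta_{[-k]} = \arg\min_\beta \; |\mathcal{I}_{-k}|^{-1} \sum_m
  |\mathcal{I}_{-k}^{(m)}| \left(\beta^{(m)\top}\hat H^{(m)}\beta^{(m)}
  - 2\beta^{(m)\top}\hat\xi^{(m)}\right)
  + \lambda \sum_{j \ge 2} \lVert \beta_j \rVert_2 ,$$
whose penalty couples each covariate's coefficients across studies and so
induces a shared support.  For the linear family the moments are exact
sufficient statistics and this fit *equals* the pooled individual-level
fit — the package tests this equivalence against an independent
proximal-gradient solver.

**Step 2 (debiasing and group statistics).** Each study refreshes
$\tilde\xi, \tilde H$ on the held-out fold at $\tilde\beta_{[-k]}$ and adds
$\tilde J = \hat P[XX^\top\{Y - \dot\phi(X^\top\tilde\beta)\}^2]$.  For
every tested coordinate the central node solves the group Dantzig selector
$$\hat u_j = \arg\min_u \max_m \lVert u^{(m)} \rVert_1
  \quad\text{s.t.}\quad
  \big\lVert \tilde H^{(\bullet)} u^{(\bullet)} - e_j^{(\bullet)}
  \big\rVert_{2,\infty} \le \tau ,$$
i.e. for every coordinate $\ell$ the $M$-vector of Hessian residuals must
have Euclidean norm at most $\tau$.  The debiased estimate averages the
one-step corrections over folds,
$\breve\beta_j^{(m)} = K^{-1}\sum_k \{\tilde\beta_{j,[-k]}^{(m)} +
\hat u_{j,[k]}^{(m)\top}(\tilde\xi_{[k]}^{(m)} -
\tilde H_{[k]}^{(m)}\tilde\beta_{[-k]}^{(m)})\}$, with variance
$(\hat\sigma_j^{(m)})^2 = K^{-1}\sum_k u^\top \tilde J u$ and group
statistic $\breve\zeta_j = \sum_m n_m (\breve\beta_j^{(m)} /
\hat\sigma_j^{(m)})^2$, asymptotically $\chi^2_M$ under $H_{0,j}$.

**Step 3 (multiple testing).** The normal-quantile transform
$\mathcal{N}_j = \bar\Phi^{-1}\{\bar F_{\chi^2_M}(\breve\zeta_j)/2\}$ maps
each statistic to the scale of $|N(0,1)|$, and the threshold
$$\hat t = \inf\Big\{0 \le t \le t_q :
  \frac{2q\bar\Phi(t)}{R(t) \vee 1} \le \alpha\Big\},
  \qquad t_q = (2\log q - 2\log\log q)^{1/2},$$
estimates the false-positive count by $2q\bar\Phi(t)$ — consistent only up
to $t_q$, which is why the search stops there and falls back to
$(2\log q)^{1/2}$ when no threshold qualifies; stopping at $t_q$ instead
would over-reject.  The infimum is computed exactly: on each interval
where $R$ is constant the condition reduces to
$t \ge \bar\Phi^{-1}(\alpha R/(2q))$, so no grid is involved (the test
suite checks agreement with an exhaustive grid search).

## Tuning parameters

* **Local penalties $\lambda^{(m)}$** — cross-validated deviance within
  each study over 30 log-spaced multiples of $\sqrt{\log p / n}$ (range
  0.05–4).  When a fit is computed on a subset (inner cross-fitting), the
  study-level choice is rescaled by $\sqrt{n / n_{\text{train}}}$ to stay
  on the rate.  For the One-shot comparator the local lasso *is* the
  estimator being debiased, so its penalty is cross-validated within the
  very subset it is fit on, with the one-standard-error rule: the local
  fit's estimation error enters the comparator's debiasing bias directly
  (there is no integrative round to absorb it), and the sparser rule
  trades a little fit for a much smaller error norm.
* **Integrative penalty $\lambda$** — chosen by a generalized information
  criterion on derived data only: $\mathrm{GIC}(\lambda) = \mathrm{Dev} +
  \gamma\,\mathrm{DF}$, with DF the trace of the penalised-to-unpenalised
  restricted Hessian ratio (at $\lambda = 0$ it equals the active-set
  size) and $\gamma = \log|\mathcal{I}_{-k}| / |\mathcal{I}_{-k}|$ (BIC)
  by default; `gic_gamma` exposes the scaling.  The grid is 25 log-spaced
  points over $[0.05, 2] \times 2\sqrt{(M + \log p)/\bar n}/M$ — the rate
  at which the group penalty dominates the gradient noise of the
  quadratic deviance.  BIC is consistent but conservative: at small
  per-study sizes it can prefer the empty model when many weak signals
  are spread over a large support (the total deviance gain of even the
  true model then falls below the BIC increment of its degrees of
  freedom).  This matters for the dense-weak replications discussed
  below.
* **Debiasing radius $\tau$** — scanned over $\{0.5, 1, 2, 4\} \times
  \sqrt{(M + \log p)/\bar n_k}$ with $\bar n_k$ the average per-study fold
  size.  Radii below half the rate are omitted: with fold sizes near the
  dimension the constraint is usually infeasible there, and when feasible
  the calibration criterion never chose them in our replications.  The
  radius is selected by the null-contrast device: recombining the
  per-fold corrections with signs $+1$ on the first $K/2$ folds and $-1$
  on the rest cancels any true signal, and
  $$\hat d(\tau) = H^{-1} \sum_{h=1}^{H} \Big[
    \hat R_{0,\mathrm{null}}\{\bar\Phi^{-1}(x_h) \mid \tau\} / (2qx_h)
    - 1 \Big]^2 , \qquad x_h = \bar\Phi\{(2\log q)^{1/2}\}\,h/H,\; H = 10,$$
  scores how well the null-centred statistics reproduce the expected tail
  counts exactly where the threshold search operates.  At moderate $q$
  the expected tail counts are fractions of one, so the criterion is
  asymmetric: a radius whose null statistics overshoot the tail is
  penalised enormously, while all sufficiently conservative radii score
  close to 1 and ties resolve to the smallest.  The selection is thus
  deliberately conservative.
* **Folds** — $K = 2$ outer folds (even $K$ is required by the
  null-contrast device) and $K' = 5$ inner folds; $\alpha = 0.1$.

## The synthetic generator

`simulate_federated()` reproduces the structure of multi-cohort
association studies: covariates either Gaussian AR(1) with adjacent
correlation $\rho = 0.5$ or a binary hidden-Markov design (latent chain
flip 0.2, emission flip 0.2 — the test suite pins the implied
adjacent-column correlation, 0.216 at the defaults, to an exact
enumeration of the pair chain); coefficients share one support of size
$s$ but vary across studies, $\beta_{0,j}^{(m)} = \mu(1 + \nu_j^{(m)})\psi_j$
with shared Rademacher signs $\psi_j$ and independent
$\nu_j^{(m)} \sim N(0, (\mu/2)^2)$; logistic outcomes drawn at the linear
predictor.  A master seed fans out to per-study, per-purpose child seeds
through a fixed integer hash (`derive_seed()`), so studies are
independent yet every dataset is reproducible bit for bit.

What the generator does *not* emulate: confounding structure, covariate
distributions that differ across studies, missing data, or
case-control sampling.  Calibration results on these simulations
therefore speak to the procedure's error control under the assumed
sampling, not to robustness against real-data artefacts.

## Numerical choices

The group-lasso subproblem is solved by cyclic block coordinate descent
with an exact group update: because the curvature of the quadratic
deviance differs across studies, the per-group minimiser solves a scalar
fixed-point equation (bisection to machine precision) rather than a
closed-form shrinkage; sweeps alternate between the active set and full
passes, tolerance $10^{-7}$ on the largest update, cap 5000 sweeps.
Objective monotonicity and KKT conditions are asserted in the tests.

The group Dantzig program is a second-order cone problem.  It is solved
by a two-block ADMM on the splitting $x_1 = x_2$, $z = Kx_2$ with
$K = \mathrm{diag}(\tilde H^{(m)})$: the $x_1$ update is the proximal map
of $\max_m \lVert\cdot\rVert_1$ (computed by a water-filling bisection
over the shared epigraph level), the $z$ update projects each
coordinate's $M$-vector onto a $\tau$-ball, and the $x_2$ update solves
$(I + K^\top K)x_2 = \text{rhs}$ with per-study Cholesky factors computed
once per fold and shared across all tested coordinates, radii and warm
starts.  Cold starts are placed at ridge-regularised inverse directions
$(\tilde H^{(m)} + \varepsilon I)^{-1} e_j$.  Every returned direction
carries a feasibility certificate recomputed outside the solver.  For
the large replication runs the per-coordinate solves are accepted once
certificate-feasible (relative slack $10^{-3}\tau$) with a stabilised
objective; the exactness tests instead run the solver to $10^{-9}$ and
match reference objectives from an independent SQP/LP solver to
$10^{-6}$.  Degenerate inputs: indefinite summary Hessians are rejected;
variance estimates are floored at $10^{-12}$ with a warning; logistic
linear predictors are clipped at $\pm 30$ inside exponentials.

## Replication-study design and what it shows

The packaged calibration studies (`scripts/acceptance.R`, and reduced
versions in the test suite) run the three pipelines on matched replicates
at $M = 3$ studies, $n_m = 300$, $p = 120$, AR(1) design: a sparse-strong
setting ($s = 10$, $\mu = 0.35$) for FDR control and the comparison with
the pooled individual-level benchmark (10 replications), and dense-weak
($s = 50$, $\mu = 0.30$) and sparse ($s = 10$, $\mu = 0.30$) settings for
the comparison with the One-shot strategy (4 replications each).  These
sizes are this package's replication choices; they trade Monte-Carlo
resolution for breadth across settings, and the reported Monte-Carlo
standard errors carry the uncertainty.

Two behaviours of the *procedure itself* at these sizes deserve note.
First, the radius calibration's conservatism (above) combined with BIC's
conservatism keeps the empirical FDR well below the nominal level — the
error-control guarantee holds with room to spare, at a cost in power.
Second, in the dense-weak setting the scaled sizes put the integrative
estimation outside its working range: $s = 50$ active groups among
$p = 120$ covariates with per-study fold size 150 means the true model's
total deviance gain falls below the BIC increment of its own degrees of
freedom, the criterion selects the empty model, and the debiasing step
then expands around a working point far from the truth.  At the original
study sizes ($M = 5$, $n_m = 500$, $p = 500$) the same code selects a
non-trivial model in the same dense setting.  Users analysing data with
many weak, dense effects at small $n$ should consider a lighter `gic_gamma`
(AIC) and should expect the One-shot comparison to look very different
than in well-powered regimes.

## Known limitations

Binary outcomes only exercise the logistic family in the calibration
suite; the count family is untested theory-side.  The procedure assumes
sub-Gaussian residuals and well-conditioned population Hessians.  The
communication payload is $O(p^2)$ per study and fold (the Hessians are
sent dense).  Networked deployment, encryption and formal privacy
guarantees are out of scope: the package emulates the message-passing
contract in-process and enforces it at the type level, not at a
transport boundary.
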