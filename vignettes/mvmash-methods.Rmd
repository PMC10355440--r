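---
title: "Methods: multivariate multiple regression with adaptive shrinkage"
author: "mvmash"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multivariate multiple regression with adaptive shrinkage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvmash)
```

## The model

mvmash fits the multivariate multiple regression

$$Y = 1 b_0^\top + X B + E, \qquad E \sim MN_{n \times r}(0, I_n, V),$$

where $Y$ is an $n \times r$ matrix of outcomes measured in $r$ conditions
(for the motivating application: expression of one gene in $r$ tissues), $X$
is an $n \times p$ matrix of predictors (genotype dosages in a gene's
cis-window), $B$ is the $p \times r$ effect matrix, and the matrix-normal
residual has an $r \times r$ covariance $V$ shared across samples.  Outcome
entries may be missing; predictors must be complete.

Each row $b_j$ of $B$ — the effect of predictor $j$ on all $r$ conditions —
receives a mixture-of-multivariate-normals prior

$$b_j \mid w_0, S_0 \sim \sum_{k=1}^K w_{0k}\, N_r(0, S_{0k}).$$

The covariance collection $S_0$ is fixed in advance and chosen to span many
candidate patterns of effect sharing: no effect at all (the null, all-zero
matrix, always listed first), equal effects in every condition, independent
effects, condition-specific effects, partial sharing, and patterns estimated
from the data.  The weights $w_0$ are *estimated* from the data by empirical
Bayes, so the model adapts: in data where effects are shared, weight
concentrates on high-correlation components; in data with no signal, weight
concentrates on the null.

## Variational empirical Bayes

The posterior of $B$ is approximated by a distribution that factorizes over
the rows, $q(B) = \prod_j q_j(b_j)$, chosen to maximize the evidence lower
bound (ELBO) on $\log p(Y \mid X, V, w_0, S_0)$.  Fitting is by coordinate
ascent.  The inner step is a Bayesian multivariate *simple* regression with
a mixture prior, available in closed form: given the expected residuals
$R_j = \tilde Y - 1 b_0^\top - \sum_{l \ne j} x_l \bar b_l^\top$, the
sufficient statistics are

$$\hat b_j = R_j^\top x_j / (x_j^\top x_j), \qquad S_j = V / (x_j^\top x_j),$$

and the updated $q_j$ is a mixture of normals with responsibilities
$w_{1k} \propto w_{0k}\, N(\hat b_j; 0, S_{0k} + S_j)$, component means
$\mu_{1k} = S_{0k} (S_{0k} + S_j)^{-1} \hat b_j$, and component covariances
$S_{1k} = S_{0k} (S_{0k} + S_j)^{-1} S_j$.  Two numerical conventions
matter here:

* singular prior components — including the null — are handled through the
  multiplication form $S_{0k}(S_{0k}+S_j)^{-1}S_j$, never by inverting
  $S_{0k}$, so the null component is exact;
* responsibilities are computed in log space with max-subtraction, because
  component likelihoods can differ by hundreds of log-units for large
  effects; every solved covariance is re-symmetrized as
  $(A + A^\top)/2$ to keep positive-semidefiniteness testable under
  floating-point drift.

Because the component factorizations depend on $x_j$ only through
$x_j^\top x_j$, they are computed once per group of predictors sharing that
value — a single group when `standardize = TRUE` (the default), which is
the main reason a sweep over hundreds of predictors with dozens of
components takes milliseconds.  The sweep itself is implemented in
compiled code (RcppArmadillo); per-iteration cost is linear in $n$ and $p$.

One outer iteration performs, in order: imputation of missing outcomes (see
below), the coordinate sweep over $j = 1,\dots,p$ in ascending order, the
intercept update $b_0 \leftarrow \operatorname{colMeans}(\tilde Y - X\bar B)$,
and the ELBO evaluation; between iterations the empirical Bayes updates

$$w_{0k} \leftarrow \tfrac1p \sum_j w_{1jk}, \qquad
V \leftarrow \tfrac1n\, \mathbb E_q\!\left[(\tilde Y - 1b_0^\top - XB)^\top
(\tilde Y - 1b_0^\top - XB)\right]$$

are applied (each maximizes the ELBO given $q$, so the recorded trace is
non-decreasing; the fitter treats any decrease beyond $10^{-6}$ as an
internal error rather than hiding it).  Any ascent-preserving update order
is valid; this one is frozen and verified by the monotonicity tests rather
than by matching any particular reference trajectory.  The expected
residual sum of squares uses the posterior coefficient variances and, with
missing data, the imputation covariances, so the $V$ update accounts for
all sources of uncertainty the approximation tracks.

The stored $V$ and $w_0$ are the values used in the final sweep, which
makes the returned per-predictor posteriors exactly self-consistent with
`Bbar`; at convergence they differ from the post-sweep updates by less than
the ELBO tolerance.

### Missing outcomes

Missing entries of $Y$ are given their own factor in the variational
approximation.  The update fills, for sample $i$ with observed set $o$ and
missing set $m$,

$$y_{im} \leftarrow \mu_m + V_{mo} V_{oo}^{-1} (y_{io} - \mu_o),
\qquad \mu = b_0 + \bar B^\top x_i,$$

and records the conditional covariance $V_{mm} - V_{mo}V_{oo}^{-1}V_{om}$,
which feeds the $V$ update and the ELBO (through the expected residuals and
the entropy of the imputation factor).  Samples sharing a missingness
pattern share one matrix factorization per iteration.  A sample with no
observed outcomes would receive the prior-predictive mean and full $V$;
the data container refuses such rows for fitting, since they carry no
information.

### Initialization, convergence, degenerate inputs

* Coefficients start at zero unless an external estimate is supplied;
  weights start uniform; $V$ starts at the (pairwise-complete) empirical
  covariance of $Y$, eigenvalue-clipped to be positive definite.
* Convergence requires the ELBO change to fall below `tol` (default 0.01,
  the method's conventional tolerance) *and* the maximum absolute
  coefficient change to fall below `coef_tol` (default $10^{-6}$), a guard
  against stopping on a transiently flat ELBO.  `max_iter` defaults
  to 5000.
* Components whose estimated weight falls below `w0_threshold`
  ($10^{-8}$) are frozen at zero but kept in the output so component labels
  remain stable.
* Constant predictor columns make the single-variable statistics undefined;
  they are flagged by the data container and rejected with an explicit
  error rather than silently dropped.
* The fit is deterministic given the data and options: there is no internal
  randomness.

## The prior covariance collection

`canonical_covariances()` supplies the pre-specified patterns: identity
("independent"), all-ones ("equal"), one singleton per condition
("condition-specific"), and constant-correlation matrices with
$\rho \in \{0.25, 0.5, 0.75\}$ ("shared with heterogeneity").

`data_driven_covariances()` estimates patterns from the data in the spirit
of multivariate adaptive shrinkage: per-predictor, per-condition
simple-regression effects and z-scores on the observed entries; the
`n_strong` predictors with the largest max-|z| (default
$\min(p, \max(2r, 100))$); the empirical second-moment matrix of their
effect rows plus rank-1 outer products of the top `n_pcs` principal axes
(default $\min(3, r)$), each normalized to unit maximum diagonal.  This
construction needs genuinely strong signals: when the signal is weak and
diffuse the strong set is dominated by null predictors and the raw
covariance is noisy — the model compensates, because the estimated weights
(not the raw matrices) decide what the prior favors.

`expand_with_scale_grid()` crosses the bases with the scale grid
(default $\{0.01, 0.025, 0.05, 0.1, 0.2, 0.4, 0.8, 1.6\}$, relative to
unit outcome variance — a geometric-style grid spanning tiny to large
effects), deduplicates, and prepends the null.  The default end-user recipe
is data-driven only, which is competitive across sharing scenarios and
cheapest; `covariance_recipe(kind = "both")` adds the canonical set.

One property of the grid worth knowing: a component whose scale is far
below the sampling variance of the single-predictor estimates
($\approx \operatorname{tr}(V)/n$ per coordinate after standardization) is
likelihood-flat against the null, so the estimated weight split between it
and the null is arbitrary — predictions are unaffected, but "weight on the
null" is then ill-defined.  Analyses that interpret the estimated weights
(as the pattern-recovery tests do) should restrict the grid to scales
resolvable at the available sample size; the defaults keep the tiny scales
because they never hurt prediction.

## The simulator

`simulate_scenario()` generates datasets whose statistical structure
mirrors the standard multi-tissue effect-sharing benchmarks.  Predictors
are unlinked biallelic dosages, Binomial(2, MAF) with MAF uniform on
[0.05, 0.5] — genotype-like margins with no linkage disequilibrium, which
is the main feature of real cis-windows the default simulator does *not*
emulate (correlated predictors mainly affect which of several equivalent
predictors carries the weight, not prediction accuracy).  Five scenarios
control sharing: equal effects (A), independent effects (B), effects in
condition 1 only (C), equal effects in conditions 1–3 and none elsewhere
(D), and a two-subgroup mixture (E) in which each causal variant affects
either conditions 1–3 (explaining 20% of variance) or conditions 4–10
(explaining 5%), with within-subgroup correlation 0.8 — a value chosen to
sit between "equal" (1) and "independent" (0) as a stand-in for "shared
but unequal".  In scenario E the fair-coin subgroup assignment is re-drawn
until both subgroups are represented, since an empty subgroup would make
its variance target unattainable.

Effect columns are rescaled on the training genotypes so causal variants
explain exactly the target fraction (default 20%, low-signal branch 5%) of
each affected condition's variance, with residual variance set so total
variance is 1 — hence a standardized RMSE of 1 is exactly the no-signal
benchmark.  Residuals are independent across conditions by default
(`resid_cor` adds exchangeable correlation).  Defaults are $n = 600$
(split 80/20 into training and test, echoing the 838 = 670 + 168 design of
the motivating data), $p = 200$, $r = 10$, 5 causal variants, and
missingness (default 0) applied completely at random with a guard that no
sample loses all its outcomes.  Everything is a deterministic function of
the spec's seed.

What passing tests on these data do and do not show: they demonstrate that
the method recovers sharing patterns, gains accuracy from joint modeling,
and gains further from integrated imputation *under correctly specified,
unlinked, homoscedastic simulations*; they do not speak to linkage
disequilibrium, confounding, or heavy-tailed expression noise in real
data.

## Evaluation

`standardized_rmse()` divides the RMSE by the standard deviation of the
true test values, computed with the sample ($n-1$) divisor — the divisor
convention is documented because it makes the constant-mean predictor
score $\sqrt{(n-1)/n}$ rather than exactly 1.  Multi-fold evaluations are
summarized as the mean of per-fold standardized RMSEs.  `relative_rmse()`
is the signed fractional difference versus a reference method.
`report_top_pattern()` rescales the highest-weight non-null prior
component to a correlation matrix, flagging zero-variance conditions as
undefined instead of propagating NaNs.

## Problem sizes used by the tests

The test suite exercises the full design sizes where the claims depend on
them (prediction-benefit and imputation-benefit checks: $n = 600$,
$p = 200$, $r = 10$, 20 and 10 replicates) and smaller instances
($n \le 400$, $p \le 60$) for the pattern-recovery and property checks,
where the relevant behavior is already fully expressed; oracle comparisons
use tiny instances ($n = 20$, $p = 2$, $r \le 2$) where dense quadrature
is exact.  The simulator calibration script uses 20 replicates with
10,000-sample test draws.

## Known limitations

* The factorized posterior understates posterior dependence, so interval
  estimates are not provided; the method is aimed at prediction.  Among
  highly correlated predictors it will concentrate weight on one more or
  less arbitrarily (this does not harm prediction).
* The per-sweep cost grows with $K r^2$–$K r^3$; for many dozens of
  conditions the diagonal-$V$ option and a pruned grid are advisable.
* Empirical Bayes weight estimation treats predictors as exchangeable; it
  can be overconfident when $p$ is small.
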