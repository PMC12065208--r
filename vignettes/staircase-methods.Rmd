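---
title: "Methods: staircase designs, REML fitting and the simulation engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staircase designs, REML fitting and the simulation engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(staircasesim)
```

## The design and the model

A *basic staircase* design is an incomplete stepped wedge: each of $S$
treatment sequences is measured in exactly two consecutive periods, one
under control and the next under intervention. Sequence $s$ occupies global
periods $s$ and $s+1$, so the trial spans $S+1$ periods, and with $K$
clusters per sequence and $m$ participants per cluster-period the trial has
$SK$ clusters and $2SKm$ observations. Participants are different in every
period (a repeated cross-section), so there is no participant-level random
effect.

```{r}
staircase_design(S = 4, K = 1, m = 10)
```

The outcome model for participant $i$ of cluster $k$ in sequence $s$ at
period $t \in \{s, s+1\}$ is the linear mixed model

$$Y_{skti} = \beta_t + \theta X_{st} + CP_{skt} + \varepsilon_{skti},$$

with fixed period effects $\beta_t$, treatment indicator $X_{st} =
\mathbb{1}(t = s+1)$, treatment effect $\theta$, cluster-period random
effects $(CP_{sks}, CP_{sk,s+1})^\top \sim N_2(0, \tau^2 R)$ with
$R_{12} = r$, and residuals $\varepsilon_{skti} \sim N(0,
\sigma_\varepsilon^2)$. The within-period intracluster correlation is
$\rho = \tau^2 / (\tau^2 + \sigma_\varepsilon^2)$ (ICC) and $r$ is the
cluster autocorrelation (CAC): the correlation between two participants of
the same cluster in *different* periods is $\rho r$. $r = 1$ collapses the
block-exchangeable structure to the exchangeable one. Period effects can be
parameterised categorically (one effect per period) or linearly
($\beta_1 + t\beta_2$); the categorical model strictly nests the linear
one.

## Closed-form variance and power

Writing $a = (1 + (m-1)\rho)/m$ for the variance of a cluster-period mean
and $\psi = m\rho r / (1 + (m-1)\rho)$ for the correlation between the two
cell means of a cluster, the GLS treatment-effect estimator has variance

$$\mathrm{var}(\hat\theta)_{cat} = \frac{2a(1-\psi)^2}
  {K\left[S(1-\psi) - \sqrt{1-\psi^2}\,
  \frac{(1+\sqrt{1-\psi^2})^S - \psi^S}{(1+\sqrt{1-\psi^2})^S + \psi^S}
  \right]}, \qquad
\mathrm{var}(\hat\theta)_{lin} = \frac{2a[(S^2+2) - (S^2-4)\psi]}
  {KS(S^2-1)},$$

and the asymptotic power against an effect of $\theta_d$ outcome-SD units
is $\Phi(\theta_d/\sqrt{\mathrm{var}(\hat\theta)} - z_{1-\alpha/2})$; with a
small-sample correction the normal reference is replaced by a central $t$
with the correction's degrees of freedom.

Numerical choices in `var_theta_categorical()`:

* the inner power ratio is computed as $(1-q^S)/(1+q^S)$ with $q =
  \psi/(1+\sqrt{1-\psi^2}) < 1$, which cannot overflow for any $S$;
* $1-\psi$ is evaluated by its exact rational form
  $(1-\rho+m\rho(1-r))/(1+(m-1)\rho)$, avoiding cancellation as $\psi\to1$;
* the expression is an indeterminate $0/0$ at $\psi = 1$, so for $\psi >
  1-10^{-6}$ the function falls back to the direct GLS computation
  (`gls_variance_oracle()`), which builds the $2\times2$ per-cluster
  covariance $\sigma^2 a \left[\begin{smallmatrix}1 & \psi\\ \psi &
  1\end{smallmatrix}\right]$ of the cell means and inverts
  $X^\top V^{-1} X$ directly. The same oracle is the validation reference
  for both formulas (agreement to $10^{-10}$ relative across the factor
  grid).

```{r}
var_theta_categorical(4, 1, 10, icc = 0.2, cac = 0)   # 2a/(K(S-1)) = 0.56/3
theoretical_power(var_theta_categorical(10, 5, 50, 0.05, 0.8), theta_d = 0.15)
```

## What the generator emulates

`simulate_staircase()` draws data exactly from the model above:
per-cluster bivariate normal cluster-period effects, iid Gaussian residuals,
and a linear-in-time mean $\beta_t = t$ (consistent with both analysis-time
parameterisations). The total variance is fixed at
$\sigma^2_{total} = \tau^2 + \sigma^2_\varepsilon = 1$, so $\tau^2 = \rho$
and the treatment effect is a standardised effect size; no other scale is
identified by the study design, and power comparisons require this
normalisation. Cells are balanced (constant $m$) in generated data; the CSV
reader tolerates unbalanced cells so that external staircase extracts can
be fitted.

The generator does **not** emulate features of real trials such as
participant-level covariates, non-Gaussian outcomes, missing data,
recruitment drift within periods, or correlation decay over more than two
periods. Passing simulation checks therefore demonstrates correctness of
the estimation machinery under the stated model, not robustness to those
departures.

Reproducibility: every scenario and replicate receives a seed derived from
the master seed by a small modular hash (`derive_seed()`); all intermediate
products stay exact in double precision and below $2^{31}$. Identical seeds
reproduce datasets bit for bit.

## REML on balanced-design sufficient statistics

Because the fixed effects are constant within a cluster-period cell and the
random structure acts at cell level, the data collapse losslessly to the
cell means $\bar Y_{skt}$ plus the pooled within-cell sum of squares $SS_w$
with $df_w = \sum (m_{cell}-1)$. In the two-component parameterisation
$g_1 = \tau^2 r$ (cluster variance) and $g_2 = \tau^2(1-r)$ (cluster-period
variance), the cell-mean covariance of a cluster is

$$\Sigma = \begin{pmatrix} g_1+g_2+\sigma_\varepsilon^2/m_1 & g_1\\
  g_1 & g_1+g_2+\sigma_\varepsilon^2/m_2\end{pmatrix},$$

and the restricted log-likelihood equals (up to a parameter-free constant)

$$-\tfrac12\Big[df_w\log\sigma^2_\varepsilon + SS_w/\sigma^2_\varepsilon
 + \textstyle\sum_c \log|\Sigma_c| + (\bar y - X\hat\beta)^\top V^{-1}
 (\bar y - X\hat\beta) + \log|X^\top V^{-1}X|\Big].$$

This identity is verified in the test suite against a dense individual-level
REML evaluation, both pointwise (constant offset across parameter values)
and at the optimum (estimates agree to $10^{-6}$). Heterogeneous cell sizes
only change the diagonal of $\Sigma$, so unbalanced external data are
handled exactly by the same collapsed likelihood rather than by a separate
dense path; the dense likelihood is retained as a validation oracle.

Optimisation is bounded quasi-Newton (`L-BFGS-B`) over
$(\log\sigma^2_\varepsilon, g_1, g_2)$ with $g_1, g_2 \ge 0$ (the
exchangeable model pins $g_2 = 0$), from three starting points: a moment
estimator (within-cell variance plus the OLS cell-mean residual excess,
split 75/25 between the components), a near-zero-component start, and an
equal split. The best criterion value wins; multi-start matters because
small-$K$ likelihoods are boundary-prone. Convergence uses a criterion
tolerance of order $10^{-9}$ (`factr = 1e6`); boundary solutions are
legitimate optima, retained, and flagged rather than raised.

**Singularity.** A fit is *singular* when a variance component is estimated
at zero, detected with tolerance $10^{-8}$ on the unit-total-variance scale
(numerically equivalent to lme4's `isSingular()` convention, with which it
agrees essentially always in side-by-side checks). For the exchangeable
model the flag is $\hat g_1 = 0$. For the block-exchangeable model the
package computes both an *any-boundary* flag ($\hat g_1 = 0$ or $\hat g_2 =
0$; note $\hat g_2 = 0$ is the same event as $\hat r = 1$) and a *strict*
flag (both zero). The any-boundary flag is the headline one: it is the
convention under which singularity is near-certain when the generating CAC
is 1, which matches how the reference rates behave; the strict definition is
also reported because the two conventions genuinely differ and the choice
is surfaced rather than hidden. With $m = 1$ cells the residual and
cluster-period variances are confounded; the fit collapses $g_2$ into the
residual with a warning instead of failing.

## Small-sample corrections

Both corrections act on the Wald statistic for $\theta$ and are computed in
the natural interior coordinates $(\sigma^2_\varepsilon, g_1, g_2)$, in
which the covariance matrix is affine, so its derivatives are exact.
Components at the zero boundary are excluded and the information matrix is
restricted to the interior coordinates, which keeps the corrections finite
on singular fits (which the engine retains).

**Satterthwaite** (observed information): $df = 2v^2/(\nabla v^\top A\,
\nabla v)$, where $v(\gamma)$ is the treatment entry of $(X^\top
V(\gamma)^{-1}X)^{-1}$, $\nabla v$ its finite-difference gradient at the
REML estimate (central differences, step $10^{-5}(1+|\gamma|)$, capped at
half the distance to the boundary), and $A$ the inverse observed
information (finite-difference Hessian of the restricted log-likelihood). A
non-positive-definite Hessian falls back to the inverse of its positive
part, flagged. The standard error is unchanged; CI and p-value use
$t_{df}$. Side-by-side checks against `lmerTest` agree to well under 1%.

**Kenward-Roger** (expected information, first-order 1997 procedure): the
fixed-effects covariance is inflated by the Kackar-Harville plus
second-order terms built from $V^{-1}$, its derivatives, and the inverse
expected information (whose residual-variance entry picks up the within-cell
contribution $df_w/2\sigma^4_\varepsilon$); since $V$ is linear in the
parameters the second-derivative term vanishes. The matched degrees of
freedom for the scalar test use the standard first-two-moment construction
(for a rank-1 contrast the two trace sums coincide). The adjusted SE is
clamped below at the unadjusted SE, and the df is floored at $10^{-2}$
(flagged) in the rare degenerate cases where the moment-matching equation
has no positive root — the same weakly identified overparameterised
small-cluster regime in which this correction is known to produce df far
below 1 and astronomically wide intervals, behaviour the package reproduces
rather than masks.

The corrections are applied only when the trial has at most 50 clusters
(`apply_correction_policy()`); larger trials use normal-based Wald
inference, mirroring the simulation design this package implements.

## The simulation engine

`run_scenario()` follows the ADEMP pattern: for each replicate it
simulates a dataset, computes the sufficient statistics once, fits each
requested analysis model (structure $\times$ time $\times$ correction,
policy applied), and records $\hat\theta$, SE, df, CI, p and the flags; a
replicate whose fit fails is recorded as non-converged, never propagated.
Performance measures with Monte Carlo standard errors:

* bias $= \overline{\hat\theta} - \theta$, MCSE $= sd(\hat\theta)/\sqrt n$;
* rejection rate $= \#\{p < \alpha\}/n$ (Type I error at $\theta = 0$,
  empirical power otherwise), MCSE $= \sqrt{\hat p(1-\hat p)/n}$;
* 95% CI coverage of the true $\theta$, same binomial MCSE form;
* singularity (both conventions) and non-convergence rates.

All fits, including singular ones, are retained in every measure. At
$\theta = 0$ coverage and rejection are complementary replicate by
replicate for the symmetric Wald intervals, which the tests assert exactly.
Each scenario row also carries the closed-form variance and normal-based
theoretical power for the fitted time parameterisation, so empirical versus
theoretical comparisons need no side computation. `run_grid()` iterates a
`staircase_grid()` — the full factorial of the study's factor levels has
576 configurations — writing a stable-column CSV; per-scenario seeds make
runs deterministic and resumable. `classify_fit()` labels each analysis
correct, overparameterised (BE fit to CAC$=1$ truth) or misspecified
(exchangeable fit to CAC$<1$ truth).

Default $\alpha = 0.05$ two-sided throughout. Nested-loop-plot rendering of
grid results is out of scope; the summary tables are the product.

## Problem sizes and what the checks show

The full factorial at 1,000 replicates (576,000 datasets, four analysis
models each) is a cluster-scale computation. The package's own verification
runs use targeted scenarios at 200–1,000 replicates with all stochastic
comparisons tolerated at $\pm3$ MCSE; at 1,000 replicates the MCSE of a 5%
rate is 0.0069. These sizes give tight checks of the properties of interest
— nominal Type I error under correct specification at 50 clusters, the
reported maximal singularity rates, power-theory alignment at $\ge 40$
clusters, Type I inflation and coverage loss under a misspecified
exchangeable fit, and parameter recovery at scale — without re-running the
entire grid. Theoretical power comparisons use the normal-based formula;
the t-based variant is available via the `df` argument but no specific df
convention is assumed for the reference value.

## Known limitations

* Only the basic staircase layout (one control, one intervention period per
  sequence); no general incomplete stepped wedges, cohorts, or more than
  two measured periods per cluster.
* Continuous Gaussian outcomes only; no GEE, sandwich/robust variances, ML
  (unrestricted) estimation, or Bartlett-type corrections.
* The Satterthwaite implementation uses the observed information and the
  Kenward-Roger implementation the expected information; the transposed
  variants are deliberately not offered.
* Sample-size inversion (solving for $K$ or $m$ at target power) is not
  provided; sweep `theoretical_power()` over candidate designs instead.
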