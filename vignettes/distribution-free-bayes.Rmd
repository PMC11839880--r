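---
title: "Distribution-free Bayesian inference: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distribution-free Bayesian inference: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfbayes)
```

## The common model: Bernoulli reductions with beta priors

Every analysis in **dfbayes** reduces its data to Bernoulli-type
information and places a beta prior on the corresponding population
proportion. A beta density with shapes $a, b > 0$ is conjugate to
Bernoulli sampling: observing $n_1$ category-1 and $n_2$ category-2
outcomes turns a $\mathrm{Beta}(a_0, b_0)$ prior into a
$\mathrm{Beta}(a_0 + n_1,\, b_0 + n_2)$ posterior — the binomial
coefficient cancels in Bayes' rule, so only the counts matter. The
default prior everywhere is the uniform $\mathrm{Beta}(1, 1)$ (maximum
entropy for a proportion); users who prefer the Jeffreys prior simply
pass $a_0 = b_0 = 0.5$, and informative priors encode earlier studies as
pseudo-counts.

The reductions are:

* **binomial** — the two category counts themselves;
* **McNemar** — only the off-diagonal switch counts $(n_{01}, n_{10})$
  of a paired binary design are informative about the switching rate
  $\phi_{rb}$, oriented so that $\phi_{rb} > .5$ means net improvement;
* **sign test** — signs of the paired differences, zeros dropped (exact
  comparison; callers on noisy floating-point scales should round
  first);
* **median test** — counts of observations strictly above the pooled
  median per group. With unequal groups the no-effect reference is not
  $.5$ but the base rate $n_E/(n_E + n_C)$, and the Bayes factor uses
  the prior mass at that base rate rather than assuming even odds;
* **concordance / gamma** — concordant vs discordant pair counts (below).

Hypotheses about a proportion are tested two ways. An *interval* null
$[L, U]$ has well-defined prior and posterior masses (regularized
incomplete beta), and $BF_{10}$ is the posterior odds of the alternative
over its prior odds; when a mass underflows to zero the Bayes factor is
reported as `Inf`, never as a large sentinel. A *point* null has zero
mass under a continuous prior, so the package uses the Savage–Dickey
density ratio $BF_{01} = f_{\text{post}}(\phi_0) / f_{\text{prior}}(\phi_0)$ —
the standard device for a nested point null; no closed form is claimed
beyond that choice, and it is flagged in the documentation.

### Interval estimates

`betaDescriptive()` reports the exact mean, variance, median
(`qbeta(.5, a, b)`), mode (interior only), an equal-tail interval, and a
highest-density interval. The HDI minimizes
$Q(\alpha + p) - Q(\alpha)$ over the lower-tail mass $\alpha$ with
`optimize()` (tolerance $10^{-10}$ on $\alpha$); the width is unimodal
in $\alpha$ when both shapes exceed 1. When exactly one shape is at most
1 the density is monotone and the HDI is the one-sided interval anchored
at the peaked boundary; when both shapes are at most 1 the density is
U-shaped (or flat) and the HDI is reported as undefined rather than
guessing a side.

## Contrasts of K binomial rates

For $K$ independent conditions with weights $\psi_i$ (summing to zero,
positive part $+1$, negative part $-1$), the contrast
$\Delta = \sum_i \psi_i \phi_i$ has closed-form posterior mean and
variance, but not a closed distribution. `betaContrast()` samples each
posterior beta, forms $\Delta_j$ per draw, and estimates $P(\Delta > 0)$,
equal-tail quantiles (type-7 interpolation, deterministic given the
sample), and $BF_{10}$ for $\Delta > 0$. The prior odds are estimated by
the same Monte Carlo scheme applied to the prior betas — with non-uniform
priors the prior $P(\Delta > 0)$ is not $\tfrac12$. Because the result is
simulation-based, the binomial standard error of $P(\Delta > 0)$ is
reported so users can judge seed-to-seed variation; results are
bit-for-bit reproducible given `(seed, samples)`.

## Rank-statistic posteriors

### Wilcoxon sign-bias parameter $\phi_w$

Paired data reduce to $T^+$ and $T^-$, the rank sums of the absolute
differences by sign (midranks for tied $|d|$, zero differences dropped).
The population parameter $\phi_w$ is the sign-bias probability filtered
through the signed-rank statistic. For $n \le 24$ blocks the posterior is
a discrete distribution over 200 candidate values
$\phi_i = .0025 + (i-1)\,.005$: at each candidate, `samples` (default
30000) random sign assignments over ranks $1..n$ are drawn with positive
probability $\phi_i$, the share of simulated $T^+$ values equal to the
observed one estimates the likelihood, and multiplying by the prior and
renormalizing gives the grid posterior. Two numerical choices matter:

* the grid prior is the beta density *evaluated* at the grid points and
  renormalized (bin integration would differ only at $O(\text{step}^2)$);
* midranks can make the observed $T^+$ non-integer, while the simulated
  statistic has integer support; the observed value is rounded to the
  nearest integer before matching. If heavy ties make the rounded value
  unreachable at every grid point the function stops with advice to use
  the large-sample method rather than returning a vacuous posterior.

Equal-tail quantiles of the grid posterior interpolate the step CDF
linearly between adjacent grid points; $P(\phi_w > .5)$ is the grid mass
above $.5$ (no grid point sits at $.5$).

### Mann–Whitney dominance parameter $\Omega_E$

Two independent groups reduce to $U_E$ and $U_C$, the strict
cross-group win counts; ties count for neither, so $U_E + U_C$ can fall
short of $n_E n_C$. The parameter $\Omega_E$ is the population limit of
$U_E / (U_E + U_C)$ — a distribution-free measure of stochastic
dominance. The small-sample likelihood at candidate $\Omega$ is estimated
by drawing the experimental group from an exponential with rate
$1 - \Omega$ and the control group from one with rate $\Omega$: this pair
has $P(X_C < X_E) = \Omega$ exactly, and since $\Omega_E$ is
distribution-free, *any* generating pair with that dominance value yields
the same likelihood. Matching is on the (rounded) observed $U_E$ alone.

### The large-sample beta approximation

For $n > 24$ (Wilcoxon) or harmonic mean of group sizes above 19
(Mann–Whitney) the discrete algorithm is replaced by an analytic path:
a normal approximation to the sampling distribution of the statistic
given the parameter — mean $\phi\, n(n+1)/2$ and variance
$\phi(1-\phi)\, n(n+1)(2n+1)/6$ for $T^+$; mean $\Omega\, n_E n_C$ for
$U_E$ with the variance calibrated once per $(n_E, n_C)$ by a
10000-draw pilot of the exponential sampler at $\Omega = .5$, scaled by
$\Omega(1-\Omega)/.25$ — is multiplied by the prior on the same 200-point
grid, and a beta distribution is fitted to the grid posterior by moment
matching. All summaries then come from the fitted beta. The boundary is
deliberately conservative: at $n = 20$ the fitted-beta quantiles agree
with the discrete algorithm within $.02$ (a property the test suite
checks), and the two methods give very similar tail probabilities well
below the cutoff. `method = "small"` / `"large"` overrides the automatic
rule. The Mann–Whitney variance calibration is an approximation of this
package's own design; its accuracy is validated behaviorally against the
discrete sampler rather than against any external shape formulas.

### More than two conditions

With $K > 2$ conditions the sharp null "all conditions equal" has zero
probability mass, so the package follows the contrast route instead of
Friedman/Kruskal–Wallis-style omnibus tests: `compositePair()` forms the
weighted positive- and negative-side variates of a within-block contrast
for a paired Wilcoxon analysis, and `poolGroups()` concatenates
independent groups by weight sign for a Mann–Whitney analysis.

## Power simulation

`simData()` draws a control sample from `model(shape1)` and an
experimental sample from `model(shape2)` plus a pure location offset
`delta`, under nine generating models. Parameterizations (auxiliary
parameters fixed): normal `sd = shape`; Weibull `shape`, unit scale;
Cauchy scale, location 0; lognormal `sdlog`, meanlog 0; chi-squared
`df`; logistic scale, location 0; exponential rate; Gumbel scale,
location 0 (inverse-CDF sampler); Pareto minimum 1, tail index `shape`
(inverse-CDF sampler). Block effects are Uniform$(0, \text{blockMax})$:
one draw per block added to both members of a pair (cancelling exactly
in the difference scores, up to float rounding) or an independent draw
per observation in the independent design.

Each replication is analysed twice: the Bayesian rank posterior
appropriate to the design, counted as a detection when
$P(\text{parameter} > .5) \ge$ `effectCrit` (default .95), and a
classical $t$ test (paired, or pooled-variance two-sample) at
$\alpha = 1 - $`effectCrit`. Both criteria are **one-sided**
(experimental greater): the Bayesian criterion is directional by
construction, and a two-sided $t$ would answer a different question at a
different error rate — with the one-sided convention the null detection
rates of both procedures calibrate to $\alpha$ and the published
sample-size benchmarks for matched power are reproduced.

Two design choices keep the drivers fast and honest:

* the power drivers evaluate the Bayesian posterior with the
  beta-approximation algorithm at *every* sample size, including those
  below the automatic small/large boundary. The discrete sampler costs
  200 grid points × 30000 draws per replication; inside
  11 × 1000-replication sweeps it is prohibitive on any hardware, while
  the approximation's detection decisions differ negligibly (the two
  methods' tail probabilities agree to a few thousandths at the
  boundary sizes);
* cells are seeded as `seed + cellIndex`, so tables are reproducible and
  cells mutually independent.

`bayesVsTPower()` sweeps 11 sample sizes ($n_{\min}$ to
$n_{\min} + 50$ by 5); `powerCurve()` sweeps 21 separations (0 to
$20\,\Delta_{\text{step}}$). Defaults: `samples = 1000` replications per
cell, `effectCrit = .95`.

## Rank-based association

`concordanceCounts()` classifies all $N(N-1)/2$ pairs by the sign
product of the coordinate differences; sign comparisons on raw values
equal sign comparisons on ranks, so ranks are never materialized. Tie
totals $T_X$, $T_Y$, $T_{XY}$ (clusters tied on X, on Y, on both) obey
$n_c + n_d = N(N-1)/2 - T_X - T_Y + T_{XY}$, an identity enforced by the
class validity and fuzz-tested. The sample
$\tau_A = (n_c - n_d)/(n_c + n_d)$ handles every tie pattern exactly;
the more common $\tau_B$ denominator is biased when points are tied on
both variates (it is computed only inside a regression test that
documents the bias, never exposed). Each comparable pair is a Bernoulli
trial, so the concordance proportion $\phi_c$ gets the conjugate
posterior $\mathrm{Beta}(a_0 + n_c,\, b_0 + n_d)$, and because
$\tau_A = 2\phi_c - 1$ is monotone, $\tau$ intervals are the transformed
$\phi_c$ quantiles rather than re-estimated.

For goodness-of-fit use, $x$ is the observed measure, $y$ the fitted
model estimate, and each of $m$ free parameters (totalled across fitted
units) is treated as removing one condition from comparison, penalizing
the concordant count to $n_c^* = n_c - Nm + m(m+1)/2$ (the discordant
count is not adjusted). A non-positive $n_c^*$ signals an
over-parameterized model and is an error.

`gammaTable()` evaluates the Goodman–Kruskal quadruple sums $N_s$ and
$N_d$ directly on an ordered contingency table; they provably equal the
concordance counts on the expanded point set (tested against that
expansion), so $G$ is the sample $\tau_A$ in table form. The pair kernel
is the $O(N^2)$ reference implementation; at the table sizes and
$N \le$ a few thousand typical of these analyses it is not a bottleneck.

## What the synthetic-data generator does and does not emulate

The generator produces independent draws from the nine listed models
with a location offset and optional uniform block effects — the
conditions under which the power benchmarks in this package are defined.
It does not emulate serial dependence, heteroscedastic block effects,
censoring, or measurement rounding; passing tests therefore demonstrate
correct behavior under clean location-shift alternatives, not robustness
to those further complications (the rank methods' insensitivity to
monotone transforms suggests graceful behavior, but that is not tested).

## Problem sizes used in the test suite

The package's own checks run the discrete-grid oracles at
$n \le 12$–$20$ with $10^5$ draws per grid point, power calibration at a
few hundred replications per cell, and the qualitative efficiency
comparisons at 250 replications per design point. These sizes give
Monte Carlo standard errors comfortably inside the asserted tolerances
while keeping a full run to a couple of minutes; the two
simulation-heavy headline quantities (the million-draw contrast and the
Cauchy $t$-power sweep) are reproduced at full size in the acceptance
script.

## Known limitations

* The Mann–Whitney large-sample variance calibration is pilot-based;
  extremely unbalanced designs ($n_E \ll n_C$) inherit its Monte Carlo
  error, though the $\Omega(1-\Omega)$ scaling keeps it well-behaved.
* The discrete algorithms match on the rounded observed statistic; with
  massive tie structure the likelihood can degenerate (reported as an
  error, with the beta approximation as the fallback).
* Point-null Bayes factors depend on the Savage–Dickey convention; users
  comparing against interval nulls should prefer the interval method,
  which needs no such convention.
* `simData()`'s t p-values are one-sided by design; they are not
  general-purpose two-sided t tests.

```{r example}
# a compact worked run: paired rank analysis plus its Bayes factor
y1 <- c(77.9, 89.2, 78.2, 50.0, 94.5, 73.1, 77.5, 70.6, 89.4, 77.6)
y2 <- c(77.2, 66.0, 69.2, 58.2, 74.0, 88.3, 77.5, 74.6, 78.4, 72.2)
wilcoxonTest(y1, y2, samples = 5000, seed = 1)
```
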