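---
title: "Comparing two dependent correlations with overlapping variables"
author: "depcorr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing two dependent correlations with overlapping variables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depcorr)
```

## The problem

A recurring question in correlational research is whether two variables
$X_1$ and $X_2$ are *equally* correlated with a shared target variable
$Y$. Typical examples: is a cognitive outcome equally associated with the
right-hand and the left-hand 2D–4D digit ratio? Is an anxiety measure
equally related to two candidate predictors measured on the same people?
Because all three correlations $r_{1Y}$, $r_{2Y}$ and $r_{12}$ come from
one sample and share the variable $Y$, the two correlations of interest
are *dependent with overlapping variables*, and comparing the $p$-values
of the two separate significance-against-zero tests is not a valid answer
— a direct test of $H_0\colon \rho_{1Y} = \rho_{2Y}$ is needed.

`depcorr` implements ten classical tests of this null, the feasibility
constraints that the three correlations must jointly satisfy, generators
of correlated non-normal data, and a Monte Carlo engine for studying the
empirical size (Type I error rate), power and robustness of the tests.

## The ten tests

All tests consume the sample triplet $(r_{1Y}, r_{2Y}, r_{12})$ and the
sample size $n$ (a `cor_triplet`). Throughout, $R$ denotes the
determinant of the $3\times 3$ sample correlation matrix,
$$R = 1 - r_{1Y}^2 - r_{2Y}^2 - r_{12}^2 + 2 r_{1Y} r_{2Y} r_{12},$$
$Z_{iY} = \tfrac12 \log\{(1+r_{iY})/(1-r_{iY})\}$ is Fisher's z, and
$\bar r = (r_{1Y}+r_{2Y})/2$.

Three statistics compare the raw correlations and refer to Student's $t$
with $n-3$ degrees of freedom:

* **Hotelling**: $t_H = (r_{1Y}-r_{2Y})\sqrt{(n-3)(1+r_{12})/(2R)}$. Its
  radicand is positive exactly when the sample correlation matrix is
  positive definite.
* **standard Williams**:
  $t_W = (r_{1Y}-r_{2Y})\sqrt{\dfrac{(n-3)(1+r_{12})}
  {2R + \bar r^2 \frac{n-3}{n-1}(1-r_{12})^3}}$.
  The extra positive denominator term both shrinks the statistic
  ($|t_W| \le |t_H|$) and widens the set of samples where it is defined.
* **Hendrickson–Stanley–Hills**: like Hotelling with
  $(r_{1Y}-r_{2Y})^2(1-r_{12})^3/\{4(n-1)\}$ added to the denominator, so
  $|t_{HSH}| \le |t_H|$ with equality at $r_{1Y} = r_{2Y}$.

Two large-sample statistics also work on the raw scale with a standard
normal reference: **Pearson–Filon** and **Olkin** (in the corrected
form). Although their radicands are printed differently, they are
algebraically identical, so the two tests always agree; both are kept as
separate code paths and the equivalence is pinned by a test.

Four statistics compare the Fisher-z transforms,
$z = (Z_{1Y}-Z_{2Y})\sqrt{(n-3)/(2-2c)}$, with a standard normal
reference and different estimates $c$ of the correlation between the two
z-estimates:

* **Dunn–Clark** uses
  $c_{DC} = \dfrac{r_{12}(1-r_{1Y}^2-r_{2Y}^2) - \tfrac12 r_{1Y} r_{2Y}
  (1-r_{1Y}^2-r_{2Y}^2-r_{12}^2)}{(1-r_{1Y}^2)(1-r_{2Y}^2)}$.
* **Steiger** substitutes the plain mean $\bar r$ for both $r_{1Y}$ and
  $r_{2Y}$ in $c_{DC}$.
* **Hittner–May–Silver (HMS)** substitutes instead the back-transformed
  mean z, $\bar r_z = \tanh\{(Z_{1Y}+Z_{2Y})/2\}$.
* **Meng–Rosenthal–Rubin (MRR)** uses
  $z = (Z_{1Y}-Z_{2Y})\sqrt{(n-3)/\{2(1-r_{12})h\}}$ with
  $h = (1-f\,\overline{r^2})/(1-\overline{r^2})$,
  $f = (1-r_{12})/\{2(1-\overline{r^2})\}$ and
  $\overline{r^2} = (r_{1Y}^2+r_{2Y}^2)/2$. The original prescription
  replaces any $f > 1$ by 1 (`cap_f = TRUE`), which makes the statistic
  computable for every sample; the default here keeps $f$ as computed,
  which leaves the statistic undefined when $f \ge 1/\overline{r^2}$.

Finally, the **Zou** method builds a $100(1-\alpha)\%$ confidence
interval $(L, U)$ for $\rho_{1Y}-\rho_{2Y}$ from the back-transformed
z-interval limits of each correlation combined through the estimated
correlation $c_Z$ between the two estimates, and rejects when $L > 0$ or
$U < 0$.

### Undefined statistics

Every statistic involves a square root whose radicand depends on the
sample correlations and can be non-positive. `depcorr` represents such
cases by `NA` with `applicable = FALSE` — a value, not an error — so that
simulations can count them. A radicand in $(0, 10^{-12}]$ is also treated
as undefined: such samples sit on a measure-zero degeneracy boundary and
the resulting numbers would be numerical noise. In rejection-rate
denominators, undefined samples count as non-rejections out of the full
replication count, and the per-condition `undefined` column makes the
accounting auditable.

A consequence of the printed covariance formulas is worth spelling out.
For Steiger and HMS, $2 - 2c > 0$ reduces to $m^2 < 2/(3-r_{12})$, where
$m$ is the respective mean correlation. Because $\tanh$ of a mean of
$\mathrm{atanh}$s overshoots the plain mean, the HMS statistic has a
slightly *larger* undefined corner region than Steiger, and that region
can intrude into the set of triplets compatible with a trivariate normal
distribution (e.g. $r_{1Y}=.99, r_{2Y}=.3, r_{12}=.35$). Likewise, under
the null with $r_{1Y} \approx r_{2Y}$, $\bar r_z \approx \bar r$, so HMS
and Steiger are nearly the same statistic and share their (good)
calibration. Claims elsewhere that the HMS form is computable for every
triplet on the correlation cube, or that it is grossly liberal at large
common correlations, do not follow from these formulas; the package
implements the formulas as printed in the original sources and its test
suite asserts their actual behaviour.

### Unsigned-strength comparisons

When the research question concerns the *strength* of association
regardless of sign ($H_0\colon |\rho_{1Y}| = |\rho_{2Y}|$ with
opposite-signed sample correlations), negating $X_2$ turns it into the
standard signed null: `flip_for_unsigned()` maps
$(r_{1Y}, r_{2Y}, r_{12})$ to $(r_{1Y}, -r_{2Y}, -r_{12})$. The choice of
which variable to negate flips the sign of the resulting statistic but
not its magnitude or $p$-value; this package negates $X_2$.

## Feasibility of correlation triplets

A non-degenerate trivariate normal distribution with correlations
$(\rho_{12}, \rho_{1Y}, \rho_{2Y})$ exists iff the determinant of the
correlation matrix is strictly positive. Solving for $\rho_{2Y}$ gives
the open interval $\rho_{12}\rho_{1Y} \pm
\sqrt{(1-\rho_{12}^2)(1-\rho_{1Y}^2)}$ (`rho2y_bounds()`), and on the
null diagonal $\rho_{1Y}=\rho_{2Y}=\rho$ the condition reduces to
$|\rho| < \sqrt{(1+\rho_{12})/2}$ (`diagonal_range()`): strongly negative
$\rho_{12}$ leaves room only for small common correlations. Simulation
designs are confined to this region; `build_power_lattice()` additionally
constructs the alternatives grid by stepping symmetrically off the
identity line, so every lattice point shares its mean correlation with
its diagonal reference. A derivable corollary: the number of feasible
lattice points at spacing $s$ scales with $\sqrt{1-\rho_{12}^2}$, i.e.
it is symmetric in the sign of $\rho_{12}$.

## Data generation

The simulation engine emulates four marginal families, all built from a
latent trivariate normal with the target correlation matrix (sampled via
its Cholesky root):

* **normal** — the latent variables themselves;
* **beta** (`beta:a,b`; uniform is `beta:1,1`) — inverse-transform
  $X = F^{-1}\{\Phi(Z); a, b\}$, giving exact Beta marginals. The latent
  correlations are used as targets without adjustment: for moderate
  shapes the transform preserves correlations almost exactly, and the
  residual bias is measured by the test suite (within $\pm 0.01$ at the
  shapes used) rather than corrected;
* **lognormal** — $X = \exp(Z)$, with the latent correlations
  pre-adjusted through $\rho_z = \log\{1 + \rho(e-1)\}$
  (`lognormal_base_correlation()`) so that the transformed variables hit
  the targets. Targets at or below $-e^{-1} \approx -0.368$ are
  unattainable and rejected;
* **mixture** (`mixture:v`) — a scale-contaminated normal: with
  probability 0.9 the triplet comes from the standard trivariate normal,
  with probability 0.1 from one with the same correlation matrix and
  common variance $v \in \{2, 4, 10\}$. Contamination applies to whole
  triplets, so the mixture's correlation matrix is exactly the target;
  the marginals are symmetric with kurtosis
  $3(1-p+pv^2)/(1-p+pv)^2$.

`analytic_moments()` returns the closed-form skewness and kurtosis of
each family (e.g. uniform: 0, 1.8; Beta(2,5): 0.596, 2.88;
Lognormal(0,1): $(e+2)\sqrt{e-1} \approx 6.185$,
$e^4+2e^3+3e^2-3 \approx 113.94$; `mixture:10`: 0, $\approx 9.058$), the
values against which the generators' empirical moments are validated.
What these generators do *not* emulate: moment-matched
(polynomial-transform) non-normality, order-constrained variable pairs,
or arbitrary marginal combinations with lognormal members — so passing
tests bound the tests' behaviour only for these specific, well-identified
departure families.

## The Monte Carlo engine

One condition is a population triplet, a sample size, a marginal family
and a replication count. `mc_rejection_rates()` draws all replications at
once, computes the three sample correlations of every replication
vectorized, evaluates each requested test two-sidedly at level $\alpha$
($\alpha/2$ per tail, with separate per-tail counts), and reports
rejection counts, undefined counts, the rate and its binomial standard
error. `type1_sweep()` walks the feasible null diagonal (step 0.02 by
default, keeping a half-step safety margin from the degeneracy boundary
to avoid near-singular matrices), `power_sweep()` walks the alternatives
lattice (step 0.04), and `robustness_sweep()` repeats the null sweep
under non-normal marginals, requiring $X_1$ and $X_2$ to share a marginal
so the null actually holds, and skipping lognormal-infeasible targets.

Reproducibility: every condition's substream seed is derived
deterministically from the master seed and the condition index
(`(seed + 104729 * index) mod (2^31 - 1)`), so results are independent of
evaluation order and any single condition can be re-run in isolation.

### Problem sizes

Defaults are desk-scale, chosen so that full property checks run in
minutes on one core: 20,000 replications for size experiments and 10,000
for power. At 20,000 replications the binomial standard error of an
estimated rate near .05 is about .0015, which comfortably supports
±3-standard-error calibration bands; the `reps` field of `sim_config()`
raises this to cluster-scale (e.g. 500,000) for high-resolution curves.

## Design choices

* **MRR default**: `cap_f = FALSE`. Capping $f$ at 1 alters a
  well-defined statistic whenever $1 < f < 1/\overline{r^2}$ and
  enlarges the non-rejection region for no clear statistical reason; the
  uncapped form is the cleaner default, with the capped original behind a
  flag.
* **Two-sided p-values** are $2\{1 - F(|s|)\}$ under the named reference
  distribution; the Zou method reports no $p$-value, only the interval
  decision.
* **Complete cases only** in `correlations_from_data()`, with the drop
  count reported: the tests assume one common $n$ for all three
  correlations, which pairwise deletion would violate.
* **Boundary snapping**: sample correlations within $10^{-12}$ of
  $\pm 1$ are snapped to the boundary so collinear inputs are flagged as
  inapplicable rather than producing astronomically large but finite
  Fisher-z statistics.
* **Recommended tests**: the command line computes the standard Williams
  test by default and labels Pearson–Filon, Olkin, Hotelling, HSH and HMS
  "not recommended (accuracy)" — under normality their empirical size is
  either systematically off (Hotelling/HSH at negative $\rho_{12}$ unless
  the common correlation is near zero; Pearson–Filon/Olkin mildly
  conservative) or their reference distribution fits poorly, while
  Williams, Dunn–Clark, Steiger, MRR and Zou hold their nominal level
  across the feasible space, as the calibration tests in the suite check
  directly.

## Limitations

The package tests exactly two dependent overlapping correlations: no
omnibus $k > 2$ equality tests, no independent-correlation or
non-overlapping-dependent comparisons, and no rank-based or robust
alternatives. Feasible correlation ranges for arbitrary non-normal
marginals are narrower than the normal-theory ellipse (for some marginal
combinations substantially so); the feasibility tools here describe the
trivariate-normal region only. Monte Carlo robustness results are
specific to the marginal families implemented and do not license
conclusions about other forms of non-normality.
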