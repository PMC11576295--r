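---
title: "Item Pool Visualization for comparing flourishing questionnaires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Item Pool Visualization for comparing flourishing questionnaires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipvkit)
```

## The problem

Flourishing — a high level of hedonic and eudaimonic wellbeing — is measured
by several questionnaires that were developed from different theoretical
traditions: the Mental Health Continuum-Short Form (MHC-SF, 14 items in
emotional/social/psychological wellbeing facets), the 15-item core of the
PERMA-Profiler (positive emotions, engagement, relationships, meaning,
accomplishment), the unidimensional Flourishing Scale (FS, 8 items), and the
Wellbeing Conceptual Framework (WBCF, 10 items in a positive-characteristics /
positive-functioning two-factor split). A practitioner choosing among them
faces the jingle-jangle problem: scales with similar names may measure
different things, and differently named scales may measure the same thing.

Item Pool Visualization (IPV) addresses this with two confirmatory factor
models estimated on the *same* pooled data:

1. a **general factor model** — one factor over all 47 items, representing
   the core of the shared construct, giving each item a standardized loading
   $\lambda_g$;
2. a **correlated factor model** — one factor per sub-pool (facet or
   instrument), factors freely correlated, giving each item a specific
   loading $\lambda_s$.

The **center distance** of an item is the proportional increase in explained
item variance under its specific factor,

$$\mathrm{cd} = \frac{\lambda_s^2 - \lambda_g^2}{\lambda_g^2},$$

so cd = 0 means the item is fully captured by the core and larger cd means
the item carries variance the core does not. A sub-pool is summarized by the
arithmetic **mean** of its item cds and by the pooled **aggregate**

$$\mathrm{acd} = \frac{\sum_i \lambda_{s,i}^2 - \sum_i \lambda_{g,i}^2}
                      {\sum_i \lambda_{g,i}^2},$$

which is exactly the $\lambda_g^2$-weighted mean of the raw item cds (an
identity the tests verify to 1e-12), hence always between the smallest and
largest item cd. The cd and acd formulas are not stated explicitly in the
IPV literature we reproduce; they are fixed here by exact numerical
agreement with the published per-item and pool values for the MHC-SF, PERMA
and FS blocks of the reference loading table bundled with the package
(`reference_loadings()`), e.g. the MHC-SF aggregate 0.104 and PERMA mean
0.039 at three decimals.

```{r cd-example}
# FS item 4 of the reference table: loadings 0.520 -> 0.623
center_distance(0.520, 0.623)[, c("cd_raw", "cd")]
```

Charts make the result legible: an item-level radar map per instrument
(items as rays, radius linear in cd, facet sectors contiguous) and a nested
scale-level map (instrument circles offset from the chart center in
proportion to their aggregate cd, facet markers inside each circle, latent
correlations annotated between circles).

## Two separate fits, not a bifactor model

$\lambda_g$ and $\lambda_s$ come from two *separately* estimated models on
the same sample covariance, mirroring the two-step IPV procedure, not from a
simultaneous bifactor decomposition. A bifactor model would orthogonalize
the specific factors against the general one and change the meaning (and
magnitude) of both loading sets; reproducing the published arithmetic
requires the two-model form, and the package treats it as the reference
behavior throughout.

Because a single factor is only a summary of a correlated-facet reality, a
specific loading can come out marginally *smaller* than the general one;
sampling noise then makes cd slightly negative. The default policy floors
negative cds at zero, flags them (`negative_flag`), and keeps the raw value
in `cd_raw`; `policy = "keep"` preserves negatives. Aggregates always use
the raw loadings. This choice is motivated by the WBCF block of the
reference table, where near-zero values print as 0.000–0.007; note that at
three printed decimals the WBCF rows are not exactly consistent with any
cd recomputation (several rows pair a *decreased* loading with a positive
printed cd), so the per-item regression checks cover the 37 MHC-SF, PERMA
and FS rows and report the WBCF rows without judging them.

A guard refuses cd when $|\lambda_g| \le 0.05$ (the ratio blows up);
the item is named in the error. Factor sign indeterminacy is removed by
reflecting every factor to load positively on its items' unit-weight sum,
so a positive manifold yields all-positive loadings and no spurious cds.

## The CFA engine

`fit_ml()` minimizes the maximum-likelihood discrepancy
$F = \log|\Sigma(\theta)| + \mathrm{tr}(S\Sigma(\theta)^{-1}) - \log|S| - p$
over free loadings (one per item — simple structure), free factor
correlations, and uniquenesses, with factor variances fixed to 1 so the
solution is directly standardized. Numerical choices:

* The model is fitted on the correlation metric. The model family is scale
  invariant, so the discrepancy and all indices are identical to a
  covariance-metric fit (a tested invariant at 1e-6), and standardized
  loadings need no post-processing.
* Uniquenesses are log-parameterized with a floor of 1e-6; a fit ending on
  the floor is a Heywood case and is flagged with a warning, never silently
  accepted.
* Optimization is quasi-Newton (`nlminb`) with an analytic gradient,
  followed by an L-BFGS-B polish whenever the projected gradient norm
  exceeds the convergence tolerance. Initialization is deterministic
  (per-facet principal components for loadings, composite correlations for
  factor correlations); there is no randomness anywhere in fitting.
* The convergence flag requires a projected gradient max-norm below 1e-6
  (default `gtol`). In practice the polish step lands near 1e-8; the looser
  flag threshold avoids declaring non-convergence for well-converged
  solutions whose gradient stalls just above machine-level flatness on
  badly conditioned problems.
* Factor correlations are optimized directly in (-0.999, 0.999); any step
  that makes the implied covariance non-positive-definite receives a large
  penalty value, which the trust-region optimizer backtracks from. With the
  deterministic starting values this is rarely triggered.
* The test statistic is the classic $\chi^2 = (n-1)\,F_{\min}$ (some
  software uses $n$); degrees of freedom are
  $p(p+1)/2 - (2p + k(k-1)/2)$ for a correlated $k$-factor model.

Likert responses are treated as continuous, as is standard in this
literature; polychoric estimation is out of scope.

### Robust (Satorra-Bentler) statistics

`satorra_bentler()` computes the mean-scaling factor
$c = \mathrm{tr}(U\hat\Gamma)/df$ from the sample fourth-order moments
($\hat\Gamma$, the asymptotic covariance of $\mathrm{vech}(S)$) and the
normal-theory residual weight projector
$U = W - W\Delta(\Delta' W \Delta)^{-1}\Delta' W$ with
$W = \tfrac12 D'(\Sigma^{-1}\!\otimes\!\Sigma^{-1})D$. Under multivariate
normality $c \to 1$; excess kurtosis gives $c > 1$ and deflates the scaled
statistic $\chi^2/c$. For a just-identified model the scaling is undefined
and reported as 1 with a flag.

Published "robust" RMSEA/CFI values are produced by at least two different
conventions, and which one a given paper used is usually not stated. The
package therefore always reports both: *scaled* indices (the scaled
statistic pushed through the naive formulas) and *population-corrected
robust* indices (numerators of the form $\chi^2 - c\,df$, with the baseline
scaled by its own $c_b$). Reference fit-index tables are treated as
validation context, not bit-exact targets.

RMSEA confidence intervals invert the noncentral $\chi^2$ CDF in the
noncentrality parameter at the 0.95/0.05 tails (bisection via `uniroot`,
tolerance 1e-10), mapping $\hat\lambda \to \sqrt{\hat\lambda/(df\,(n-1))}$;
the lower bound is 0 whenever the statistic falls below the corresponding
central quantile. The independence baseline has the closed form
$F_b = -\log|R|$.

Cronbach's alpha, composite scoring and Pearson correlation matrices use
sample ($n-1$) variances throughout, matching the conventions of the
reliability literature. Composites are item *means* (not sums): the
published descriptive tables for these instruments print values inside the
response ranges, which identifies the mean convention. Facets that mix
response formats (the WBCF's 5-/4-/11-point items) are z-scored per item
before averaging by default; single-format facets keep their raw metric.

## The synthetic-data generator

Real response data for these four instruments cannot be redistributed, so
every downstream stage is exercised against a seeded generator whose
defaults are the study conditions: 47 items with the reference
correlated-model loadings as facet loadings, $n = 698$, and each
instrument's own response range (0–5, 0–10, 1–7, and the WBCF's mixed
0–4/0–3/0–10).

The data-generating process is a *correlated-facet* common-factor model:
$\Sigma = \Lambda\Phi\Lambda' + \Theta$ with simple structure,
$\Theta = I - \mathrm{diag}(\Lambda\Lambda')$, so $\Sigma$ is a correlation
matrix. A general factor is not modeled explicitly — it emerges from the
uniformly high facet correlations, which is exactly the configuration the
two-model IPV analysis probes, and it lets the reference loading table
serve directly as ground truth. $\Phi$ is built from a two-level latent
structure (facet $=$ $a_f\,G + b\,V_{\text{instrument}} + $ residual, with
$a_f$ spread over 0.92–0.96 and $b = 0.25$), which guarantees positive
definiteness and puts every facet correlation in [0.83, 0.99], the range
reported for these measures, with within-instrument correlations above
between-instrument ones. The population's general-model loadings — needed
for recovery targets — are defined as the single-factor ML solution fitted
to the population $\Sigma$ itself, not invented numbers.

Continuous latent scores are discretized through per-item thresholds on the
standard-normal scale. The default is equal-probability cuts (uniform
category marginals); a `"skewed"` preset concentrates mass on the upper
codes, since real wellbeing items are left-skewed, but no threshold
calibration to the original sample is possible because only means and SDs
of composites were published. Discretized output is emitted in raw
questionnaire coding (the reverse-keyed WBCF item leaves the simulator
flipped), so the validation/recoding step sees data shaped like a real CSV
export. `attenuation_report()` quantifies what discretization costs:
a median split attenuates small correlations by $\approx 2/\pi$, six
uniform categories retain over 85%.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: non-normal latent distributions, response
styles beyond threshold skew (acquiescence, extreme responding), correlated
uniquenesses between similarly worded items, and the idiosyncratic misfit
that makes real CFAs reject. Simulated fit indices are consequently much
better than published ones; only the *arithmetic* of the published indices
(e.g. $\chi^2/df$ ratios) is desk-checkable, and the suite checks exactly
that.

## Problem sizes and runtime

The test suite fits the full 47-item models at $n = 698$ (the study's
sample size) and the parameter-recovery check at $n = 5000$ continuous
observations, where all 47 loadings and 55 facet correlations recover
within $\pm 0.05$. The Satorra-Bentler normality check runs at
$n = 20000$ on the 14-item MHC-SF block — the moment matrices grow with
the fourth power of the item count, and a 14-item model demonstrates the
$c \to 1$ limit as well as the full pool would. Monte Carlo checks of
discretization attenuation use $4\times10^5$ draws per item. A complete
pipeline run (simulate, validate, four instrument CFAs with scaling,
three pooled models, reports, charts) takes a few seconds on one CPU.

## Known limitations

* Only complete data are accepted (the reference design was
  forced-response); there is no missing-data machinery.
* Estimation is normal-theory ML on Pearson covariances; for very coarse
  (binary/ternary) items polychoric-based estimation would be preferable.
* The chart geometry (sector allocation, circle radii, label placement) is
  package-defined plumbing: it echoes the published figures visually but
  carries no accuracy claims beyond the radial ordering, which is tested.
* The mapping from aggregate cd to instrument-circle *radius* is not
  recoverable from the published figures; the radius is a style constant.
* Item-level charts reuse the nested-model loadings for the per-instrument
  views (whether the original figures refitted per instrument is not
  documented; the nested choice keeps every displayed number traceable to
  one pair of fits).
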