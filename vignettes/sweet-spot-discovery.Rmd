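---
title: "Sweet-spot discovery: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sweet-spot discovery: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific idea

Homeostasis keeps physiological variables — glucose, blood pressure, serum
albumin — near optimal operating points. Two consequences are exploitable in
cross-sectional cohort data. First, in *healthier* people, regulated
phenotypes should sit closer to their optima, so their variance should be
*lower* among the healthiest participants than among the least healthy.
Second, if deviation from an optimum in either direction damages health, the
relationship between a phenotype and a health-deficit score should be
V-shaped, with its minimum at the optimum — the *sweet spot*.

`sweetspot` implements the full discovery pipeline built on these two
observations:

1. score overall health with five deficit-accumulation *instruments*;
2. screen phenotypes for variance heterogeneity between the healthiest and
   least-healthy strata (Brown–Forsythe test, Bonferroni control);
3. for phenotypes passing the screen, fit a one-breakpoint segmented
   regression of the age-residualized instrument score on the phenotype,
   test the change in slope, and classify the relationship;
4. invert the score-test power function to plan replication in smaller
   cohorts.

A synthetic-cohort generator with planted ground truth makes every stage
testable without access to restricted cohort data.

# Health instruments

All five instruments live on the unit interval, higher = less healthy:

| Instrument | Definition | Health levels |
|---|---|---|
| I | frailty index: mean of 51 deficits coded in [0, 1] | pooled quartiles |
| II | five major diseases (cancer, cardiovascular, pulmonary, dementia, diabetes): count / 5, with medication/treatment implying confirmed status | 0 diseases = healthiest, ≥ 2 = least healthy, 1 = intermediate |
| III | other chronic conditions (default 28 flags): normalized count | pooled quartiles |
| IV | composite cognitive score: rank-normalized tests averaged within domain, then across domains | pooled quartiles |
| V | physical functioning: flat mean of rank-normalized tests | pooled quartiles |

Choices the definition leaves open, fixed here and recorded in the run
manifest:

* **Rank normalization** maps the value with average rank $r$ among $n$
  non-missing values to $(r - 0.5)/n$. It is invariant under any strictly
  monotone transform of a test, which is what makes composites of
  heterogeneous tests commensurable, and makes the direction-of-risk
  inversion (implemented as negation) immaterial beyond its sign.
* **Quartile cutoffs** use the inclusive linear-interpolation quantile
  (R type 7) on the pooled cohort, all ages and sexes together. Levels are
  half-open: a score exactly at the first cutoff is "good health", not
  "healthiest" — scores strictly below the first quartile are the healthiest
  group.
* **Frailty-index denominator** is the number of non-missing deficits, with
  the index set missing below 80% completeness. Complete-case analysis makes
  this moot downstream, but the behavior on partial records must be defined.
* **Domain compositing** averages observed tests within a domain, and leaves
  the composite missing when an entire domain is unobserved. Whether to
  average before or after handling within-domain missingness is not
  determined by the instrument definitions; this rule is a declared package
  decision.

# The variance screen

For each phenotype × instrument × sex × age stratum (< 55, 55–64, 65–74,
≥ 75 years), the phenotype's variance is compared between the healthiest and
least-healthy groups with the two-group Brown–Forsythe statistic
$$W = (N-2)\,\frac{\sum_j n_j(\bar z_j - \bar z)^2}
                  {\sum_j \sum_i (z_{ij} - \bar z_j)^2},
  \qquad z_{ij} = |x_{ij} - \tilde x_j|,$$
with $\tilde x_j$ the group median, referred to $F(1, N-2)$. Median centering
is the point: deficit counts and many biomarkers are skewed, and the
median-based statistic keeps its size under skew where the mean-based Levene
statistic does not.

Decisions:

* The test is two-sided; the direction requirement ("healthiest group has
  lower variance") is imposed afterwards as a flag, mirroring the two-step
  selection logic.
* Cells where either group has fewer than 30 complete cases are skipped but
  retain their slot in the Bonferroni denominator, which is the *planned*
  product #phenotypes × 5 instruments × 2 sexes × 4 strata. With 231
  phenotypes this is 9240 tests. Keeping the denominator fixed makes the
  correction reproducible and auditable from the run manifest regardless of
  which cells had data.
* Complete cases are defined by the phenotype under test and the instrument
  score (whose own completeness rules encode the deficit components) —
  not by all phenotypes jointly.
* Before the screen, phenotypes with more than 24% missingness are dropped
  (unless explicitly exempted, as one would for sparse but important
  inflammatory biomarkers), and within any pair correlated above |r| = 0.9
  the later-listed phenotype is dropped. The tie-break by input order is
  arbitrary but deterministic and logged.

Calibration is verified by simulation: under equal-variance Gaussian nulls
with unequal groups of a few hundred (the size of real sex × age strata),
the rejection rate at $\alpha = 0.05$ sits inside the binomial 95% band and
the p-values pass a Kolmogorov–Smirnov uniformity check. At much smaller
groups (tens), the F reference for the Brown–Forsythe statistic is known to
be slightly off; the 30-per-group floor keeps the screen out of that regime.

# Segmented regression and classification

For each selected phenotype, per sex and instrument, the instrument score is
first residualized on age by OLS (optionally on lifestyle covariates too),
then the broken-line model
$$y = \beta_0 + \beta_1 x + \delta\,(x - \psi)_+ + \varepsilon$$
is fitted with free breakpoint $\psi$. Fitting is by iterative
linearization: at the current $\psi^{(t)}$ the working covariates
$(x-\psi^{(t)})_+$ and the gap indicator $-\mathbf 1(x > \psi^{(t)})$ are
refit by OLS and $\psi^{(t+1)} = \psi^{(t)} + \hat\gamma/\hat\delta$.
Numerical choices:

* start at the median of $x$, with restarts from the 10th, 30th, 70th and
  90th percentiles; $\psi$ is projected into the 2nd–98th percentile range;
* steps are halved until the exact profile SSE decreases; convergence is
  declared when the gap coefficient falls below $10^{-8}$ *or* the damped
  update stalls at machine scale. The stall rule matters: with noisy data
  the profile-SSE minimizer generically sits exactly at a data point, where
  the gap coefficient jumps across zero and can never shrink below a fixed
  tolerance, so a pure gap-tolerance rule would misreport well-identified
  minima as failures;
* a 501-point quantile grid with exact OLS at each candidate backs up the
  iteration; if the grid beats the iterative solution the iteration is
  restarted from the grid optimum and the best SSE is kept, so the returned
  fit is never worse than the grid and the segmented SSE never exceeds the
  straight-line SSE;
* genuinely non-convergent fits are classified from the straight-line slope
  and counted in the manifest, never dropped.

The slope difference is tested with a pseudo-score test: the mean of the
working covariates $(x - \psi_k)_+$ over ten fixed interior quantiles of
$x$ is added to the straight-line model and its $t$ statistic referred to
$t_{n-3}$, two-sided. Because the evaluation points are fixed under the
null, the test is exact for Gaussian errors and needs no estimable
breakpoint under the alternative. Its calibration and its agreement with
the analytic power function are both verified by simulation in the test
suite.

A relationship is a **sweet spot** only if all three criteria hold:
(1) $\hat\beta_1$ and $\hat\beta_1 + \hat\delta$ have opposite signs;
(2) both slopes' 95% CIs exclude zero; (3) the Bonferroni-adjusted
score-test p-value (denominator: #phenotypes × 2 sexes × 5 instruments,
e.g. 1420 for 142 phenotypes) is below 0.05. Otherwise the fit is
classified increasing/decreasing (same-sign slope CIs excluding zero),
nonmonotonic-nonsignificant (opposite signs, criteria failed), or flat.

Inference for $\psi$ uses the delta method on the gap coefficient,
$\mathrm{se}(\psi) = \mathrm{se}(\hat\gamma)/|\hat\delta|$, conditioning on
the final breakpoint; slope CIs likewise condition on $\hat\psi$ and do not
propagate breakpoint uncertainty. This is a known approximation: in
simulations with a normal covariate and the breakpoint at its center
(matching both the generator and the replication power model), CI coverage
for $\psi$ is ≈ 0.94 at nominal 95%; with a uniform covariate the
breakpoint estimator's heavier finite-sample tails push coverage down to
≈ 0.87–0.90, and alternative intervals (profile-SSE inversion,
gap-test inversion) do no better. Treat the $\psi$ CI as
approximate when the phenotype's distribution is far from Gaussian.

Breakpoints are assumed fixed across age (hence pooling ages after
residualization) but not across sex, so all analyses stratify by sex.
Sensitivity re-runs (e.g. excluding users of a medication class) are
expressed as row filters to `sweet_spot_scan()` rather than bespoke code
paths.

# Power and replication planning

The power of the slope-change test under an alternative with slope
difference $\delta$ at standardized breakpoint $\psi$ uses the same working
covariate as the test itself. With $X$ standard normal, all required
moments of hinge functions $(X - a)_+$ have closed forms via the normal
density and distribution function. After projecting out the intercept and
linear term, the test statistic is asymptotically normal with unit variance
and noncentrality
$$\mathrm{ncp} = \sqrt n\,\frac{|\delta|}{\sigma}\,
  \frac{\langle \tilde U_\psi, \tilde M\rangle}{\lVert \tilde M\rVert},$$
where $\tilde M$ is the projected mean working covariate, giving
$\text{power} = \Phi(-z_{\alpha/2} + \mathrm{ncp}) +
\Phi(-z_{\alpha/2} - \mathrm{ncp})$, which equals $\alpha$ exactly at
$\delta = 0$. Using the test's own covariate (rather than the single hinge
at the true breakpoint) keeps the analytic power and the simulated
rejection rate of `score_test_slope_change()` asymptotically identical;
the test suite checks agreement within ±0.03.

`min_detectable_slope_diff()` root-finds the smallest $\delta$ reaching a
target power; `select_replication_subset()` keeps the phenotypes whose
largest standardized |slope difference| from the primary analysis exceeds
that threshold. Standardization multiplies the per-unit slope difference by
the phenotype's sample sd, recorded per record in the scan output. Under
the published planning assumptions (group sd 0.07, standardized breakpoint
−0.24, $\alpha$ 0.05, power 0.8) the thresholds at group sizes 282 and 95
are ≈ 0.041 and ≈ 0.071 — the quantities `scripts/acceptance.R`
recomputes.

# The synthetic cohort

The generator emulates the structure of a comprehensive aging-cohort
assessment, ages 45–85, with a single latent health-deficit propensity
$$p_i = \mathrm{clamp}\bigl(b_0 - 0.011\,\mathbf 1[\text{male}]
        + 0.0022\,(\text{age}_i - 65) + \varepsilon_i
        + \textstyle\sum_k c_k(x_{ki}) + \text{covariate effects},\;
        0.001, 0.95\bigr)$$
driving independent Bernoulli deficits, disease and chronic-condition flags
(probabilities proportional to $p_i$), and noisy test scores. This minimal
mechanism reproduces the qualitative facts the pipeline relies on:
right-skewed deficit instruments, scores rising monotonically across age
strata, and near-Gaussian rank-composite instruments. With the default
panel the female frailty-index mean is ≈ 0.095 (sd ≈ 0.065) and the male
mean ≈ 0.083, matching published instrument characteristics; $b_0$ was
calibrated once against that target.

Phenotypes are Gaussian draws whose sd is scaled by the latent-health
percentile $w_i$: $\mathrm{sd} = \text{base\_sd}\,(1 + (F - 1)\,
\mathrm{clamp}(3w - 1, 0, 1))$, so the residual-sd ratio between the
least-healthy and healthiest latent *tertiles* equals the spec'd
heteroskedasticity factor $F$ exactly — the factor's operational
definition. Planted relationships enter the propensity as
piecewise-linear contributions $c_k$, so the age-residualized expected
instrument score is exactly piecewise-linear in the phenotype with its
kink at the planted breakpoint. Two subtleties deserve note:

* Hinge contributions are centered *conditionally on latent health*
  ($E[(x-\psi)_+ \mid w] = \mathrm{sd}(w)/\sqrt{2\pi}$ is subtracted).
  With global centering only, every phenotype whose noise scales with $w$
  inherits a U-shaped conditional-mean component from its correlation with
  the V-shaped phenotypes, which would make the registry's "monotone" and
  "null" labels false in the generated data.
* Even so, variance-scaling tied to latent health implies a residual
  U-shaped information channel (conditioning on an extreme phenotype value
  raises the probability of a high-variance, i.e. unhealthy, draw). At the
  default factors this channel's arm slope is about ±0.006 per phenotype-sd;
  the default monotone slopes (±0.012 per sd) are set to dominate it, which
  is why planted monotone phenotypes classify as monotone rather than as
  shallow V-shapes.

The default panel plants six V-shaped phenotypes on realistic clinical
scales (factor 1.8), six monotone (factor 1.4) and six null (factor 1.0),
with missingness 2% completely at random. What the generator does *not*
emulate: informative missingness, sampling weights, longitudinal waves,
discrete/ordinal phenotypes, non-Gaussian phenotype noise, and
between-deficit correlation beyond the shared latent factor. Passing the
planted-truth tests therefore demonstrates internal consistency of the
pipeline, not robustness to every feature of real cohort data.

# Problem sizes used in the test suite

The bundled suites run the calibration checks at the sizes a desk
validation supports: 2000 null replicates for the screen's size, 5000 for
p-value uniformity, 200 seeds × n = 2000 for breakpoint recovery and CI
coverage, 100 random datasets for the grid-oracle equivalence, 3000
simulated datasets for power self-consistency, and a full pipeline run on
one synthetic cohort of 10,000 participants with the default 18-phenotype
panel. The same end-to-end demo is reproducible via `run_pipeline()` with
any fixed seed.

# Known limitations

* Slope and breakpoint CIs condition on $\hat\psi$; coverage is
  approximate (see above) and degrades for strongly non-Gaussian
  phenotypes.
* The screen's direction rule uses the sample variances; with heavy-tailed
  phenotypes the flagged direction can disagree with a robust spread
  measure.
* The pseudo-score test's evaluation points (10 interior quantiles) are a
  convention; other placements give slightly different power. The power
  module uses the same convention, so planning and testing stay coherent.
* Bonferroni control over the planned product is conservative when many
  cells are skipped.
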