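---
title: "Methods: acute heat-stress screening analysis with coralscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acute heat-stress screening analysis with coralscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Coral restoration programmes increasingly screen source colonies for heat
tolerance before propagating them. The standard acute assay (a CBASS-style
tank array) exposes four fragments of each colony to a one-day thermal cycle
at four temperatures — a baseline near the local maximum monthly mean (MMM)
climatology and three elevated holds — and records the dark-acclimated
photochemical yield of photosystem II (Fv/Fm) at the end of the cycle. Heat
stress depresses Fv/Fm, and the temperature at which a colony loses half of
its baseline yield (the ED50) is the assay's tolerance threshold.

`coralscreen` implements the full analysis around that design for a paired
donor/nursery campaign: dose-response fitting, site-standardized thresholds,
retention/recovery statistics across seasons, colony-level reproducibility and
cohort-assignment reliability under subsampled screening effort, and
growth-tolerance trade-offs. A seeded synthetic-campaign generator makes every
stage testable without field data.

## The dose-response model

Fv/Fm against hold temperature $T$ is modelled with a three-parameter
log-logistic curve with zero lower asymptote:

$$ f(T) = \frac{f_{\max}}{1 + \exp\{\,h\,(\ln T - \ln \mathrm{ED50})\,\}} $$

with slope $h$ (`hill`), upper asymptote $f_{\max}$ (`max`, the unstressed
Fv/Fm), and the half-maximum temperature ED50. At $T = \mathrm{ED50}$ the
curve equals $f_{\max}/2$ for any slope. Temperature in °C is used directly
as the dose; all assay temperatures are far from 0 °C so the log transform is
innocuous, and this matches the parameterization used by the dose-response
fitting tools common in this field.

Fits are bounded least squares with the conventional CBASS box:
$h \in [10, 100]$, $f_{\max} \in [0.3, 0.8]$, $\mathrm{ED50} \in [30, \infty)$.
With only four fragments per colony (one per tank — tank replication is
traded for colony replication in this design) the bounds are what keep
colony-level fits biologically interpretable. Solutions pinned at a bound are
flagged (`at_bound`), not rejected: a colony whose unconstrained optimum lies
below 30 °C is reported at 30 °C with the flag set.

### Numerical choices

* **Deterministic multi-start.** `ed50` starts at every observed temperature,
  `hill` at 15/40/80, `fmax` at the largest observed Fv/Fm (clamped into the
  box). Best sum of squares wins; ties break toward the smaller ED50. A final
  polish pass runs the bounded quasi-Newton search at machine-precision
  convergence with the parameters rescaled to comparable magnitudes. Results
  are therefore run-to-run identical — there is no stochastic global
  optimizer to re-seed.
* **Convergence.** The multi-start stage uses a relative SSE tolerance of
  about 1e-12 (`factr = 100`), far below the 0.01 °C precision at which
  thresholds are reported. The polish stage may halt on a resolution code
  rather than a convergence code; the `converged` flag reflects the
  multi-start stage.
* **Degenerate inputs.** Fewer than four points or fewer than three distinct
  temperatures is an error (three parameters would be unidentified), as is an
  all-zero response (no information about $f_{\max}$).
* **Per-colony ED50 uncertainty** is not defined by the field's standard
  workflow (four points, three parameters), so `ed50_uncertainty()` provides
  a case-resampling bootstrap as this package's own choice. Resamples with
  fewer than three distinct temperatures leave the model unidentified and are
  redrawn (up to 50 attempts each) rather than propagated as failures.
* **Population fits vs averaged colony fits.** Whether a "population-level"
  curve should pool fragments or average colony fits is genuinely open; both
  are provided (`fit_ed50s(scope = "population")` pools; summaries of colony
  fits average). Group summaries in the pipeline use colony fits, matching
  how mean ± SEM panels are usually produced.

## Thermal metrics and the retention/recovery tests

Relative thresholds are `ED50 − MMM`, with MMM defaulting to 30.52 °C (the
climatological value used for standardization) while the CBASS baseline
profile uses 30.5 °C; both are configurable and deliberately distinct.
Treatment holds default to baseline + {4, 6, 9} °C, and ED50 models use the
*measured* hold-phase means (e.g. 31/35/37/40 °C) rather than the programmed
setpoints; `hold_phase_mean()` averages logger samples over the half-open
window [ramp end, hold end) so boundary minutes are never double-counted.

Paired comparisons (nursery vs donor within a season; a condition's first vs
second season) are restricted to complete pairs of genets. A Shapiro-Wilk
test on the *paired differences* (the quantity the test acts on; applying it
to the raw groups would answer a different question) gates at α = 0.05
between a two-tailed paired t-test and a Wilcoxon signed-rank test.
Site-by-condition contrasts within a season use the Tukey-Kramer studentized
range procedure, which handles the unequal group sizes that colony loss
produces.

The species-level condition effect is also estimated from fragment-level
Fv/Fm with a linear mixed model — temperature (categorical: the four measured
levels) and condition as fixed effects, random intercepts for site and
season, one species at a time. Two environment-driven implementation choices:
backward elimination uses likelihood-ratio tests on ML refits, and the
condition t-statistic's degrees of freedom use a containment-style
approximation (observations − fixed-effect rank − random-intercept levels)
rather than a Satterthwaite approximation, whose standard implementation is
not available here. With hundreds of fragments the df is large and the
t-statistic effectively normal, so the approximation is immaterial at this
design's size. When the random-intercept variances collapse to zero the
model downgrades to ordinary least squares with a `singular` flag — in that
limit the two estimators coincide exactly, which the tests exploit.

## Screening reliability

`ed50_reproducibility()` flags colonies whose two ED50 determinations agree
to within 1 °C. The published convention is written "< ±1 °C"; strict
inequality is used (a difference of exactly 1.0 °C does not count) and the
threshold and strictness are configurable.

`cohort_misassignment()` counts, for the top-k and bottom-k cohorts of two
rankings, how many colonies of one cohort are missing from its counterpart,
and reports the *average* of the two counts. An average (0–5 scale at k = 5)
rather than a sum is used because reported misassignment magnitudes ("about
one colony misassigned at screening sizes of 15 or more") sit on that scale.
Ties in ED50 are broken by colony id so rankings are deterministic.

`screening_curve()` subsamples s colonies without replacement, re-ranks both
ED50 columns within the subsample, and averages misassignment over (by
default) 1000 seeded iterations for every s from 2k to n, reporting a
Monte-Carlo standard error so precision is explicit. Two closed-form nulls
anchor the tests: perfect concordance gives identically zero, and independent
rankings give expectation $k - k^2/s$ (hypergeometric overlap). Note that a
single realized table has its own conditional mean; the package's tests
average over freshly drawn tables so the Monte-Carlo error covers all the
randomness.

## Growth

Fragment size is the geometric mean radius, the cube root of the product of
the three *semi*-axes ($((L/2)(W/2)(H/2))^{1/3}$) — "radius" in the classical
usage; full axes are available via `semi_axes = FALSE`, and the factor of two
cancels from any growth *rate*. The specific growth rate is
$(\ln G_1 - \ln G_0) \cdot 100 / t$ in % per day. Trade-offs are tested with
the Pearson product-moment correlation between SGR and ED50 (the statistic
reported as "Pearson (r)" in this literature, despite occasional "rank
correlation" phrasing; the correlation is identical for absolute and relative
ED50 because the MMM shift is constant). Growth-group contrasts use
Tukey-Kramer with a compact letter display built by insert-absorb, so sharing
a letter is exactly equivalent to a non-significant pair.

## The synthetic campaign: what it states and what it does not

The generator's defaults state a two-species, two-site, two-season paired
campaign:

* **Design**: 14 + 13 colonies for the deficit species, 12 + 12 for the
  retention species; every colony paired across conditions (donor genet ↔
  nursery propagule); one fragment per colony per tank; measured holds
  31/35/37/40 °C; Fv/Fm noise SD 0.05.
* **Group means** are the published values (relative threshold + MMM), e.g.
  deficit-species nursery means of 35.54/36.18 °C at the first season
  against donor means of 38.22/37.79 °C. Per the transient-deficit model,
  nursery means *rejoin the donor means at the second season*: the stated
  world has a true second-season difference of zero, and observed
  second-season gaps are sampling noise. The retention species' donor and
  second-season means are not published; the retention world sets all its
  group means to its published first-season values (an assumption, not data).
* **Colony-level spread**: latent ED50 SD of 1.9 °C and donor-nursery
  correlation 0.25. Neither is published directly; both are implied — the SD
  by a donor group SEM of 0.52 °C at n = 14, the correlation by the published
  paired-test p-values, which imply paired-difference SDs near 2.3 °C
  ($\sigma\sqrt{2(1-\rho)} \approx 2.3$). Colony z-scores are shared across
  seasons (a genet effect), so season-to-season ED50 scatter in the synthetic
  world comes from measurement noise through the four-point fits, not from
  latent drift — real campaigns likely contain additional temporal biology,
  which is one reason synthetic reproducibility fractions need not match
  field values.
* **Curve constants**: `fmax` uniform on [0.50, 0.65] and `hill` uniform on
  [25, 60] per colony, constant across conditions and seasons — tolerance
  differences are carried by ED50, not by curve shape. Simulated Fv/Fm is
  clipped to [0, 1] (physical bounds of a quantum-yield ratio; at noise SD
  0.05 clipping is negligible) rather than resampled.
* **Growth**: group mean SGRs at the published values (0.07–0.28 %/day),
  SGR SD 0.08 %/day and initial-size SDs of 0.65/0.80 cm chosen to match the
  published SGR ranges and size SEMs; initial GMR means 2.77/3.39 cm; the
  SGR-ED50 correlation is induced on the standardized latent nursery ED50,
  giving exact control at ±1 and the usual $O(1/\sqrt{n})$ sampling spread
  otherwise. The default trade-off is zero: the stated world has no
  growth-tolerance trade-off.

A green end-to-end test therefore establishes that the *pipeline* recovers
the stated pattern — a significant site-pooled nursery deficit at the first
season and none at the second for the deficit species, no differences for the
retention species — from data with realistic noise. It does not establish
anything about field reproducibility percentages or the exact published SEMs,
which depend on the deposited colony-level data; those quantities are covered
by property-based tests of the estimators instead. Per-site paired tests at
the published effect sizes hover near the detection boundary (exactly as the
published p-values 0.0006–0.057 suggest), which is why the headline is
defined on the site-pooled species-level test.

All randomness flows from one root seed through per-stage derived streams, so
`run_pipeline()` reruns are byte-identical.

## Known limitations

* Four points and three parameters leave colony fits sensitive to single
  outlying fragments; steep true slopes (hill ≳ 70) are recovered with
  absolute error up to ~1e-3 even noise-free, limited by double-precision
  flatness of the SSE surface.
* The mixed model's df approximation is containment-style, adequate at
  hundreds of observations but not for small designs.
* The generator does not simulate tank micro-environments, light, flow, or
  fragment mortality, and colony-level ED50 variance within groups is an
  assumption (only group SEMs are published).
* No multiple-testing correction is applied beyond Tukey's procedure,
  matching the source workflow.
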