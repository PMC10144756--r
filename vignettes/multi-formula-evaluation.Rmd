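---
title: "Evaluating no-history IOL power formulas after myopic laser refractive surgery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating no-history IOL power formulas after myopic laser refractive surgery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(postiol)
library(dplyr)
```

## The problem

Myopic laser refractive surgery (LASIK, PRK, LASEK) flattens the central
cornea. Standard keratometry afterwards overestimates corneal power — devices
extrapolate the centre from paracentral readings, and the keratometric index
no longer holds — so when such an eye later needs cataract surgery, standard
IOL power formulas underestimate the required lens power and the patient ends
up hyperopic (the "hyperopic surprise"). "No-history" methods correct for
this using only the measurements available at the cataract visit: axial
length (AL, mm), mean keratometry (K, D) and the lens A-constant, with no
pre-refractive-surgery data.

`postiol` implements the full evaluation pipeline for seven such methods —
ALMA, Barrett True-K, Ferrara, Jin, Kim, Latkany (flat-K) and Shammas — on a
per-eye cohort table:

1. **Back-calculation** of each method's predicted spectacle-plane refraction
   for the *implanted* IOL power, giving the refractive prediction error
   `PE = observed SE − predicted SE` (positive = hyperopic surprise).
2. **Lens-constant optimization** per IOL model by zeroing the mean PE.
3. **Accuracy batteries and paired tests** overall and within ranges of K,
   AL and the AL/K ratio.
4. A **range-based multi-formula selection rule** with an AL/K tie-break.

## The prediction model

Every internal method is a correction wrapped around a published thick-lens
vergence formula. The three base formulas share one vergence core (aqueous
index 1.336, keratometric radius $r = 337.5/K$, spectacle vertex 12 mm) and
differ in their effective-lens-position (ELP) model:

* **SRK/T** — corrected axial length (quadratic above 24.2 mm), corneal
  height from corneal width, ELP offset `0.62467 A − 68.747 − 3.336`, optical
  axial length with the retinal-thickness term `0.65696 − 0.02029 AL`.
* **Holladay 1** — anatomical ACD from the capped anterior-segment width
  (`AG = 12.5 AL / 23.45`, at most 13.5 mm) plus the surgeon factor
  `0.5663 A − 65.60`; optical axial length `AL + 0.2`.
* **Shammas-PL** — the post-LASIK variant: axial length pulled toward 23 mm
  (`L − 0.1 (L − 23)`), lens plane `pACD + 0.05` with
  `pACD = 0.5835 A − 64.40`, corneal power `Kc / 1.0125`.

The method corrections, centralized in one registry and locked by golden
tests, are:

| Method  | Base      | Correction |
|---------|-----------|------------|
| Shammas | Shammas-PL| clinically derived `Kc = 1.14 K − 6.8` |
| Kim     | SRK/T     | true-net-power style `Kc = 1.114 K − 6.10` |
| Jin     | Holladay 1| `Kc = 1.114 K − 6.06`, aiming at −0.75 D |
| Ferrara | SRK/T     | variable index `n(AL) = −0.0006 AL² + 0.0213 AL + 1.1572`, `Kc = (n − 1) K / 0.3375` |
| ALMA    | SRK/T     | axial-length radius regression `r' = r (0.0276 AL + 0.3635)` |
| Latkany | SRK/T     | flat-K power regression, no-history limit: method power = SRK/T power − 0.21 D |

Barrett True-K is unpublished; the package treats it strictly as an external
predictor whose per-eye predicted refractions (possibly at several constants)
are registered with `external_predictions()`.

Because each vergence formula is linear in the IOL power, predicted
refraction and target power invert each other in closed form;
`emmetropic_power()` also offers a bracketed root-finding engine used as a
self-consistency check. Jin's −0.75 D aim is stored as a native target and is
honoured when recommending powers, but never enters the PE back-calculation,
which always predicts at the implanted power.

Two numerical details are worth knowing. The published SRK/T long-eye
quadratic does not exactly join `AL` at the 24.2 mm switch (it evaluates to
24.176 there), leaving a step of about 0.008 D in predictions; this is
inherited from the published formula and left as is. And the corneal-height
expressions clamp their square-root arguments at zero (domain guard), which
only activates far outside the plausible biometric range. All predictions are
spectacle-plane spherical equivalents at a 12 mm vertex; no corneal-plane
conversion is exposed. Predicted refraction rises strictly with the
A-constant at fixed implanted power (a deeper lens plane leaves the eye
underplussed), and falls strictly with implanted power.

## Constant optimization (zeroing the mean error)

Comparing formulas fairly requires removing each one's systematic offset:
per (IOL model × method) group the lens constant is adjusted until the mean
signed PE is zero. Groups need a known model and at least 3 eyes; eyes with
`iol_model = "UNKNOWN"` or in smaller groups are excluded from optimization
but retained in manufacturer-constant analyses — the package exposes both the
manufacturer-constant and the optimized-constant analysis mode throughout.

The search is bracketed root-finding on the A-constant scale (±6 units,
widened once to ±12; |ME| tolerance 1e-3 D — three printed decimals).
Because predicted SE is strictly increasing in the constant, the root is
unique when bracketed; a failed bracket keeps the manufacturer constant and
flags the group. For external Barrett tables the package scans a 0.01-unit
grid over the tabulated constants (ties toward the smaller constant); with
only one constant per eye the optimization degrades — documented, flagged
`offset_optimized` — to an additive refraction offset.

Zeroing removes the offset only to first order: the derivative of PE with
respect to the constant varies slightly across eyes in a group, so "PEs after
= PEs before − group mean" holds in the small-shift limit (verified as a
first-order property in the tests), while the exact claims — |ME| after ≤
|ME| before, and |ME| ≤ 1e-3 after success — hold always.

## Metrics and tests

`summarize_errors()` computes the conventional battery: signed ME, MedAE,
MAE, the standard error of the absolute errors, min/max, type-7 interquartile
range, `MAE ± 1.96 SE` as a 95% interval, and counts within ±0.50/±1.00 D
(inclusive thresholds, the literature's convention; the IQR is taken over
absolute errors, consistent with the surrounding columns).

The testing layer mirrors standard practice for paired formula comparisons:
exact one-sample Kolmogorov–Smirnov normality screening against a normal with
estimated moments (Lilliefors available as an alternative), a one-sample t
against zero ME, Friedman's rank test on absolute errors with
Bonferroni-adjusted pairwise rank-sum z comparisons (the post-hoc flavour is
the textbook rank-sum comparison; 21 pairs at k = 7), and Cochran's Q on the
within-threshold indicators with pairwise two-column Q tests — identical to
McNemar without continuity correction. A matrix with no discordant rows
carries no evidence of a difference and is reported as Q = 0, p = 1 rather
than an error. Significance is 0.05 throughout.

`rm_power()`/`rm_sample_size()` compute noncentral-F power for the one-group
repeated-measures design that motivates a minimum cohort size. The
Greenhouse–Geisser correction ε multiplies both degrees of freedom
(`df1 = (m−1)ε`, `df2 = (N−1)(m−1)ε`) and the correlation among repeated
measures ρ (default 0.5) enters the noncentrality as
$\lambda = N f^2 m / (1 + (m-1)\rho)$. Several λ conventions circulate for
within-subject designs; this one was chosen because it is the only candidate
under which the design's published inputs (f = 0.509 from partial η² = 0.206,
α = 0.05, power 0.85, m = 7, ε = 0.357, ρ = 0.5) yield a minimum of 27
subjects with 26 falling short — the adjudication the package's tests pin
down exactly.

## Range analysis and the multi-formula rule

Accuracy is compared within ranges of K, AL and AL/K. Cutoffs for the
four-range K and AL schemes come from quartiles (type-7) of the optimizable
subset, rounded to the nearest 1.00 D and 0.50 mm respectively (halves away
from zero); the canonical bounds are K 36/38/40 D and AL 26.5/28.0/29.5 mm.
The AL/K scheme is fixed at 2/3 (0.67) and 3/4 (0.75). All intervals are
left-open right-closed, `(a, b]`, so a boundary eye falls in the lower range,
matching the printed table headers. Cutoffs are always derived from the
optimizable subset and reused for both analysis modes.

`per_range_comparison()` runs the battery plus Friedman and Cochran tests per
range, flagging the lowest-MedAE method; ranges with fewer than 5 eyes are
summarized but not tested. `loess_trend()` draws tricube local-linear trends
of PE along each variable (span 0.75, degree 1 — the smoother's common
defaults, annotated on the plots).

`builtin_tables()` encodes the resulting decision rule: per (K range × AL
range) cell either ALMA, Barrett True-K, or the pair; pair cells consult the
AL/K row (never overriding a single-method cell — the rows exist only as
tie-breaks), and an inconclusive AL/K row keeps the pair with the suggested
power the mean of the two methods' powers for the surgeon's target.
Recommendations are research decision-support output, not clinical advice.

## The synthetic cohort generator

No public post-LRS cohort exists, so `simulate_cohort()` emulates one:
(AL, K) from a truncated bivariate normal (defaults AL 27.65 ± 2.11 mm on
[23.72, 34.20], K 38.08 ± 2.69 D on [31.56, 43.81], correlation −0.5 — more
myopic eyes had more flattening), IOL models by market share with labeled and
true A-constants, implanted power set by a ground-truth method for a slightly
myopic target quantized to 0.5 D steps, and observed refraction = the truth
method's own noiseless prediction (at the true constant) plus Gaussian noise
(default SD 0.4 D, a realistic subjective-refraction repeatability). About
19% of records lose their model label, reproducing the typical known/unknown
split (132 → 90 optimizable in a 132-eye cohort). A sidecar table carries the
generating method, true constants and noiseless refractions, making recovery
tests exact. `truth_mixture_cohort()` varies the generating method by
biometric range to test that the range comparison recovers the truth.

The generator models measured post-LRS K directly — no ablation-profile
physics, no topography, no device error models beyond additive noise — which
is sufficient for pipeline validation but means passing tests say nothing
about which method is clinically best in real eyes; clinical conclusions
require patient data. Every stochastic function takes an explicit seed and is
byte-reproducible.

Test problem sizes were chosen to keep the suite quick while leaving the
properties sharp: 200-eye grids for inversion identities, 50–132-eye cohorts
for optimization, 60 eyes per range (at noise SD 0.05 D) for truth-mixture
recovery.

## Worked example

```{r example, eval = FALSE}
co <- simulate_cohort(132, seed = 2026)
cst <- optimize_constants(co, methods = c("ALMA", "KIM", "SHAMMAS"))
pred <- predict_refraction(co, methods = c("ALMA", "KIM", "SHAMMAS"),
                           constants = cst)
summarize_errors(pred)

sch <- derive_cutoffs(co$k_d[co$iol_model != "UNKNOWN"], step = 1, variable = "K")
rc <- per_range_comparison(pred, co, sch)
rc$summaries |> filter(best_medae)

recommend(co, mode = "optimized", compute_power = FALSE) |> head()
```

## Known limitations

* The Barrett True-K formula is unpublished: only passthrough predictions
  are supported, and single-constant optimization is an offset approximation.
* Correction coefficients for ALMA, Ferrara, Jin, Kim and Latkany are
  transcribed from the comparative literature and locked by golden tests;
  published variants exist (e.g. flat-K vs average-K Latkany) and ALMA is
  implemented as its axial-length radius-regression core.
* Haigis-L (needs ACD), contact-lens and intraoperative-refraction methods
  are out of scope, as are biometer file formats and toric/multifocal lenses.
* Reported accuracy on synthetic cohorts reflects the generator's
  assumptions, not clinical performance.
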