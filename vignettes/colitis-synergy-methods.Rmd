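---
title: "Methods: scoring, MPO quantification and bootstrap synergy testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, MPO quantification and bootstrap synergy testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coliboot)
```

coliboot implements the analysis layer of a multi-arm mouse DSS-colitis
drug-combination experiment. This vignette is the package's account of the
underlying methods: what each computation assumes, which parameters matter,
what the synthetic-data generator does and does not emulate, and where the
design was genuinely open and a choice had to be made.

## The composite damage scores

The **macroscopic score** is an ordinal composite over five observations
made at necropsy on day 7:

| component | range | rule |
|---|---|---|
| stool consistency | 0–3 | 0 = well-shaped pellets, 3 = diarrhea (expert-assigned) |
| ulcers | 0–3 | number of ulcers; counts above 3 are treated as already at the ceiling |
| colon length | 0–4 | percent-change bins vs the control-group mean |
| colon weight | 0–4 | same bins |
| fecal blood | 0–1 | present/absent |

The percent-change bins are: ≤5% → 0, more than 5% and below 15% → 1,
15–<25% → 2, 25–<35% → 3, ≥35% → 4. Two numerical choices live here and are
centralized in `percent_change_points()`:

* **Seam convention.** The rule table as conventionally printed overlaps at
  5% and 35%. We resolve the bins as closed below — exactly 5% scores 0 and
  exactly 35% scores 4 — letting the more specific severe clause win at the
  top seam. The choice only matters for measurements landing exactly on a
  seam.
* **Absolute deviation.** Colitis shortens the colon but can raise its
  weight, and the direction is not part of the rule; the bins act on
  `100 * |value − control_mean| / control_mean`. The function is therefore
  scale-invariant (same points for `k*value` vs `k*control_mean`), which the
  test suite checks as a property.

The **microscopic score** is the plain sum of five expert histology
subscores (goblet depletion 0/1, crypt abscesses 0/1, mucosal architecture
1–3, muscle thickening 1–3, immune infiltration 1–3), ranging 3–11. Scores
are inputs here: the package does no image analysis.

Whether colon weight should be scored with or without fecal content is not
settled by the scoring rule itself (the weighing happens with content); the
package scores the value as recorded and leaves the harmonization to the
data-collection protocol.

## MPO activity from kinetic traces

Neutrophil myeloperoxidase activity is the inflammation proxy. The assay
reads 450 nm absorbance of an O-dianisidine/H₂O₂ reaction in triplicate at
0, 30 and 60 s. The computation is:

1. per replicate, the ordinary least-squares slope of absorbance vs time,
   converted to absorbance/min;
2. aggregation over replicates — mean by default, median available for
   outlier-heavy plates (`aggregate = "median"`);
3. inversion of the standard curve `rate = slope · activity + intercept`
   fitted on purified peroxidase of known activity
   (`fit_standard_curve()`, OLS with residual diagnostics retained):
   `activity_in_well = (rate − intercept) / slope` in mU;
4. normalization to tissue: the well contains
   `homogenate_concentration × supernatant_volume` grams of tissue
   (defaults 0.030 g/mL × 0.007 mL, i.e. ~30 mg/mL homogenate and a 7 µL
   aliquot), so activity per gram of wet tissue is the well activity divided
   by that product.

Step 4 is the one genuinely open design point: assay write-ups typically
stop at "expressed per gram of wet tissue" without the dilution arithmetic.
The grams-in-the-aliquot accounting above is the standard choice; it is
isolated in `mpo_activity()` with both constants exposed, so a lab using a
different convention changes one call. Note the consequence: with the
default constants one well represents only 2.1·10⁻⁴ g of tissue, so
per-gram numbers are ~4,800× the per-well mU — display units (mU/g vs µU/g)
are a labelling choice, and the pipeline computes in mU/g throughout.

Negative fitted rates and negative well activities clamp to 0 with a
warning: enzyme activity cannot be negative, and a falling trace is a
plate artifact, not evidence of negative peroxidase.

`synthesize_mpo_kinetics()` inverts the whole chain: given a target
activity, it produces the straight-line triplicate trace (plus optional
i.i.d. Gaussian read noise) that the forward computation maps back to the
target — exactly at zero noise, and unbiasedly under noise provided the
signal is well above the noise floor. The noisy round-trip tests therefore
use a steep standard curve (10 abs/min per mU) so that the encoded rate is
several noise SDs above zero; with a shallow curve and the default dilution
constants, a 10 mU/g activity encodes a per-well rate of 2·10⁻⁵ abs/min,
which no plate reader resolves — a real assay is calibrated so that its
working range is measurable, and the tests emulate that.

## The bootstrap synergy test

Small arms (5–10 animals) give the classical t-test little power, and the
question "is the combination different from the monotherapy?" is asked on
top of a battery of other tests. The package's core inferential tool is a
bootstrap hypothesis test on the absolute difference in group means:

* observed statistic `T = |mean(a) − mean(b)|`;
* B = 10,000 bootstrap iterations by default;
* p-value = (number of resampled statistics ≥ T) / B, inclusive ≥, no +1
  smoothing, so p = 0 is attainable;
* fully deterministic given `seed`, and the caller's RNG stream is left
  untouched.

**Null construction.** "Resampling with replacement from the data" admits
two readings. Drawing each group from *itself* preserves the observed group
difference, so the resampling distribution is centred on T rather than on
the null — the resulting number is not a hypothesis-test p-value. A valid
test must resample under the null, which we impose by **pooling** the two
samples before drawing both resamples. Both strategies are implemented
behind `strategy = c("pooled", "per-group")` — pooled is the default and the
one whose operating characteristics the test suite verifies; per-group
exists for comparison with pipelines that resample that way.

**Verification.** Because every with-replacement resample pair from a pool
of size N is equally likely, the exact p-value is computable for tiny
groups by enumerating all N^N outcomes (`exact_p_oracle()`, refused above
10⁷ outcomes). The suite checks the Monte-Carlo test against the oracle on
randomized small instances (agreement within 4 binomial SEs at B = 10,000),
checks type-I calibration on N(0,1) arms of n = 8 (rejection rate at
α = 0.05 within [0.03, 0.08] over 1,000 simulated experiments, plus a
Kolmogorov–Smirnov uniformity check on the p distribution), and checks
power monotonically: a combination arm shifted 3 pooled SDs beyond
additivity is flagged in at least 80% of 500 replicates, while a
combination arm identical in distribution to the monotherapy rejects at the
nominal rate. Simulation sizes (1,000 null experiments, 500 power
replicates, inner B = 2,000 in the replicated suites, B = 10,000 wherever a
single test is pinned to the default) were chosen once as the smallest
sizes at which the binomial noise of the check itself is well below the
bands being asserted.

**Ties.** The inclusive ≥ means that with heavily discrete data (constant
groups, small integer scores) the test is conservative: identical constant
arms give T = 0 and p = 1, never a spurious rejection.

## The comparison pipeline

`build_report()` mirrors how such studies are reported, per endpoint
(body-weight change %, macroscopic score, colon length, colon weight, MPO
activity):

* group summaries: mean, SD, SEM = SD/√n, n — the "mean ± SEM" panel;
* Shapiro–Wilk per group — a rejection **warns** but does not abort, since
  the parametric battery is run regardless and the bootstrap contrast is
  the robustness check;
* one-way ANOVA, then pooled-variance t-tests on the configured contrast
  set (default: every arm vs control, every treated arm vs DSS) with
  Bonferroni adjustment *within that set* (adjusted p = min(1, m·p));
  no correction is applied across endpoints, matching common reporting
  practice in this field, and the report makes the contrast set explicit so
  readers can judge the multiplicity;
* the mono-vs-combination bootstrap contrasts, reported as (observed
  difference in means, P_bootstrap) pairs; each contrast receives a
  deterministic sub-seed derived from the report seed, so the report
  contrast is identical to a standalone `bootstrap_p()` call on the same
  two columns (asserted as an invariant — no hidden filtering);
* significance stars at 0.05 / 0.01 / 0.001 / 0.0001, missing values
  excluded per endpoint with a logged count.

Reports serialize to JSON and CSV (`write_report()`); the run is
reproducible from (cohort CSV, config, seed).

## What the synthetic generator emulates — and what it does not

`default_design()` encodes a severe acute-colitis experiment: five arms of
n = 8 (within the usual 5–10; n is a design parameter), baseline body
weight N(24, 1) g as for 22–26 g adult mice, a −12% final body-weight
change and ~25% colon shortening under DSS, four-fold MPO elevation, modest
single-drug effects that are real on MPO and negligible elsewhere — the
qualitative pattern of a study in which monotherapies do not reach
significance on gross endpoints. The combination arm's mean is DSS + the
sum of the single-drug shifts + `synergy_shift`, so additivity is the
explicit null and `synergy_shift` is the one dial that encodes synergy
(scalar, or named per endpoint, in endpoint units; default 0).

Choices a user should know about:

* **Body-weight trajectories** are parameterized by their endpoint: baseline
  × a multiplicative daily trend landing exactly on the drawn final percent
  change at day 7. The within-week shape is a smooth convenience, not a
  disease-course model; analyses should use the day-7 change.
* **Ordinal endpoints are independent** of the continuous ones and of each
  other. Real data correlate (an animal with diarrhea tends to have a short
  colon); none of the package's operations exploit correlation, so the
  tests' conclusions about scoring arithmetic and test calibration carry
  over, but the generator must not be used to estimate, e.g., the joint
  distribution of score components.
* **Truncation.** MPO draws truncate at 0 and colon measurements at small
  positive floors; with the default parameters truncation is negligible,
  but designs that push means near 0 will see mild upward bias.
* Passing tests on this generator show that the *computations* are correct
  and the *test* is calibrated for normal endpoints at these n; they do not
  show that any real drug pair is or is not synergistic, and non-normal
  real endpoints (heavy tails, floor effects in scores) are exactly where
  the bootstrap contrast earns its keep over the t-test.

## Reproducibility and numerical conventions

Every stochastic entry point takes a `seed`; identical (inputs, seed) give
byte-identical output, and seeding is done on a saved-and-restored RNG
state so library calls never perturb a caller's stream. Degenerate inputs
are rejected with descriptive errors (negative SDs, probabilities not
summing to 1, empty samples, zero within-group variance, degenerate
calibration); the only silent-ish repairs are the documented clamps (ulcer
counts to 3, negative rates/activities to 0 with a warning).

## Known limitations

* The pipeline analyses endpoints one at a time; no multivariate or
  longitudinal modelling of the body-weight series.
* The bootstrap contrast tests mean differences only — no confidence
  intervals, no BCa machinery, by scope.
* Histology and stool scores are expert inputs; no image or sequence data
  is touched.
* The per-group resampling strategy is provided for comparability but its
  output should not be interpreted as a p-value (see above).
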