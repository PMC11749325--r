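---
title: "Methods: the neonatal HAI antibiotic decision-making pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the neonatal HAI antibiotic decision-making pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neohai)
```

## The problem

Healthcare-associated infection (HAI) in hospitalised neonates — infection
presenting after 72 h of admission — is hard to diagnose: symptoms are
non-specific, blood cultures take days, and most units therefore start
empiric antibiotics for every investigated episode. The result is long
antibiotic courses in infants who turn out not to be infected. This package
implements an episode-level analysis of a bedside decision strategy that
combines a five-item infection prediction score (NeoHoP) with a
point-of-care C-reactive protein (POC CRP) measurement at presentation (t0)
and 24 h later (t24), and quantifies the strategy's theoretical effect on
antibiotic length of therapy (LOT — calendar days on any systemic
antibiotic, irrespective of the number of agents).

## Reference standard

Each suspected-HAI episode receives one of three mutually exclusive labels
(`classify_hai()`):

* **Proven HAI** — a blood culture isolating a recognised pathogen,
  collected after 72 h of admission, with clinical signs; or
  coagulase-negative staphylococci (CoNS) adjudicated as true infection
  (two positive cultures 24–48 h apart, or a single positive culture with
  serum CRP ≥ 10 mg/L and clinical features of infection).
* **Presumed HAI** — negative culture, serum CRP ≥ 10 mg/L, antibiotics
  continued ≥ 5 days.
* **No HAI** — short-lived symptoms, negative culture, serum CRP
  < 10 mg/L, antibiotics stopped within 48–72 h.

"Any HAI" (proven or presumed) is the reference standard for all
diagnostic-accuracy work. Three reading decisions were genuinely open and
are resolved as follows:

* The presumed / no-HAI branches use the *laboratory* CRP on which the case
  definitions are based, not the POC value the score uses. The episode
  schema therefore carries an optional `lab_crp` column; when it is absent
  the t0 POC CRP stands in. This distinction matters: the POC test can be
  falsely negative in a truly infected episode (that is precisely what the
  accuracy analysis measures), while an episode is only *labelled* presumed
  when the definitional CRP was elevated.
* Organisms on the contaminant list, and CoNS adjudicated as
  contamination, make the culture non-probative: such episodes fall through
  to the presumed / no-HAI branches as if culture-negative.
* The three definitions do not literally partition every field
  combination. Episodes matching no branch are returned as
  `"unclassifiable"` with the conflicting fields, counted, and excluded
  from accuracy denominators — never silently defaulted.

## The score, the tests and the tool

The NeoHoP score (`compute_neohop()`) awards one point each for capillary
refill time > 3 s, lethargy, abdominal distention, a central venous
catheter in situ or within 48 h, and CRP ≥ 10 mg/L (the t0 POC value), and
is positive at ≥ 2. All threshold comparisons are inclusive, with no
tolerance band. Five candidate tests are evaluated (`test_positivity()`):
CRP t0, NeoHoP t0, CRP t24, "CRP t0 or t24", and the stepwise rule
"NeoHoP t0, then CRP t24 for score-1 episodes". Missing measurements
propagate as `not_evaluable` and shrink the denominator; nothing is
imputed. For the either-time-point CRP rule an episode negative at t0 with
no t24 measurement is not evaluable — a negative call requires both
measurements, a positive call only one.

The bedside tool (`recommend_tool()`) maps the score to an action: 0 — no
antibiotics and no further investigations; 1 — start antibiotics, and let
the t24 CRP decide between cessation after 24 h and continuation; ≥ 2 — a
full course. Theoretical LOT (`theoretical_lot()`) is 0 days for the
no-antibiotics branch, 1 day for early cessation, and the observed LOT
where the tool would have continued. Where the tool says "continue" but the
clinician in fact stopped early, the observed (shorter) course is copied —
the conservative reading, since reassignment is only defined relative to
observed courses. Score-1 episodes with no t24 CRP have no tool outcome and
are excluded pairwise from LOT comparisons, with counts reported.

## Diagnostic accuracy

`diagnostic_metrics()` computes sensitivity, specificity, predictive
values, accuracy and likelihood ratios from a confusion matrix built
against the any-HAI standard. Percentages are displayed to one decimal and
ratios to two, rounded half away from zero **in two stages** (the percent
value is first rounded to two decimals, then to one). Two-stage rounding is
the display convention of common clinical statistics packages and is what
reproduces reference cells such as 60/79 → 76.0 % (single-stage rounding
would print 75.9) and 77/80 → 96.3 %. A guard of 1e-9 is added before
truncation so decimal ties (96.25) round upward despite binary floating
point. Metrics with zero denominators are undefined (`NA`), never coerced
to 0; a perfect test has an undefined positive likelihood ratio rather
than an infinite one. Wilson and Clopper–Pearson intervals are available
(`metric_ci()`), and ROC AUC is computed by the rank formula, equivalent to
trapezoidal integration with tied scores contributing one half.

## Exhaustive CHAID

`grow_tree()` implements the exhaustive variant of Chi-squared Automatic
Interaction Detection over categorical predictors. For each predictor at a
node, the merge search (`best_grouping()`) starts from all observed
categories separate and repeatedly merges the *least* significantly
different pair of compound categories until two groups remain; every
intermediate grouping is tested against the outcome (Pearson chi-square
without continuity correction; a likelihood-ratio variant sits behind the
`test` option) and its p-value is multiplied by the number of ways to
partition the original c categories into that many groups (the Stirling
number S(c, g)) — the Bonferroni adjustment for a nominal predictor. The
grouping with the smallest adjusted p wins; the node splits on the
predictor with the smallest winning p at or below `alpha_split`. Ties break
deterministically: smaller adjusted p, then larger chi-square, then
lexicographic predictor name.

Stopping rules default to `alpha_split = 0.05` (the analysis-wide alpha),
`min_parent_size = 20`, `min_child_size = 7` and `max_depth = 3` — sane for
a cohort of ~200 episodes and all configurable; none of these control
parameters is dictated by the underlying study, which reports only the
method. Bit-exact replication of any particular proprietary CHAID
implementation is explicitly not promised; the test surface is structural
(on calibrated synthetic data the tree splits first on the banded score
{0, 1, ≥ 2} and then on the t24 CRP within the score-1 band) plus oracle
equivalence against brute-force partition enumeration on small inputs.
Whether the underlying analysis used the raw 0–5 score or bands is not
knowable from the published material; both work here, and the bundled
analysis uses bands because they map 1:1 onto the tool's branches.

## Nonparametric comparisons

LOT distributions are summarised as median and IQR. Quartiles default to
Tukey hinges (`stats::fivenum()`), with type-7 linear interpolation behind
an option; the published integer-valued IQRs are insensitive to the choice
at these sample sizes. The Mann-Whitney U test (`mann_whitney_u()`)
computes U from midranks. Exact mode obtains the permutation distribution
of the rank sum by dynamic programming over doubled midranks (doubling
keeps tied midranks integral), so ties are handled exactly; the two-sided
p is `min(1, 2·min(P(U ≤ u), P(U ≥ u)))`. Approximate mode uses the normal
approximation with tie-corrected variance and continuity correction and
agrees with `stats::wilcox.test()` to numerical precision. The two modes
converge as samples grow: the worst absolute gap on tie-free data falls
below 0.01 by n = 15 per arm (at n = 8 per arm it can reach ~0.011, and
several times that under heavy ties — a property of the approximation, not
of either implementation).

The observed-vs-theoretical comparison (`lot_comparison()`) runs
Mann-Whitney on the two LOT vectors per stratum, matching the stated
toolbox of the underlying analysis even though the vectors are paired; a
Wilcoxon signed-rank alternative sits behind the `test` flag. Strata where
the vectors are identical report p = 1 without invoking a test.

## The synthetic cohort

Patient-level data for this problem are not publicly deposited, so
`generate_cohort()` produces cohorts with the structure the analysis
assumes, and the defaults of `cohort_config()` *are* the study conditions:
214 episodes, class probabilities 22/214, 56/214, 136/214, t24 CRP missing
with probability 9/214, and per-test positivity calibrated from the
reference confusion counts by `calibrate_from_counts()`
(P(positive | any HAI) = tp/(tp+fn), P(positive | no HAI) = fp/(fp+tn)).
Generation is class-first; every downstream field is then drawn
consistently with the class, which is what makes the 100 % round-trip
property (every episode re-classifies to its sampled label) testable.

Distributional choices the published marginals do not pin down, chosen once:

* **CRP** is class-conditional lognormal with log-scale SD 0.6 and
  location solved so the cutoff exceedance equals the calibrated
  positivity. Only the exceedance matters to any downstream computation;
  the shape is cosmetic. A target exceedance of exactly 0 is clamped to
  1e-4 to keep the location finite. Values are clamped to the 1–200 mg/L
  device range.
* **The laboratory (definition) CRP** is drawn from the same lognormal,
  truncated above the cutoff for any-HAI episodes and below it for no-HAI
  episodes. Without a separate laboratory value the calibrated 76 %
  POC-CRP sensitivity and the definitional requirement that presumed
  episodes have CRP ≥ 10 mg/L would be mutually inconsistent.
* **The four clinical score components** are Bernoulli, independent given
  class, at a common prevalence solved (by `uniroot`) so that
  P(score ≥ 2) matches the calibrated NeoHoP positivity — the parsimonious
  solution, since no joint or per-component prevalences are published.
* **LOT** is gamma, truncated to the class's admissible range (≥ 5 days
  for presumed, ≤ 3 days for no HAI), discretized to half days, with
  parameters fitted by least squares to the published class quartiles
  (proven 9 (7–14), presumed 7 (5–9), no HAI 3 (2.5–3)); the median gets
  weight 4 versus 1 for the hinges because a two-parameter skew family
  cannot always hit all three quartiles and the median is the primary
  reported statistic. 8/136 of no-HAI episodes never start antibiotics
  (LOT 0); their stop flag is set, which a never-started course satisfies
  vacuously.
* **Cultures**: 35 % of proven episodes grow CoNS (half by paired
  cultures, half single-culture adjudicated through the elevated
  definition CRP plus signs); a small fraction (2 %) of non-proven
  episodes grow listed contaminants, and no-HAI episodes may additionally
  grow CoNS read as contamination.

What the generator deliberately does **not** emulate: demographics
(gestational age, birth weight), organism-level taxonomy, correlation
between the clinical score components, correlation between t0 and t24 CRP
beyond class membership, and informative missingness of the t24 CRP
(missingness is MCAR). Passing tests on these cohorts therefore
demonstrate that the pipeline's logic is correct under the published
marginal structure — not that the tool would achieve the same operating
characteristics on new real-world data, where component correlations and
missingness mechanisms differ.

## Problem sizes and numerical choices

The test suite exercises the pipeline at n = 214 (study scale; 200 seeds
for the LOT direction property), n = 10,000 for calibration recovery
(empirical sensitivity/specificity within ±2 percentage points of
calibration for all five tests) and the round-trip property, and small
enumerable inputs (n ≤ 8 + 8 for exact Mann-Whitney enumeration,
3-category toys for CHAID partition search) for the brute-force oracles.
Gamma fitting uses L-BFGS-B on log-parameters with shape bounded to
[0.05, 500]; the exact Mann-Whitney mode refuses combined samples above 60
(the dynamic program is quadratic in total rank mass) and directs the
caller to the normal approximation.

## Known limitations

The published headline medians (observed 3 → theoretical 1 days overall;
3 → 0 in the no-HAI stratum) concern one specific unavailable patient-level
dataset; this package reproduces them only in distribution on calibrated
synthetic cohorts — which it does, along with p < 0.001 for both
comparisons — and asserts the direction, not the exact medians, in its
tests. The accuracy-table reproduction, by contrast, is exact, because the
confusion counts are published. The AUC reported for the original tree
model is a model-internal statistic of unavailable data and is provided as
an operation (`score_auc()`) but not asserted against. Unclassifiable
episodes, not-evaluable test calls and tool branches are all surfaced and
counted rather than resolved by imputation, so denominators vary across
tests exactly as they do in the published table.
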