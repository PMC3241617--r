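---
title: "Estimating minimally important differences for treatment-satisfaction scales"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating minimally important differences for treatment-satisfaction scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

A patient-reported satisfaction instrument produces scores on a 0–100
standardised scale, but a score difference has no clinical meaning until it
is calibrated: the minimally important difference (MID) is the smallest
difference patients themselves perceive. `midsat` estimates the MID for
multi-domain satisfaction questionnaires — the 17-item, six-domain SATMED-Q
is the shipped default schema — by triangulating one anchor-based method
against three distribution-based benchmarks, the standard practice when a
prospective change anchor is unavailable (a cross-sectional design has only
one visit, so a transition item cannot be administered).

```{r setup}
library(midsat)
```

## Scoring model

Raw Likert responses (default coding 0–4 per item) are summed within each
domain and the sum is mapped linearly onto 0–100:

$$\mathrm{score} = 100\,\frac{\text{raw sum} - \text{raw min}}{\text{raw max} - \text{raw min}}.$$

Reverse-coded items are flipped (`min + max − value`) before summation;
by default the three side-effects items are reverse-coded, because
side-effect items are answered in the direction opposite to satisfaction
("No, not at all" is the most satisfied answer). The total composite
standardises the 17-item raw sum rather than averaging domain scores, so
items — not domains — carry equal weight; with a 2-item medical-care domain
next to 3-item domains the two conventions genuinely differ, and the
item-sum rule is the standard one for composite Likert totals. Both the raw
coding and the reverse-keyed set are schema fields, not constants: the
instrument's published description leaves the raw coding ambiguous (a
"0 to 20" raw range is quoted for 3-item domains, which no 5-point coding
yields), so the schema makes the choice explicit and configurable.

Missing items are handled by policy: `complete_only` (a domain with any
missing item is missing) or `prorate_half` (a domain with at least half its
items answered is scored from the mean of answered items rescaled to the
full range). Every cell of the score matrix carries a provenance flag
(`complete` / `prorated` / `missing`), and the total requires all domains.

## Anchor model

The anchor is a single 7-category global-satisfaction item with a neutral
midpoint (code 4 on the 1–7 coding). Only the *distance* from neutral is
used — satisfied and dissatisfied sides are merged — giving four difference
levels: reference (0), small (1), medium (2), large (3). The numeric coding
of the categories is a schema field; since the method only uses symmetric
distance, only the neutral position matters.

The anchor-based MID of a scale is the absolute difference between the
small-level and reference-level means. Medium and large step differences
are reported alongside; monotonicity across steps is *reported, never
enforced*, because real data can produce a non-monotone step when an
extreme anchor category is sparsely populated (the reconstruction's
side-effects domain shows exactly this: the large-level gap is smaller than
the medium-level gap).

## Distribution-based benchmarks

All three use the whole-sample SD $s$ of the scale with the $n-1$
denominator — a deliberate convention choice, stated in the report
metadata, rather than a within-group pooled SD:

* effect size $\mathrm{ES} = \mathrm{MID}/s$, labelled by the conventional
  bands (<0.20 negligible, 0.20–<0.50 small, 0.50–<0.80 moderate, ≥0.80
  large);
* one-half SD, $s/2$;
* standard error of measurement, $\mathrm{SEM} = s\sqrt{1-r}$.

The reliability $r$ is a per-scale input: supplied directly (e.g. from a
prior validation study) or computed as Cronbach's alpha
$\alpha = \frac{k}{k-1}\left(1 - \sum_i v_i / v_T\right)$ from item-level
data with listwise deletion. The report records which source was used,
because the two can differ materially and SEM inherits that difference.

## Inference

* **ANOVA across difference levels** is computed in both the classic and
  the Welch (variance-weighted, Welch–Satterthwaite df) forms, from group
  summary moments — the classic form reconstructed from sums of squares is
  identical to a raw-data ANOVA with the same moments, and the Welch form
  is identical to `stats::oneway.test()`. Both are always reported: with
  heterogeneous group variances (flagged by Levene's test) the two can
  disagree noticeably, and reporting both is more transparent than choosing
  one after the fact. The two statistics coincide only asymptotically even
  at equal group variances and sizes, because the Welch denominator
  correction does not vanish at finite $n$.
* **Levene's test** is a one-way ANOVA on absolute deviations from the
  group centre; centring defaults to the mean (the classic test) with the
  median (Brown–Forsythe) available.
* **Pairwise contrasts** vs the reference level use two-sided t-tests with
  Bonferroni adjustment, $p_{adj} = \min(1, m\,p)$ with $m$ the number of
  comparisons performed.
* **Percentile bootstrap**: the whole sample is resampled with replacement
  (group sizes vary per replicate, per the estimator's sampling model; a
  stratified mode is available as a sensitivity flag), the per-level mean
  difference vs reference is recomputed in each replicate, and the 2.5/97.5
  percentiles give the 95% limits. Replicates in which a required group
  comes up empty are dropped and counted; more than 10% dropped flags the
  result. Bootstrap differences are *signed* (a level straddling the
  reference can legitimately produce an interval crossing zero) while the
  headline MID is absolute; both conventions are stated in the output.
* **Clinician contrast**: as an external-validity check, the
  treatment-effectiveness score is contrasted across clinician-rated
  effectiveness groups (poor/acceptable/good/excellent) against the
  `acceptable` reference, with Welch standard errors and Bonferroni
  adjustment over the three non-reference categories.

## The synthetic cohort generator

The raw study data behind the shipped group-summary targets are not
public, so the generator stands in for them at two fidelity tiers.

**Latent tier (continuous).** Per difference level, scores are drawn from
a normal with the target moments — by default truncated to [0, 100] by
inverse-CDF sampling, which produces the negative skew and ceiling
concentration typical of satisfaction scores. `moment_match()` then
rescales each group affinely so its sample mean and SD equal the targets
*exactly* (to 1e-9); matching is idempotent, never changes group
membership, and never clips — values pushed past a bound are flagged
instead, because clipping would break the exactness that is the tier's
whole point. `reconstruct_satmedq_study()` applies this to all 28
scale-by-level cells of the published summary table, so every anchor-based
quantity computed downstream reproduces the published values. The
reconstruction implies a whole-sample composite mean of about 75.04 and SD
of about 14.77; the published whole-sample figures (75.03, 14.76) differ
in the last digit and no forcing is applied.

**Item tier (discrete).** Latent domain scores are discretised into item
responses: the score is converted to the nearest attainable raw domain sum
and spread across the domain's items as evenly as possible
(largest-remainder allocation, earlier items taking the surplus),
respecting reverse coding. Rescoring recovers each domain score to within
the quantisation bound $100/(2\,R)$ for raw range $R$. Exact group moments
are unattainable at this tier — Likert quantisation and ceiling clamping
bias group means by up to a few points — which is why alpha/scoring tests
use the item tier but all moment-exact checks use the latent tier. One
consequence worth knowing: the item-tier *total* is the standardised
17-item sum, so its anchor MID tracks the item-weighted mean of the domain
gaps (about 15.5 under the default targets), not the latent composite's
own gap (13.4); the two totals answer subtly different questions.

Generator defaults are the study conditions: 456 respondents split
68/213/136/39 across reference/small/medium/large; the large level split
35 satisfied / 4 extremely dissatisfied (the only published side split —
the small and medium levels default to 3:1 satisfied:dissatisfied, a
choice consistent with the overall satisfaction skew); clinician ratings
generated either by thresholding the effectiveness score (default cuts
30/55/81, placed so rating prevalences approximate the published contrast
precision, i.e. a poor group of about 3%) or, for parameter-recovery
studies, by drawing ratings multinomially and adding configured score
offsets so group contrasts recover the offsets in expectation. Scales are
drawn independently by default; a shared-latent correlation is available
behind `latent_cor` but no attempt is made to emulate the published
between-scale correlation matrix numerically, nor the demographic strata
beyond labels.

What passing tests on this cohort do and do not show: they verify the
estimator machinery exactly at the published group moments and verify
frequentist calibration (bootstrap coverage, shift recovery) under clean
mixture-normal data; they cannot certify behaviour under real-data
features the generator omits — item-level response styles, correlated
domains, informative missingness.

## Numerical choices

* Internally everything is carried at full double precision; only report
  views round — half *away from zero* (so 0.845 → 0.85), 1 decimal for
  score-scale quantities, 2 for effect sizes, matching how such tables are
  conventionally printed. `round_half_up()` guards the .5 boundary with a
  1e-9 epsilon against representation error.
* SDs use the $n-1$ denominator throughout; groups with $n<2$ have their
  SD flagged undefined rather than silently zero.
* Degenerate inputs degrade to flagged cells, not crashes: an empty anchor
  level yields an `n = 0` summary row; a zero-variance scale is flagged and
  its ES/SEM left missing; estimation failures in one scale never abort
  the others. Hard errors are reserved for schema violations (out-of-range
  responses, unknown items, degenerate raw ranges) and carry classed
  conditions naming the offending value.
* All randomness funnels through a single integer seed per generator or
  bootstrap call; reruns are byte-identical, including the written report
  bundle (the JSON serialises doubles at 17 significant digits so the
  round trip is bit-exact).
* Bootstrap needs at least 100 replicates (percentile limits are
  meaningless below that) and defaults to 1000.

## Problem sizes used by the test suite

The automated checks run the full 456-respondent reconstruction for all
exact quantities; calibration properties use 200 simulations at 400
bootstrap replicates (coverage), 10 seeds × 3 contrasts (shift recovery),
and 100 random datasets for the summary-vs-raw ANOVA identity — sizes
chosen to make binomial pass thresholds sharp while keeping the suite
quick to run.

## Known limitations

* The anchor design is cross-sectional: the MID calibrates *between-person*
  score gaps against perceived satisfaction levels, not within-person
  change. Prospective transition anchors and external clinical-event
  calibration are out of scope.
* Only the neutral-adjacent contrast defines the MID; a signed
  (directional) anchor analysis separating the satisfied from the
  dissatisfied side is not implemented, since the merged design is what the
  grouped summaries support.
* Reliability coefficients computed from the synthetic item tier reflect
  the generator's allocation mechanism (within-domain item agreement is
  high by construction), so SEM values on synthetic data should be read as
  machinery checks, not instrument properties.
* The multi-scale reports apply no multiplicity control across scales;
  Bonferroni adjustment is applied only within pairwise level contrasts.
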