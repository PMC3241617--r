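# midsat

Minimally important difference (MID) estimation for treatment-satisfaction
questionnaires scored on a 0–100 standardised scale, with the 17-item,
six-domain SATMED-Q instrument as the built-in default.

## The problem and the method

Patient-reported satisfaction scales need an interpretability benchmark:
how many points on the 0–100 scale correspond to a difference a patient
actually perceives? `midsat` estimates that MID by triangulating one
anchor-based and three distribution-based methods.

**Anchor-based MID.** Respondents also answer a single global-satisfaction
item on a 7-point ordinal scale (extremely dissatisfied … neutral …
extremely satisfied). Each response is classified by its distance from the
neutral category, merging the satisfied and dissatisfied sides:

| anchor codes | level |
|---|---|
| 4 | reference (neutral) |
| 3, 5 | small |
| 2, 6 | medium |
| 1, 7 | large |

For every scale (each domain and the total composite), the MID is the mean
absolute difference between the *small* group and the *reference* group:

```
MID = | mean(score | small) − mean(score | reference) |
```

with the medium- and large-level gaps reported as step differences.

**Distribution-based benchmarks**, all using the whole-sample SD `s`
(n−1 denominator) of the scale:

- effect size (Kazis): `ES = MID / s`, labelled negligible (< 0.20), small
  (0.20–< 0.50), moderate (0.50–< 0.80) or large (≥ 0.80);
- one-half SD: `s / 2`;
- standard error of measurement: `SEM = s · sqrt(1 − r)`, where `r` is the
  scale's reliability (Cronbach's alpha, computed from item data or
  supplied).

Inference accompanies the estimates: classic and Welch one-way ANOVA
across the four difference levels (computable from raw data or from group
summary moments alone), Levene's test, Bonferroni-adjusted pairwise
contrasts vs the reference group, and a percentile bootstrap (whole-sample
resampling with replacement, 2.5/97.5 percentiles of the replicate mean
differences) for the confidence intervals.

Because the original respondent-level data are not public, the package
also ships a synthetic-cohort generator: `reconstruct_satmedq_study()`
draws a 456-respondent cohort and affinely rescales each scale within each
anchor level (`moment_match()`) so that all 28 published group means and
SDs are reproduced exactly, making every anchor-based estimate computable
without any download.

## Worked example

```r
library(midsat)

study <- reconstruct_satmedq_study(seed = 1)
fit <- mid_estimate(study$scores, study$levels, reliability = c(total = 0.840))
fit
#> Triangulated MID estimates (n = 456 respondents)
#>
#>                     scale  MID SEM half SD   ES    label
#>   treatment_effectiveness 15.6  NA    10.9 0.71 moderate
#>        convenience_of_use 15.1  NA    11.6 0.65 moderate
#>       impact_daily_living 20.6  NA    12.2 0.85    large
#>              medical_care 10.2  NA     9.8 0.52 moderate
#>      general_satisfaction 18.1  NA    10.6 0.85    large
#>  undesirable_side_effects 11.5  NA    10.0 0.58 moderate
#>                     total 13.4 5.9     7.4 0.91    large

confint(fit, parm = "total", B = 1000, seed = 1)
#>   scale  level mean_mid    se ci_low ci_high
#> 1 total  small    13.36 1.780  9.959   16.90
#> 2 total medium    23.26 1.798 19.743   26.78
#> 3 total  large    30.02 2.015 26.138   34.01
```

Reading: a change of about 13 points on the 0–100 total satisfaction score
is the smallest difference associated with a one-step move away from the
neutral anchor category — an effect size of 0.91 whole-sample SDs, roughly
twice the SEM benchmark (5.9) and above the half-SD benchmark (7.4), so
the anchor-based estimate is a conservative, clearly perceptible change.
The bootstrap places its 95% interval at about 10–17 points.

`run_mid_pipeline()` chains scoring → anchor classification → estimation →
inference → bootstrap from a raw respondent table (one row per respondent:
17 item columns, `anchor`, optional `clinician_rating`) and writes the
group-summary, MID, bootstrap and descriptive tables as CSV plus a
full-precision JSON report; reruns with the same seed are byte-identical.
A small synthetic example dataset and the instrument schema files are in
`inst/extdata/`.

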