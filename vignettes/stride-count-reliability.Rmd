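---
title: "How many strides does a reliable gait variability measurement need?"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How many strides does a reliable gait variability measurement need?}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stridevar)
```

## The measurement model

A continuous over-ground walk with 180° turns, recorded by a body-worn
inertial sensor system, is exported as a stride-wise table: one row per
gait cycle with its onset timestamp, stride length (normalized to percent
of body stature) and stride time (seconds). The export software excises
turns, so a properly processed trial shows straight-walking *segments*
separated by timestamp *gaps* where the turns were. Everything in this
package operates on that tabular export model; raw inertial signals and
the vendor's segmentation algorithm are outside its scope — only the
algorithm's observable output (gaps, or their absence when a turn is
missed) is modeled.

Gait variability is quantified as the coefficient of variation,
$\mathrm{CoV} = 100 \cdot s/\bar{x}$, with $s$ the *sample* SD
($n-1$ denominator — the convention of the reliability literature; the
package uses it everywhere). Two complementary reliability views are
computed:

1. **Consistency across segments.** Each straight segment yields a mean
   and CoV per parameter; treating segments as repeated measurements, a
   two-way random-effects single-measure intraclass correlation is
   computed from the ANOVA mean squares,
   $$\mathrm{ICC}(2,1) = \frac{MS_R - MS_E}
     {MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)},$$
   banded as poor (< 0.4), fair to good (0.4–0.8, both ends inclusive)
   and excellent (> 0.8). The mean squares come from explicit sums of
   squares and are returned for audit; the test suite checks them to
   1e-10 against an independent `aov()`-based oracle.
2. **Convergence of cumulative statistics.** For each subject the mean
   and CoV of the first $n$ strides are evaluated for
   $n = 3, \dots, N_{\max}$, and for each $n$ the Pearson correlation
   across subjects between the value at $n$ and the value at $N_{\max}$
   is formed. The smallest $n$ with $R > 0.8$ is reported as the stride
   count needed for a reliable estimate. $N_{\max}$ is 40 under standard
   excision and 32 under the generous mode (which removes eight strides
   from a four-turn trial). The profile ends at exactly 1 by
   construction.

Two rules here were genuinely open choices:

* **First crossing, not sustained exceedance.** Convergence profiles can
  dip after first crossing the criterion (a late aberrant stride lowers
  correlations at intermediate $n$). The default reports the first
  crossing; `required_stride_count(..., sustained = TRUE)` instead
  requires the profile to stay above the threshold through $N_{\max}$,
  for users who consider a dip disqualifying.
* **The individual reference includes peri-turn strides.** Peri-turn
  strides are normalized to the mean of the subject's first 40 (or 32)
  analyzed strides *including* the peri-turn strides themselves, since
  they are part of the exported window. Excluding them would shift the
  reference by well under the peri-turn effect size but would no longer
  correspond to "the mean of all analyzed strides".

## Turn detection and quality control

Turns are detected as gaps: an inter-onset interval exceeding
`gap_factor` (default 1.5) times the subject's **median** stride time.
Referencing each subject's own tempo makes the threshold scale-free: a
slow walker's long strides are not mistaken for gaps, and a fast walker's
turns are not missed. The median (not the mean) is used so that the
threshold itself is robust to the short turning strides present when a
turn was *not* excised. With turn gaps of 2–5 s and stride times near
1 s, the margin between the longest stride and the shortest gap is wide,
which is why detection on clean data is complete with zero false
positives (a property the suite checks across seeds).

Non-detection QC automates what is usually a visual check of the stride
plot. Two flags are raised: `missed_turn_suspected` when fewer gaps than
the protocol's turn count are found, and `implausible_short_strides` when
any stride *not* adjacent to a gap is shorter than `short_stride_frac`
(default 0.5) of the trial's median stride length — turning steps are
roughly half-length or less, so 0.5 separates them cleanly from
physiological variation at CoVs of a few percent. Either flag marks the
trial excluded; excluded trials are dropped from all downstream
statistics, never repaired.

The generous excision mode (`excision_width = 1`) removes one additional
stride on each side of every gap. The width parameter is an abstraction:
what a vendor's excision already removes is generally undisclosed, so the
package exposes the amount of extra trimming as an explicit, auditable
knob rather than hard-coding either convention.

## What the synthetic generator emulates — and what it does not

`generate_trial()` draws a subject's mean stride length and stride time
from the group's between-subject normal distributions, then draws each
stride independently from $\mathcal{N}(\mu_{subj},
(\mu_{subj}\cdot \mathrm{CoV}/100)^2)$. Onsets are cumulative sums of
stride times; a uniform 2–5 s gap (chosen to exceed any plausible stride
time; the true turn duration distribution is not modeled) separates
consecutive segments. The built-in group profiles encode published
cohort statistics for healthy elderly and for ataxia, essential tremor
and Parkinson's disease groups; segment stride counts default to 8 per
10 m segment and 14 per 20 m segment (about 1.3 m strides), so both
protocols deliver at least 40 strides per trial.

Strides adjacent to a gap are tagged and perturbed: in the
movement-disorder protocol the stride *after* each turn is shortened by
2.8% and lengthened in time by 3.2%; in the healthy-elderly protocol
strides before *and* after turns are perturbed by 1.2% / 1.4%. Per-group
peri-turn effect sizes for the disease subgroups are not separately
parameterized; the pooled movement-disorder values are used for all of
them. The missed-turn artifact (`inject_missed_turn()`) replaces a gap
with a few records at a fixed fraction (default 0.4) of the subject's
mean stride length whose times exactly fill the gap — the signature that
inflates a healthy subject's CoV beyond the physiological range and that
QC must catch.

Deliberately **not** emulated, and therefore not demonstrated by passing
tests:

* stride-to-stride autocorrelation, drift, fatigue or attention effects —
  values are i.i.d. around the subject mean, appropriate for a
  magnitude-of-variability analysis but not for temporal-structure
  metrics;
* between-subject heterogeneity of the *true* CoV within a group: every
  simulated subject of a group shares the group CoV, so the
  between-subject spread of measured CoVs reflects sampling variation
  (plus peri-turn effects) only, and is narrower than in real cohorts.
  Counts of subjects above the 2.6% cut-off are correspondingly
  all-or-nothing at the group level rather than graded;
* curved-path kinematics inside turns, foot laterality, and any raw
  signal processing.

A negative-value guard redraws stride values below 10% of the subject
mean (flooring at that value after 50 attempts, with a warning); it only
engages at CoVs far beyond the physiological range.

## Numerical and statistical notes

* **Small-sample CoV bias.** The sample CoV of an 8-stride segment is
  biased low relative to a 40-stride CoV, because
  $E[s] = c_4(n)\,\sigma$ with $c_4(8) \approx 0.965$ versus
  $c_4(40) \approx 0.994$. The whole-walk CoV therefore sits
  systematically about 0.1 percentage points above the mean of
  per-segment CoVs even with peri-turn perturbation disabled. This is a
  property of the statistic, not an artifact of the generator; tests of
  the pooled-versus-segment contrast bound the unperturbed gap rather
  than asserting exact agreement.
* **Pearson R is computed on untransformed values** (no Fisher z), and
  the self-correlation at $N_{\max}$ is set to exactly 1 rather than
  trusting floating-point `cor(x, x)`.
* **Listwise deletion for ICC**: subjects lacking any segment statistic
  (e.g. a segment with fewer than three strides, which is skipped with a
  warning) are dropped before forming the subjects × segments matrix.
* **Degenerate inputs** raise typed errors rather than returning NaN: CoV
  of fewer than two values or non-positive mean, ICC of an all-equal
  matrix, paired t-test on zero-variance differences, convergence with no
  between-subject variance at $N_{\max}$.
* The cumulative sequence runs over the concatenated post-excision
  strides in onset order; turns contribute no strides and no index.

## Problem sizes

The test suite and the acceptance script work at the study's natural
scale where it is cheap (162 healthy-elderly subjects, 31
movement-disorder subjects, 40-stride windows) and at reduced cohort
sizes (10–30 subjects, 10–30 seeded replicates) for the replicated
property checks, which keeps a full run within a few minutes on one CPU
while leaving every stochastic bound a wide margin: the cross-subject
correlation of a 3-stride cumulative mean with the 40-stride mean, for
instance, is driven by a between-subject SD of ~4.8 %stature against a
within-subject SE of ~1 %stature, putting the expected R near 0.98
against a 0.9 criterion.

## Limitations

The package estimates stride-count requirements *under its generative
model*. Real exports add effects the model omits (autocorrelation, CoV
heterogeneity, disease-specific turning behavior), so the synthetic
required-stride counts should be read as a lower bound sanity check of
the methodology, not as clinical reference values. The ICC's known
deflation under low between-subject variance — poor ICC despite segment
CoV ranges well under half a percentage point — is reproduced by the
package and checked directionally in the tests; it argues for reporting
absolute segment differences alongside ICC whenever within-group spread
is small.
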