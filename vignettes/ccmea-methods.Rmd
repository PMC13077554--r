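---
title: "Mucosal exposure scoring for colonoscopy quality control: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mucosal exposure scoring for colonoscopy quality control: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccmea)
```

## The quality problem and the score

Adenomas missed at colonoscopy are the leading cause of post-colonoscopy
colorectal cancer, and miss rates track how much of the mucosa the
endoscopist actually inspects during withdrawal. Classical quality
indicators (withdrawal time, bowel-preparation scores, the adenoma
detection rate itself) are either indirect or only available after
histology. This package implements a direct, per-frame measure of mucosal
exposure and its per-procedure accumulation:

* **CMEA** (colorectal mucosal exposure area) of one frame is the area of
  clearly exposed mucosa divided by the area of the endoscopic field of
  view, a dimensionless ratio in $[0, 1]$. Regions obscured by specular
  reflection, fecal material/occlusion, instruments or excessive darkness
  do not count as exposed mucosa. Using the segmented field of view as
  the denominator removes the bias of different scope vendors masking
  different portions of the video frame, and makes the ratio independent
  of pixel scale.
* **CCMEA** is the sum of CMEA over all *qualified* frames of the
  withdrawal. Frames that are out of the patient, blurred, or otherwise
  uninformative contribute nothing, and chromoendoscopy (dye-spray)
  segments *suspend* accumulation entirely, because dye imaging is used
  for lesion characterization rather than search.

A procedure with CCMEA at or above a calibrated threshold (2000 at the
calibration frame rate; ties qualify) is called a *qualified
colonoscopy*. Because CCMEA is a sum over frames, its magnitude scales
with the sampling rate: a threshold calibrated at one frame rate is not
transferable to another, so every `procedure_record` stores its
`sampling_rate` and the package treats the rate as mandatory bookkeeping
rather than guessing it.

## Pipeline stages and their baselines

The deployed system this package models uses three neural networks:
a frame-quality classifier, an exposed-mucosa segmenter and a
field-of-view segmenter. Trained weights are not distributable, so each
stage here is a *contract* with a deterministic baseline behind it:

1. **Frame QC** (`classify_frame`): routes each frame to one of
   `qualified`, `in_vitro`, `blurred`, `flushing`, `instrument`,
   `operation`, `chromoendoscopy`. The heuristic baseline decides by
   mean luminance (dark in-vitro frames), hue coverage (blue dye tint),
   and a Laplacian-energy sharpness score whose value can only decrease
   under additional Gaussian blur. The baseline cannot see flushing,
   instrument or operation frames (they are not visually constructable
   without clinical footage); those labels remain in the taxonomy for
   richer backends, and accumulation bookkeeping collapses them into
   "other unqualified" anyway. An `oracle` backend returns the
   generator's ground-truth label, so every downstream stage can be
   tested under perfect frame filtering.
2. **View segmentation** (`segment_view`): luminance threshold above the
   near-black surround, largest connected component, hole filling,
   convex closure. An all-black frame raises an explicit empty-view
   error and the caller treats the frame as unqualified.
3. **Exposure segmentation** (`segment_exposure`): inside the view,
   removes specular pixels (bright, unsaturated), dark pixels, fecal /
   occlusion pixels (brown hue band with high saturation) and
   instrument-grey pixels, then applies a small-disc morphological
   opening. The result is a subset of the view by construction.
4. **Accumulation** (`accumulate`): a constant-size streaming fold over
   the frame sequence; only the optional per-frame log grows with the
   stream.

All color thresholds live in `qc_config()` / `seg_config()`, not in the
logic; the defaults were chosen on fixed-seed synthetic fixtures by
maximizing agreement with generator labels, and every run's
configuration is inspectable from the objects it returns.

Segmenter quality is judged with the Dice coefficient
$2|A \cap B| / (|A| + |B|)$ and mean IoU. Two conventions for "mean IoU"
circulate — mean foreground IoU over images, or the average of
foreground and background IoU — and reports rarely say which. The
package defaults to the per-image foreground mean (the common reading
when quoted alongside Dice) and offers the class-averaged variant via
`seg_config(miou_average = "class")`. Two empty masks compare as Dice 1
(perfect agreement on absence), reported via a message, which avoids an
undefined $0/0$ and matches common toolkit behavior.

## The synthetic-data module

No endoscopy video or patient table ships with the package; the
synthetic module generates both, with exact ground truth, so the whole
pipeline is testable offline.

**Phantom frames** (`generate_frame`) are a bright textured disk
(mucosa-pink, low-frequency multiplicative texture) on a near-black
surround, with artifact patches placed as random disks strictly inside
the view up to per-class area budgets: specular (white, unsaturated),
fecal (brown), dark (low luminance, but above the view floor so
darkness does not carve the view), instrument (grey). Chromoendoscopy
is rendered as a global blue tint, detectable by hue statistics; blur
is a global Gaussian. Ground-truth masks are recorded *before*
blurring, so they are exact pixel sets, and rendering is a pure
function of the spec (fixed seed, bit-identical output). Phantoms
reproduce the *taxonomy* of obscured regions, not the photometric
statistics of real endoscopy: passing tests demonstrate the pipeline's
arithmetic, contracts and invariances, not clinical segmentation
performance. The published performance of the trained segmenters
(Dice 0.93, mean IoU 0.87 for exposure; 0.99 for the view) is not
reproducible without their weights and data, and the package makes no
claim to it.

**Synthetic cohorts** (`generate_cohort`) draw per-patient CCMEA from a
gamma distribution (shape 2, scale 1150) — positive, right-skewed, and
spanning several 1000-wide bins, as the binned calibration procedure
requires. Adenoma presence follows a logistic model on the logit scale
with a gamma-anchored linear CCMEA term, sex and indication effects,
and a Gaussian healthcare-center random intercept; covariate marginals
(47% male; indication 21.8/62.0/16.2%) follow the prospective study's
baseline table. Defaults anchor the marginal ADR curve to cross the
25% screening benchmark at CCMEA ≈ 1700. The anchor is deliberately
placed *inside* the $[1000, 2000)$ bin rather than at the 2000 edge: a
crossing exactly at a bin edge would make the selected threshold an
unstable coin flip under sampling noise, whereas an interior crossing
makes 2000 the modal selected threshold (93% of replicates at the
calibration-set size of 716). With these defaults the qualified /
unqualified group rates approximate the prospective study's outcome
table (ADR ≈ 58% vs 17% against 53.7/14.2; mean polyps 6.1 vs 1.4
against 5.8/1.3).

Lesion counts are built so the orderings
`polyp_count >= adenoma_count >= 1{adenoma}` hold by construction:
positive patients carry $1 + \mathrm{Poisson}$ extra adenomas and an
independent negative-binomial count of non-adenomatous polyps, both
with mean rates linear in CCMEA (linear rather than log-linear so the
gamma tail cannot produce runaway counts). The negative binomial (size
0.35) is needed because real polyp counts are strongly overdispersed —
a pure Poisson with the unqualified group's mean of 1.3 would force a
polyp detection rate above 73%, far from the observed 40% — but even
so the generator only partly emulates that zero-inflation (synthetic
PDR ≈ 82/45% vs 89.6/40.0). Per-lesion sizes are log-normal
(median ≈ 3 mm) with small probabilities of high-grade dysplasia and
villous histology feeding the advanced-adenoma definition (≥10 mm, or
high-grade, or villous).

`generate_grouped_cohort` is a separate, simpler harness for
mixed-model validation: a binary group carries a specified log odds
ratio and log incidence-rate ratio with a center random intercept, and
sex/indication are drawn as pure noise covariates.

## Threshold calibration

`bin_by_ccmea` groups patients into half-open 1000-wide intervals (a
CCMEA of exactly 2000 belongs to $[2000, 3000)$). `fit_adr_curve` fits
the three-parameter saturating logistic
$\mathrm{ADR}(c) = L / (1 + e^{-k(c - c_0)})$ to bin midpoints weighted
by bin size. The curve family is a modelling choice: ADR is a bounded,
increasing dose-response in cumulative exposure, and this is the
minimal such family; when the Levenberg–Marquardt fit fails the code
falls back to weighted isotonic regression and flags it, and
identical-ADR bins give a flagged constant curve. `select_threshold`
returns the smallest multiple of the bin width at and beyond which the
*fitted* curve exceeds the target (default 25%). Applying the criterion
to the fitted curve rather than raw bin ADRs is deliberate — raw bins
are non-monotone under noise — and a raw-bin mode is available via
`use_fitted = FALSE`. Thresholds are restricted to bin-width multiples
on purpose: the calibration procedure reads a round number off a binned
curve, and finer granularity would over-read the fit. If the curve
never reaches the target the result is an explicit
"no qualifying threshold", never a silent maximum.

## Cohort analysis

`compare_groups` reproduces the prospective study's analysis surface:
11 outcomes (ADR; adenoma detection by diminutive ≤5 mm, small >5 to
<10 mm, large ≥10 mm; advanced adenomas; polyp detection overall and by
the same size classes; mean adenoma and polyp counts), each with group
rates or means, an absolute difference, a ratio, and a significance
flag at the Bonferroni-adjusted level $\alpha / 11 = 0.0045$.

Method choices where the convention was open:

* **Rate-difference CIs** use the Newcombe hybrid score method
  (square-and-add of Wilson intervals). Published intervals of this
  kind are asymmetric, which Wald intervals cannot produce; a Wald
  option exists. Point estimates are method-independent, and printed
  percentages use half-away-from-zero rounding, the convention of
  clinical tables (1.25% prints as 1.3).
* **Adjusted ratios** come from generalized linear mixed models with a
  center random intercept — logit link for binary outcomes (adjusted
  odds ratios) and Poisson log link for counts (adjusted incidence-rate
  ratios), adjusting for sex and indication — fitted with `lme4::glmer`
  and reported with Wald intervals. Non-convergence falls back to a
  flagged fixed-effects fit, never a silent answer. Poisson is retained
  for counts because it is the standard analysis despite visible
  overdispersion in such data; the count *generator* is negative
  binomial precisely so this mismatch is represented honestly.
  Adjusted ratios on the real study are not reproducible (per-patient
  covariates are unpublished); the package's validation surface for
  them is parameter recovery on synthetic cohorts, where 95% CIs cover
  generating effects of $\log 8$ (logit) and $\log 4$ (Poisson) in
  well over 90% of replicates at $n = 510$ with 3 centers.
* **Power** (`power_two_proportions`) uses the two-sided normal
  approximation with unpooled variance; at the design rates (33% vs
  23%, $\alpha = 0.05$, 247 per group) it gives ≈70%, consistent with
  the ~74% a commercial exact routine reports for the same design. A
  Monte-Carlo harness in the test suite checks the approximation
  against simulated two-proportion tests.

`apply_exclusions` performs the enrolment-flowchart accounting
(screened − per-reason exclusions = analysis set) and refuses
contradictory flags.

## Numerical and degenerate-input conventions

* All generators are pure functions of their spec and seed; the RNG
  state of the caller is saved and restored.
* Oracle-pipeline equivalence is *exact*: the generator's analytic
  CCMEA is computed with the same sequential double-precision addition
  as the streaming accumulator, so the test can assert identity rather
  than closeness.
* Empty frame streams score 0 and are unqualified; empty view masks are
  errors at `cmea` but demote the frame to unqualified inside
  `accumulate`; a CCMEA exactly at threshold is qualified.
* Zero cells in 2×2 tables get the Haldane–Anscombe 0.5 correction; two
  zero cells sharing a margin are an error.
* Masks are `(row, column)` logical matrices; areas are pixel counts;
  no physical units anywhere (the ratio cancels them).

## Problem sizes used in the shipped checks

The test-suite and acceptance-script experiments run at the sizes the
corresponding procedures were designed around: calibration cohorts of
716 patients (20 replicates) for threshold recovery, $n = 510$ with 3
centers (50 replicates) for mixed-model coverage, 100 generated
procedures of up to ~20 frames at 48–128 px for oracle equivalence, and
1000 fuzzed 10×10 mask pairs for metric exactness. Phantom sizes only
scale pixel counts — every contract they exercise is
resolution-independent.

## Known limitations

* Baseline classifiers/segmenters are color-rule systems tuned to the
  phantom renderer; on real endoscopy they are a starting point, not a
  result. The backend contracts are the extension point.
* Withdrawal-phase detection, cecal-intubation recognition and
  bowel-preparation scoring are out of scope; the scorer assumes its
  input is the withdrawal segment (an optional frame window stands in).
* Chromoendoscopy re-entry semantics are simple suspension: qualified
  frames after a dye segment resume accumulation immediately.
* The 2000 threshold is only meaningful at the frame rate it was
  calibrated at; re-calibrate (`calibrate_threshold`) for any other
  sampling regime.
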