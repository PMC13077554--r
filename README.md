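# ccmea — cumulative mucosal exposure scoring for colonoscopy quality control

Adenomas missed during colonoscopy are the main driver of
post-colonoscopy colorectal cancer, and whether they are missed depends
on how much of the colorectal mucosa the endoscopist actually exposes
and inspects during withdrawal. `ccmea` implements a quantitative
quality indicator for exactly that:

* **CMEA** — per frame, the area of clearly exposed mucosa divided by
  the area of the endoscopic field of view,
  `CMEA = area(exposure) / area(view) ∈ [0, 1]`. Regions obscured by
  specular reflection, fecal material, occlusion or darkness do not
  count as exposed.
* **CCMEA** — per procedure, the sum of CMEA over all *qualified*
  withdrawal frames. Unqualified frames (out-of-body, blurred,
  flushing, instrument, operation) contribute nothing and
  chromoendoscopy suspends accumulation. A withdrawal with
  `CCMEA ≥ 2000` (at the calibration frame rate) is a *qualified
  colonoscopy*; the threshold is calibrated so the fitted adenoma
  detection rate (ADR) over 1000-wide CCMEA bins stays above the 25%
  screening benchmark.

The package covers the full pipeline for whoever wants to study or
extend such an indicator without clinical data or trained networks:
deterministic baseline frame QC and segmenters behind pluggable backend
contracts, Dice / mean-IoU mask evaluation, streaming CCMEA
accumulation, ADR-based threshold calibration (weighted logistic fit
with isotonic fallback), and the prospective-study outcome analysis —
detection rates, Newcombe score intervals for rate differences,
mixed-model adjusted odds/incidence-rate ratios (`lme4`), Bonferroni
correction at `0.05/11`, and two-proportion power. A synthetic-data
module generates endoscopy-like phantom frames with exact ground-truth
masks and multi-center cohorts with a known CCMEA→outcome generative
model, so every stage is testable end to end.

## Worked example

```r
library(ccmea)

# a synthetic withdrawal: 45 qualified frames with artifacts, a
# chromoendoscopy segment, and a few blurred frames
proc <- generate_procedure(
  60,
  data.frame(class = c("qualified", "chromoendoscopy", "qualified", "blurred"),
             n = c(30, 10, 15, 5)),
  frame_phantom_spec(seed = 4, specular = 0.08, fecal = 0.05, dark = 0.04),
  jitter_artifacts = TRUE)

# score it with the baseline classifier + segmenters
rec <- accumulate(proc$frames, threshold = 40)
rec
#> Procedure procedure: CCMEA 40.58 over 60 frames (45 qualified, 10 chromoendoscopy, 5 other unqualified) at 25 fps
#> qualified colonoscopy (CCMEA >= 40): TRUE
round(proc$ccmea_truth, 2)  # generator's analytic CCMEA
#> 40.63

# calibrate the qualified-colonoscopy threshold on a synthetic cohort
coh <- generate_cohort(cohort_gen_spec(n_patients = 2000, seed = 3))
calibrate_threshold(coh)
#> Qualified-colonoscopy threshold: CCMEA >= 2000 (fitted ADR above 25% target; logistic curve)

# published-table arithmetic: ADR 145/270 vs 34/240
detection_rate(145, n = 270)
#> 145 / 270 = 53.7%
rate_difference(145, 270, 34, 240)
#> 39.5 percentage points (95%CI 31.8 to 46.5)
```

The baseline pipeline's CCMEA (40.58) sits within a fraction of a frame
of the generator's analytic truth (40.63); with the truth-oracle
backend the two are identical to the last bit. The 39.5-point ADR
difference and its score interval reproduce the published comparison of
qualified vs unqualified procedures.

A command-line front end with verbs `score`, `calibrate`, `compare`,
`simulate` and `evaluate` is installed at
`system.file("exec", "ccmea", package = "ccmea")`; e.g.

```sh
CLI=$(Rscript -e 'cat(system.file("exec","ccmea",package="ccmea"))')
Rscript "$CLI" simulate frames frames/ --n 50 --seed 7
Rscript "$CLI" score frames/ --threshold 2000 --log per_frame.csv
```

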