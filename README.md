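# sacchoice

Simulation and analysis of two-alternative **saccadic-choice
experiments**: paradigms in which two images appear left and right of
fixation and the subject's task is to saccade to the target category
(e.g. a familiar face among unknown faces, or a face among objects).
The package is aimed at visual-psychophysics and eye-movement
researchers who want a tested, reproducible version of the standard
analysis chain for such experiments — and a generative simulator to
validate every stage against planted ground truth.

## What it implements

* **Balanced design generation** — 6 blocks per subject (one per
  ordered target/distractor category pair), 162 trials per block
  (9 target images × 9 distractor images × 2 hemifields, each exactly
  once), seeded randomization.
* **1000 Hz gaze simulation** — logistic saccade kinematics with
  main-sequence durations, shifted log-normal latencies per task,
  latency-dependent direction errors, fixational drift + tracker
  noise, planted anticipations and fixation breaks.
* **Stimulus normalization** — affine luminance/contrast matching:
  `clip(m + (x - mean(x)) * s / sd(x), 0, 255)` with targets
  m = 128, s = 40 pixel-intensity units.
* **Offline saccade detection** — direction from the first
  image-border crossing of the x-coordinate; candidate onsets where
  2-D speed exceeds 3 baseline SDs (200 ms blank baseline); onset at
  the candidate where the sign of dx/dt last changed and then stayed
  constant to the crossing; rejection of anticipations (onset
  < 80 ms), fixation breaks, and saccade-free trials.
* **Minimum reliably accurate SRT** — saccadic reaction times in
  10 ms left-inclusive bins; per-bin Monte Carlo chi-square test
  (2000 replications) of correct vs incorrect counts against 50/50;
  the minimum SRT is the first bin of the first run of ≥5 consecutive
  bins with p < .05 and correct > incorrect.
* **Mixed-effects inference** — logit mixed models on accuracy and
  linear mixed models on log SRT (lme4), with likelihood-ratio
  selection of the random-effect structure, Type III analysis of
  deviance (car), no-intercept reparameterization with
  reference-level switching, and parametric-bootstrap 95% CIs.

## Worked example

Two blocks of one simulated subject, end to end (this subject's first
two blocks happen to be the unknown-vs-familiar-face task and the
familiar-face-vs-object task):

```r
library(sacchoice)

design <- build_design(1, seed = 2)
design$trials <- design$trials[design$trials$block %in% 1:2, ]
ds  <- simulate_experiment(design, seed = 3)   # 324 gaze traces
res <- detect_all(ds)
table(res$status)
#>              accepted rejected_anticipation     rejected_fixation
#>                   299                    17                     8

acc <- res[res$status == "accepted", ]
minimum_srt(acc[acc$task == "FamiliarFace_vs_Object", ], seed = 4)
#> Minimum reliably accurate SRT: 130 ms
#>    9 of 24 bins significant at alpha = 0.05 (run length 5 )
minimum_srt(acc[acc$task == "UnknownFace_vs_FamiliarFace", ], seed = 4)
#> Minimum reliably accurate SRT: none (no run of significant bins)
#>    0 of 25 bins significant at alpha = 0.05 (run length 5 )

summarize_conditions(acc, chance_tasks = "UnknownFace_vs_FamiliarFace")
#>                          task target_position   n accuracy mean_srt
#> 1      FamiliarFace_vs_Object         overall 150 92.00000 173.5072
#> 2      FamiliarFace_vs_Object            left  73 91.78082 182.2836
#> 3      FamiliarFace_vs_Object           right  77 92.20779 165.2254
#> 4 UnknownFace_vs_FamiliarFace         overall 149 49.66443       NA
#> 5 UnknownFace_vs_FamiliarFace            left  76 47.36842       NA
#> 6 UnknownFace_vs_FamiliarFace           right  73 52.05479       NA
```

Reading it: ~6% of trials were rejected by the anticipation and
fixation filters (both artifact types are planted by the simulator at
3%). Saccades to a familiar face among objects are reliably accurate
from the 130 ms latency bin on and 92% accurate overall, while
saccades to an unknown face among familiar faces stay at chance — so
no minimum SRT exists and the mean SRT is suppressed.
`fit_accuracy_model()` / `fit_rt_model()` then run the mixed-model
workflow on the same accepted-trials table; see
`vignettes/saccadic-choice-analysis.Rmd` for the statistical details
and modelling choices.

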