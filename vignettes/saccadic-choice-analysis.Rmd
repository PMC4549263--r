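---
title: "Methods: simulating and analysing saccadic-choice experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing saccadic-choice experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sacchoice)
```

# The task and the pipeline

In a saccadic-choice experiment two images appear simultaneously left
and right of fixation and the subject is asked to saccade as fast as
possible to the image of the target category. The scientific questions
are about *latency*: how early after stimulus onset are eye movements
reliably directed at the target, and how do accuracy and saccadic
reaction time (SRT) depend on the task (which category is the target,
which the distractor)?

`sacchoice` implements the full analysis chain for such experiments,
plus a generative simulator so that every stage can be validated
against planted ground truth:

1. **Design generation** (`build_design()`): a balanced design with 6
   blocks per subject — one per ordered (target category, distractor
   category) pair over the categories *familiar face*, *unknown face*,
   *object* — and 162 trials per block: 9 target images x 9 distractor
   images x 2 target hemifields, each combination exactly once, in a
   seeded random order. Each image therefore appears 18 times per
   block, and half of the trials have the target on the left.
2. **Gaze simulation** (`simulate_trial()`, `simulate_experiment()`):
   1000 Hz traces with planted saccade onsets, directions and
   artifacts.
3. **Stimulus normalization** (`lum_match()`, `match_set()`): affine
   equalization of mean luminance and contrast across images.
4. **Saccade detection** (`detect_all()` and friends): velocity
   thresholding against a blank-period baseline, a derivative-sign
   onset rule, border-crossing direction assignment, and rejection
   filters for anticipations and fixation breaks.
5. **Minimum-SRT estimation** (`minimum_srt()`): 10 ms latency bins,
   per-bin Monte Carlo chi-square tests, and a five-consecutive-bins
   rule.
6. **Mixed-effects inference** (`fit_accuracy_model()`,
   `fit_rt_model()`): logit models on trial correctness and linear
   models on log SRT with crossed random effects, likelihood-ratio
   selection of the random structure, Type III analysis of deviance,
   no-intercept reparameterization, and parametric-bootstrap CIs.

# The gaze simulator

## Geometry

The simulated rig is an 800x600 px display at 50 cm, image centres at
8.6 degrees of eccentricity, images subtending 14x14 degrees. The
physical monitor size — and hence the pixels-per-degree factor — is a
free parameter: `display_geometry(px_per_deg = 25)` by default, which
puts the outer image edge (15.6 deg) at 390 px from centre, just
inside the display. All degree-valued parameters are converted through
this single factor.

## Trial kinematics

A trace covers the 200 ms blank before stimulus onset (the velocity
baseline) and the 400 ms stimulus window at a 1 ms step. The eye holds
fixation until the planted onset, then translates horizontally to the
chosen image centre along a logistic displacement profile, normalized
so displacement is exactly zero before the onset and exactly the 8.6
deg amplitude at the end of the movement. The logistic profile was
chosen because it is smooth, strictly monotone, and gives the
x-derivative a single sign change at the movement start — the
assumptions the onset detector exploits. Saccade duration follows a
main-sequence-like rule, 21 ms + 2.2 ms/deg, i.e. ~40 ms for the 8.6
deg movement, inside the 30–60 ms range typical of human saccades of
this size.

## Latency, errors, noise

Latencies are drawn per task from a shifted log-normal
(`latency_lognormal(mean, sd = 35, shift = 80)`): right-skewed, like
empirical SRT distributions, with support above the 80 ms
stimulus-driven floor. `reference_condition_params()` supplies per-task
accuracies and mean SRTs matching the reference experiment's condition
table; the latency SD (35 ms) and the mean SRT of the
unknown-vs-familiar task (195 ms), which the reference does not
report, are package choices. Direction errors (saccades to the
distractor) occur with a per-task probability that may depend on
latency (`error_constant()`, `error_step()` — the latter plants an
accuracy crossover for validating the minimum-SRT estimator).

Noise has two components per coordinate (`noise_model()`):

* **fixational drift** — a mean-reverting AR(1) process with
  stationary SD 0.15 deg and an RMS drift velocity of 1 deg/s
  (physiological drift runs at roughly 0.5–2 deg/s; the lag-1
  correlation is derived from the speed, not set directly);
* **measurement noise** — white, SD 0.01 deg per sample, the order of
  a tower-mounted 1000 Hz video tracker's RMS noise after its
  on-board filtering.

What the generator deliberately does *not* emulate: blinks and pupil
artifacts, vertical or oblique saccades, secondary/corrective
saccades, calibration drift, and saccadic curvature. Passing the
recovery tests therefore shows the algorithms are correct under clean,
single-saccade kinematics with realistic noise levels — not that they
are robust to every pathology of real recordings.

Artifacts that the rejection filters must catch are planted
explicitly (`artifact_model()`): anticipatory saccades (onset uniform
in [30, 79] ms) with probability 3% and fixation breaks (a 3 deg
vertical drift completed 60 ms after onset) with probability 3%,
together of the order of the ~6% rejection rate reported for this
paradigm.

# Stimulus luminance matching

`lum_match()` forces each grayscale image to a target mean pixel
intensity (128) and SD (40) by the affine map
$y = \bar{t} + (x - \bar{x})\,s_t/s_x$, clipping to [0, 255]
*afterwards*. When nothing clips the achieved moments are exact; under
clipping they deviate slightly and `match_set()` reports the achieved
values per image. A zero-variance image cannot attain a positive
target contrast; it is returned constant at the target mean with a
warning. Matching is applied to the full frame; restricting it to a
foreground mask is possible by matching a sub-matrix, but the default
treats the whole image, background included.

# Saccade detection

`compute_velocity()` is the 2-D point-to-point speed (Euclidean
displacement per 1 ms sample), assigned to the later sample of each
pair. The detector then proceeds in the order the offline algorithm
prescribes:

1. **Direction** comes from the first sample at or after stimulus
   onset whose x-coordinate reaches an inner image border. The border
   default is eccentricity minus half the image width (8.6 − 7 = 1.6
   deg from centre); which edge of the image counts as "the border"
   is configurable via `border_offset_deg`.
2. **Candidate onsets** are post-onset samples whose speed exceeds
   `velocity_sigma` (default 3) times the SD of the baseline speed
   over the 200 ms blank. The SD is taken about the baseline mean — a
   dispersion criterion — not about zero.
3. **The onset** is the candidate at which the sign of the first
   derivative of x last changed and then remained constant up to the
   border crossing. The derivative-sign rule is applied to the
   x-coordinate (direction is defined on x); if the trace is monotone
   after onset there is no sign change and the rule degenerates to
   the first supra-threshold candidate. If the sign-change sample
   itself is below threshold, the first candidate after it is taken.

Rejection filters, in order of precedence: traces with missing
samples; onsets earlier than 80 ms (anticipations — the boundary is
left-closed: an onset of exactly 80 ms is accepted, "before 80 ms" is
not); trials where gaze leaves a 2 deg radius (configurable; the
criterion's radius is a package choice) around the centre within the
first 80 ms after stimulus onset; trials with no detectable saccade.

Numerical notes: aligning velocities to the later sample means a
noiseless step at time $t$ is detected at $t + 1$ ms, a one-sample
systematic offset well inside the ±5 ms recovery tolerance used in
validation. The baseline SD of a noiseless trace is 0, so any positive
speed is then supra-threshold.

# Minimum reliably accurate SRT

SRTs are assigned to 10 ms left-inclusive bins centred on multiples of
10 (`bin_srt()`: the 120 ms bin covers 115–124 ms). For each bin from
the 80 ms floor to the last bin with data, a chi-square
goodness-of-fit statistic against a 50/50 split of correct versus
incorrect saccades is referred to a Monte Carlo null (2000 binomial
replications by default) with the add-one estimator
$p = (1 + \#\{T^\ast \ge T\})/(B + 1)$, which cannot return 0. A bin
is *significant* only if $p < .05$ **and** correct counts exceed
incorrect counts — the chi-square is two-sided, and a bin reliably
*wrong* must not count as reliably accurate. Empty bins are
non-significant and break runs. The minimum SRT is the centre of the
first bin of the first run of at least five consecutive significant
bins (`run_length = 5`; runs longer than five qualify), or undefined
when no such run exists — as happens for a task whose accuracy never
exceeds chance.

Condition summaries (`summarize_conditions()`) report percent
accuracy and mean SRT per task and hemifield; the mean SRT uses
correct trials only by default (consistent with the RT model's use of
correct trials; configurable) and is suppressed for tasks flagged as
at-chance by the inference stage.

# Mixed-effects inference

Both analyses share fixed effects: task, target position, their
interaction, and the trial number standardized to zero mean and unit
SD (z-scoring, rather than centring alone, keeps the design matrix
well conditioned; the raw 1–972 covariate produces extreme
eigenvalues that impede convergence).

**Random-effect selection.** Two candidate structures with equal
parameter counts are fitted by ML: fully crossed intercepts (subject,
target item, distractor item) versus subject plus subject-by-target
and subject-by-distractor combinations. The higher log-likelihood
wins; exact ties go to the first candidate. Each retained effect is
then tested by a likelihood-ratio test of the full against the
reduced model on a naive $\chi^2_1$ reference — the convention in
which such tests are usually reported, although the null variance sits
on the boundary of its parameter space; `boundary_mixture = TRUE`
applies the 50:50 mixture correction, which halves the p-values.

**Fixed effects.** Type III analysis of deviance (Wald chi-square
tests with sum-to-zero contrasts, via `car::Anova`) for task,
position, interaction and trial number. The model is then refitted
*without* intercept, so each task's coefficient is its log-odds of a
correct saccade (accuracy model) or its mean log SRT (RT model) in
the reference hemifield, and refitted again with the other hemifield
as reference to obtain per-hemifield estimates. On the accuracy
model's log-odds scale, 0 is chance: a task is above chance exactly
when its bootstrap CI excludes 0.

**The RT model** uses correct trials only, excludes any task found at
chance (there is no meaningful "reaction time of a correct saccade"
when correctness is a coin flip), and models log SRT to absorb the
right skew; estimates are reported exponentiated as well (ms for task
cells, multiplicative ratios for contrasts). Model comparisons use
ML; final estimates use REML.

**Parametric bootstrap.** `parametric_bootstrap_ci()` simulates
response vectors from the fitted model's own estimates, refits, and
takes percentile intervals (95% default; 1,000 replicates default,
10,000 recommended for final reported intervals). Replicates whose
refit fails are dropped and counted; more than 10% failures aborts
with an error rather than silently reporting intervals from a
truncated sample. Identical seeds give identical intervals.

Numerical choices: the lme4 fits skip the optional post-fit
derivative check (`calc.derivs = FALSE`) — model adequacy is judged
here by likelihood comparisons and the bootstrap, and the derivative
pass would dominate the cost of bootstrap refitting; singular-fit
messages are suppressed (boundary fits are legitimate outcomes for
null variance components, and the LRT handles them). Non-convergence
of a candidate fit falls through `tryCatch` and is reported rather
than masked.

# Validation scale

The test suite validates each stage against independent oracles
(exhaustive scans for the onset rule, exact binomial tests for the
Monte Carlo chi-square, planted generative parameters for recovery)
at sizes chosen to keep the full suite at desk scale: onset recovery
on a 500-trial battery at default noise, minimum-SRT recovery over
100 seeded replicates of 800 trials, bootstrap coverage over 300
replicates at 150 bootstrap draws each, and Monte Carlo convergence
checks at 200,000 replications. These sizes give Monte Carlo standard
errors comfortably below the margins being asserted (e.g. a coverage
check of 95% ± 3 points has an MC standard error of ~1.3 points at
300 replicates).

# Known limitations

* The simulator plants one horizontal saccade per trial; express
  corrective sequences, blinks, and vertical components are out of
  scope, so rejection-filter behaviour on such events is untested.
* The derivative-sign onset rule is applied to the x-coordinate; an
  alternative reading applies it to the speed signal. The choice
  matters only when vertical noise dominates near onset; with the
  package's geometry both readings give the same onsets on clean
  traces.
* Whether the run of significant bins must be exactly five or at
  least five is ambiguous in the field's verbal definition; the
  package requires *at least* five.
* The per-bin Monte Carlo tests are not corrected for multiplicity
  across bins beyond the consecutive-run requirement itself.
* Accuracy cells at 0% or 100% (complete separation) make logit
  coefficients diverge; the fitter flags such cells instead of
  pretending the estimates are finite.
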