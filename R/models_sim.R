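# Generative models used by the gaze simulator: saccade latency,
# direction-error probability, and fixation/measurement noise.

#' Shifted log-normal saccade latency model
#'
#' Latencies are `shift + X` with `X` log-normal, parameterized by the
#' desired mean and SD of the full latency so condition tables can be
#' plugged in directly. The shift (default 80 ms) reflects the minimal
#' afferent+efferent delay below which saccades cannot be stimulus
#' driven.
#'
#' @param mean desired mean latency, ms (must exceed `shift`).
#' @param sd desired latency SD, ms.
#' @param shift lower bound of the support, ms.
#' @return A latency model (list with a `sample(n)` function).
#' @export
latency_lognormal <- function(mean, sd = 35, shift = 80) {
  stopifnot(mean > shift, sd > 0)
  mu <- mean - shift
  sdlog <- sqrt(log(1 + (sd / mu)^2))
  meanlog <- log(mu) - sdlog^2 / 2
  structure(list(name = "shifted_lognormal",
                 mean = mean, sd = sd, shift = shift,
                 sample = function(n)
                   shift + stats::rlnorm(n, meanlog, sdlog)),
            class = "latency_model")
}

#' Truncated normal saccade latency model
#'
#' Normal latencies truncated below at `min` ms (rejection sampling).
#'
#' @param mean,sd normal parameters, ms.
#' @param min truncation point, ms.
#' @return A latency model (list with a `sample(n)` function).
#' @export
latency_truncnorm <- function(mean, sd, min = 80) {
  stopifnot(sd > 0)
  structure(list(name = "truncated_normal",
                 mean = mean, sd = sd, shift = min,
                 sample = function(n) {
                   x <- stats::rnorm(n, mean, sd)
                   while (any(bad <- x < min))
                     x[bad] <- stats::rnorm(sum(bad), mean, sd)
                   x
                 }),
            class = "latency_model")
}

#' Constant direction-error model
#'
#' The probability that the planted saccade goes to the distractor is
#' the same at every latency.
#'
#' @param p probability of an incorrect (distractor-directed) saccade.
#' @return An error model (function of latency).
#' @export
error_constant <- function(p) {
  stopifnot(p >= 0, p <= 1)
  structure(function(latency) rep(p, length(latency)),
            class = "error_model", name = "constant", p = p)
}

#' Step (crossover) direction-error model
#'
#' Saccades launched before `threshold` ms are correct with probability
#' `p_before` correct-rate (passed as error probabilities); from
#' `threshold` on the error rate drops to `p_after`. Used to plant a
#' known accuracy crossover for testing minimum-SRT estimation.
#'
#' @param p_before error probability for latencies below `threshold`.
#' @param p_after error probability at or above `threshold`.
#' @param threshold crossover latency, ms.
#' @return An error model (function of latency).
#' @export
error_step <- function(p_before = 0.5, p_after = 0.1, threshold = 175) {
  structure(function(latency) ifelse(latency < threshold, p_before, p_after),
            class = "error_model", name = "step")
}

#' Gaze noise model
#'
#' Two additive components on each coordinate: slow fixational drift
#' and white measurement noise. The drift is a mean-reverting AR(1)
#' process whose stationary SD is `jitter_sd_deg` (how far the eye
#' wanders from the fixation point) and whose per-sample step size is
#' set by `drift_speed_deg_s`, the typical drift velocity (ocular
#' drift runs at roughly 0.5--2 deg/s; 1 deg/s default). The
#' measurement noise is white with per-sample SD `measurement_sd_deg`,
#' emulating video-tracker RMS noise (~0.01 deg for a tower-mounted
#' 1000 Hz tracker). Set all SDs to 0 for noiseless traces.
#'
#' @param jitter_sd_deg stationary SD of the fixational drift, degrees.
#' @param drift_speed_deg_s RMS drift velocity, degrees per second.
#' @param measurement_sd_deg SD of the white measurement noise, degrees.
#' @return A noise model (list); the implied lag-1 autocorrelation of
#'   the drift is stored as `jitter_ar`.
#' @export
noise_model <- function(jitter_sd_deg = 0.15, drift_speed_deg_s = 1,
                        measurement_sd_deg = 0.01) {
  stopifnot(jitter_sd_deg >= 0, measurement_sd_deg >= 0,
            drift_speed_deg_s >= 0)
  # AR(1) with stationary SD s and innovation SD matching the drift
  # step per 1 ms sample: step_sd = s * sqrt(2 * (1 - rho))
  ar <- if (jitter_sd_deg == 0 || drift_speed_deg_s == 0) 0 else {
    step <- drift_speed_deg_s / 1000
    max(0, 1 - (step / jitter_sd_deg)^2 / 2)
  }
  structure(list(jitter_sd_deg = jitter_sd_deg,
                 drift_speed_deg_s = drift_speed_deg_s,
                 jitter_ar = ar,
                 measurement_sd_deg = measurement_sd_deg),
            class = "noise_model")
}

#' Artifact model: anticipations and fixation breaks
#'
#' With probability `p_anticipation` a trial's saccade is launched at a
#' uniform latency in [30, 79] ms (too fast to be stimulus driven);
#' with probability `p_fixation_break` the eye drifts 3 degrees
#' vertically away from fixation during the first tens of ms after
#' stimulus onset. Both exist to exercise the trial-rejection filters.
#'
#' @param p_anticipation probability of an anticipatory saccade.
#' @param p_fixation_break probability of a fixation break.
#' @return An artifact model (list).
#' @export
artifact_model <- function(p_anticipation = 0.03, p_fixation_break = 0.03) {
  stopifnot(p_anticipation >= 0, p_fixation_break >= 0,
            p_anticipation + p_fixation_break <= 1)
  structure(list(p_anticipation = p_anticipation,
                 p_fixation_break = p_fixation_break),
            class = "artifact_model")
}

#' Per-task generative parameters of the reference experiment
#'
#' Returns, for each of the six tasks, the accuracy and mean correct
#' saccadic reaction time of the reference experiment (familiar face
#' vs. object 92.72% / 172 ms; object vs. familiar face 85.59% /
#' 216 ms; unknown face vs. object 92.77% / 171 ms; object vs. unknown
#' face 86.21% / 200 ms; familiar vs. unknown face 61.81% / 191 ms;
#' unknown vs. familiar face 55.28%, mean RT not reported — 195 ms is
#' assumed). Latency SD is not reported; 35 ms is used for every task.
#'
#' @param srt_sd latency SD in ms applied to all tasks.
#' @return Named list (one element per task) of lists with `accuracy`,
#'   `latency` (a latency model) and `error` (an error model).
#' @export
reference_condition_params <- function(srt_sd = 35) {
  tab <- list(
    FamiliarFace_vs_Object      = c(acc = 0.9272, srt = 172),
    Object_vs_FamiliarFace      = c(acc = 0.8559, srt = 216),
    UnknownFace_vs_Object       = c(acc = 0.9277, srt = 171),
    Object_vs_UnknownFace       = c(acc = 0.8621, srt = 200),
    FamiliarFace_vs_UnknownFace = c(acc = 0.6181, srt = 191),
    UnknownFace_vs_FamiliarFace = c(acc = 0.5528, srt = 195)
  )
  lapply(tab, function(v)
    list(accuracy = unname(v["acc"]),
         latency = latency_lognormal(unname(v["srt"]), sd = srt_sd),
         error = error_constant(1 - unname(v["acc"]))))
}
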