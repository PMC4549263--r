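# Gaze-trace simulation: 1000 Hz traces with planted saccades.

#' Construct a gaze trace
#'
#' A gaze trace holds one trial's eye-position samples at a uniform
#' 1 ms step. Times are in ms relative to stimulus onset (t = 0), so a
#' standard trial covers [-200, 400): the 200 ms blank used as the
#' velocity baseline plus the 400 ms stimulus window.
#'
#' @param t integer ms timestamps, strictly increasing with step 1.
#' @param x,y eye position in screen px.
#' @param stimulus_onset time of stimulus onset on the `t` axis (ms).
#' @param sampling_rate sampling rate in Hz.
#' @param geometry a [display_geometry()].
#' @return An object of class `"gaze_trace"`.
#' @export
gaze_trace <- function(t, x, y, stimulus_onset = 0, sampling_rate = 1000,
                       geometry = display_geometry()) {
  stopifnot(length(t) >= 2, length(x) == length(t), length(y) == length(t))
  dt <- diff(t)
  if (any(is.na(dt)) || any(dt != dt[1]) || dt[1] <= 0)
    stop("gaze trace timestamps must be strictly increasing with a constant step")
  structure(list(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
                 stimulus_onset = stimulus_onset,
                 sampling_rate = sampling_rate,
                 geometry = geometry),
            class = "gaze_trace")
}

#' @export
print.gaze_trace <- function(x, ...) {
  cat("Gaze trace:", length(x$t), "samples @", x$sampling_rate, "Hz, t in [",
      min(x$t), ",", max(x$t), "] ms (stimulus onset at t =",
      x$stimulus_onset, ")\n")
  invisible(x)
}

#' @export
as.data.frame.gaze_trace <- function(x, ...) {
  data.frame(t_ms = x$t, x_px = x$x, y_px = x$y)
}

# Normalized logistic displacement profile: exactly 0 at tau <= 0 and
# `amplitude` at tau >= duration, smooth and strictly monotone between.
saccade_displacement <- function(tau, amplitude, duration) {
  k <- 2 * log(99) / duration
  raw <- function(u) stats::plogis(k * (u - duration / 2))
  lo <- raw(0); hi <- raw(duration)
  amplitude * (raw(pmin(pmax(tau, 0), duration)) - lo) / (hi - lo)
}

# AR(1) series with stationary SD `sd` and lag-1 correlation `rho`.
ar1_noise <- function(n, sd, rho) {
  if (sd == 0) return(numeric(n))
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
  innov[1] <- stats::rnorm(1, 0, sd)
  as.numeric(stats::filter(innov, rho, method = "recursive"))
}

#' Simulate one trial's gaze trace
#'
#' Produces a 1000 Hz trace covering the 200 ms blank and the 400 ms
#' stimulus window. The eye fixates the screen centre (with drift and
#' measurement noise from `noise`) until the planted saccade onset,
#' then moves horizontally to the centre of one image along a logistic
#' displacement profile whose duration follows a main-sequence-like
#' rule (21 ms + 2.2 ms/deg; ~40 ms for the 8.6 deg amplitude used
#' here). The saccade goes to the target hemifield except with the
#' error probability given by `error` at the planted latency.
#'
#' Artifacts: with the probabilities in `artifacts` the trial is an
#' anticipation (onset uniform in [30, 79] ms) or contains a fixation
#' break (3 deg vertical drift completed 60 ms after stimulus onset).
#'
#' @param spec one trial's metadata: a list or one-row data frame with
#'   at least `target_hemifield` (`"left"`/`"right"`).
#' @param latency a latency model ([latency_lognormal()] or
#'   [latency_truncnorm()]).
#' @param error an error model ([error_constant()], [error_step()]).
#' @param noise a [noise_model()].
#' @param artifacts an [artifact_model()].
#' @param geometry a [display_geometry()].
#' @param seed optional integer seed for this trial.
#' @return A list with elements `trace` (a [gaze_trace()]) and `truth`
#'   (planted ground truth: `true_onset`, `true_direction`, `correct`,
#'   `artifact`, `latency_model`).
#' @export
simulate_trial <- function(spec, latency, error,
                           noise = noise_model(),
                           artifacts = artifact_model(),
                           geometry = display_geometry(),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  hemi <- spec$target_hemifield
  stopifnot(hemi %in% c("left", "right"))

  n_pre <- 200; n_post <- 400
  t <- seq.int(-n_pre, n_post - 1)
  n <- length(t)
  amp <- deg_to_px(geometry$eccentricity_deg, geometry)
  dur <- round(21 + 2.2 * geometry$eccentricity_deg)

  u <- stats::runif(1)
  artifact <- if (u < artifacts$p_anticipation) "anticipation"
              else if (u < artifacts$p_anticipation + artifacts$p_fixation_break)
                "fixation_break" else "none"

  if (artifact == "anticipation") {
    onset <- stats::runif(1, 30, 79)
  } else {
    onset <- latency$sample(1)
    tries <- 1
    while (onset > n_post - dur - 10) {
      if ((tries <- tries + 1) > 1000)
        stop("latency model cannot produce a saccade that crosses the image ",
             "border within the recorded trace")
      onset <- latency$sample(1)
    }
  }

  is_error <- stats::runif(1) < error(onset)
  direction <- if (is_error) setdiff(c("left", "right"), hemi) else hemi
  dir_sign <- if (direction == "right") 1 else -1

  ppd <- geometry$px_per_deg
  disp <- saccade_displacement(t - onset, amp, dur)
  drift_y <- if (artifact == "fixation_break")
    deg_to_px(3, geometry) * pmin(pmax(t, 0), 60) / 60 else 0

  x <- geometry$center[1] + dir_sign * disp +
    ar1_noise(n, noise$jitter_sd_deg * ppd, noise$jitter_ar) +
    stats::rnorm(n, 0, noise$measurement_sd_deg * ppd)
  y <- geometry$center[2] + drift_y +
    ar1_noise(n, noise$jitter_sd_deg * ppd, noise$jitter_ar) +
    stats::rnorm(n, 0, noise$measurement_sd_deg * ppd)

  list(trace = gaze_trace(t, x, y, stimulus_onset = 0, geometry = geometry),
       truth = list(true_onset = onset,
                    true_direction = direction,
                    correct = identical(direction, hemi),
                    artifact = artifact,
                    latency_model = latency$name))
}

#' Simulate a full saccadic-choice experiment
#'
#' Runs [simulate_trial()] for every row of `design$trials` (subset
#' the data frame beforehand to simulate part of an experiment), with
#' per-task latency and error models taken from `condition_params`.
#' The whole dataset is a deterministic function of `seed`.
#'
#' @param design an [build_design()] result, possibly with `trials`
#'   subset.
#' @param condition_params named list keyed by task, each element a
#'   list with `latency` (latency model) and `error` (error model);
#'   see [reference_condition_params()].
#' @param noise a [noise_model()].
#' @param artifacts an [artifact_model()].
#' @param geometry a [display_geometry()].
#' @param seed integer seed.
#' @return An object of class `"saccade_dataset"`: list with `trials`
#'   (metadata incl. a `trial_id` column), `traces` (named list of
#'   [gaze_trace()]), `truth` (data frame of planted ground truth) and
#'   the models used.
#' @export
simulate_experiment <- function(design,
                                condition_params = reference_condition_params(),
                                noise = noise_model(),
                                artifacts = artifact_model(),
                                geometry = display_geometry(),
                                seed = 1) {
  trials <- design$trials
  missing_tasks <- setdiff(unique(trials$task), names(condition_params))
  if (length(missing_tasks) > 0)
    stop("condition_params missing task(s): ",
         paste(missing_tasks, collapse = ", "))
  set.seed(as.integer(seed))
  trials$trial_id <- sprintf("%s_t%03d", trials$subject, trials$trial_index)

  traces <- vector("list", nrow(trials))
  names(traces) <- trials$trial_id
  truth <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    cp <- condition_params[[trials$task[i]]]
    sim <- simulate_trial(trials[i, ], cp$latency, cp$error,
                          noise = noise, artifacts = artifacts,
                          geometry = geometry)
    traces[[i]] <- sim$trace
    truth[[i]] <- data.frame(trial_id = trials$trial_id[i],
                             sim$truth, stringsAsFactors = FALSE)
  }
  structure(list(trials = trials,
                 traces = traces,
                 truth = do.call(rbind, truth),
                 geometry = geometry,
                 noise = noise,
                 artifacts = artifacts,
                 seed = as.integer(seed)),
            class = "saccade_dataset")
}

#' @export
print.saccade_dataset <- function(x, ...) {
  cat("Simulated saccadic-choice dataset:", nrow(x$trials), "trials,",
      length(unique(x$trials$subject)), "subject(s)\n")
  invisible(x)
}
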