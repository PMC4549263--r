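# Offline saccade detection: velocity-threshold candidate selection,
# derivative-sign onset rule, border-crossing direction, and
# trial-rejection filters.

#' Detection configuration
#'
#' Parameters of the offline saccade detector. The velocity threshold
#' is `velocity_sigma` times the SD (about its mean) of the 2-D sample
#' speed over the `baseline_window` ms blank preceding stimulus onset.
#' The inner image borders sit `border_offset_deg` from the screen
#' centre (image eccentricity minus half the image width: 8.6 - 7 =
#' 1.6 deg by default). Saccades starting before `min_srt` ms are
#' rejected as anticipations; trials where gaze leaves
#' `fixation_radius_deg` of the centre within the first
#' `fixation_window` ms after stimulus onset are rejected as fixation
#' breaks.
#'
#' @param geometry a [display_geometry()].
#' @param baseline_window ms of blank used for the velocity baseline.
#' @param velocity_sigma threshold in baseline-SD units (default 3).
#' @param min_srt earliest acceptable saccade onset, ms (default 80).
#' @param fixation_window ms after stimulus onset over which fixation
#'   must be held (default 80).
#' @param fixation_radius_deg fixation tolerance, degrees (default 2).
#' @param border_offset_deg inner image border distance from the
#'   screen centre, degrees.
#' @return A list of class `"detection_config"` with the above plus
#'   the derived `border_x_left`/`border_x_right` in px.
#' @export
detection_config <- function(geometry = display_geometry(),
                             baseline_window = 200,
                             velocity_sigma = 3,
                             min_srt = 80,
                             fixation_window = 80,
                             fixation_radius_deg = 2,
                             border_offset_deg =
                               geometry$eccentricity_deg -
                               geometry$image_size_deg / 2) {
  stopifnot(baseline_window > 0, velocity_sigma > 0, min_srt > 0,
            fixation_window > 0, fixation_radius_deg > 0,
            border_offset_deg > 0)
  off <- deg_to_px(border_offset_deg, geometry)
  structure(list(geometry = geometry,
                 baseline_window = baseline_window,
                 velocity_sigma = velocity_sigma,
                 min_srt = min_srt,
                 fixation_window = fixation_window,
                 fixation_radius_deg = fixation_radius_deg,
                 border_offset_deg = border_offset_deg,
                 border_x_left = geometry$center[1] - off,
                 border_x_right = geometry$center[1] + off),
            class = "detection_config")
}

#' Point-to-point gaze speed
#'
#' Euclidean displacement per sample interval (px/ms at 1000 Hz),
#' aligned to the later of the two samples: element `i` is the speed
#' over (`t[i]`, `t[i+1]`] and carries timestamp `t[i+1]`.
#'
#' @param trace a [gaze_trace()].
#' @return Numeric vector of length `n - 1` with the corresponding
#'   timestamps as attribute `"t"`.
#' @export
compute_velocity <- function(trace) {
  dt <- diff(trace$t)
  if (any(dt != dt[1])) stop("non-uniform timestamps")
  v <- sqrt(diff(trace$x)^2 + diff(trace$y)^2) / dt[1]
  attr(v, "t") <- trace$t[-1]
  v
}

#' Find the first image-border crossing
#'
#' Scans samples at or after stimulus onset for the first x-coordinate
#' at or beyond an inner image border; the side crossed defines the
#' saccade direction.
#'
#' @param trace a [gaze_trace()].
#' @param config a [detection_config()].
#' @return `NULL` if no border is crossed, else a list with `time`
#'   (ms from stimulus onset) and `direction` (`"left"`/`"right"`).
#' @export
find_border_crossing <- function(trace, config = detection_config()) {
  post <- trace$t >= trace$stimulus_onset
  idx <- which(post & (trace$x <= config$border_x_left |
                         trace$x >= config$border_x_right))
  if (length(idx) == 0) return(NULL)
  i <- idx[1]
  list(time = trace$t[i] - trace$stimulus_onset,
       direction = if (trace$x[i] <= config$border_x_left) "left" else "right")
}

#' Detect the saccade onset in one trace
#'
#' Implements the two-stage rule. Candidates are post-onset samples
#' whose 2-D speed exceeds `velocity_sigma` baseline SDs (the baseline
#' being the blank before stimulus onset). Among candidates at or
#' before the border crossing, the onset is the one at which the sign
#' of the first derivative of the x-coordinate last changed and then
#' stayed constant up to the crossing; if the sign never changes after
#' stimulus onset (monotone trace) the first supra-threshold candidate
#' is taken.
#'
#' @param trace a [gaze_trace()].
#' @param config a [detection_config()].
#' @return `NULL` if no border crossing exists or no sample exceeds
#'   the velocity threshold, else a list of class `"saccade_event"`
#'   with `onset` (ms from stimulus onset), `direction`,
#'   `border_crossing` (ms) and `threshold` (px/ms).
#' @export
detect_onset <- function(trace, config = detection_config()) {
  cross <- find_border_crossing(trace, config)
  if (is.null(cross)) return(NULL)

  v <- compute_velocity(trace)
  tv <- attr(v, "t") - trace$stimulus_onset  # velocity timestamps, rel. onset
  base <- tv <= 0 & tv > -config$baseline_window
  if (!any(base)) stop("trace does not cover the baseline window")
  threshold <- config$velocity_sigma * stats::sd(v[base])

  window <- tv >= 0 & tv <= cross$time
  cand <- which(window & v > threshold)
  if (length(cand) == 0) return(NULL)

  dx <- diff(trace$x)
  sgn <- sign(dx)
  ci <- which(tv == cross$time)
  # run of constant derivative sign ending at the crossing; its first
  # element is where the sign last changed
  run_start <- ci
  while (run_start > 1 && sgn[run_start - 1] == sgn[ci] && tv[run_start - 1] >= 0)
    run_start <- run_start - 1
  changed <- run_start > 1 && tv[run_start] > 0  # a post-onset sign change exists
  onset_idx <- if (changed) {
    after <- cand[cand >= run_start]
    if (length(after) > 0) after[1] else cand[1]
  } else cand[1]

  structure(list(onset = tv[onset_idx],
                 direction = cross$direction,
                 border_crossing = cross$time,
                 threshold = threshold),
            class = "saccade_event")
}

#' Apply the trial-rejection filters
#'
#' Turns a detection outcome into a trial result. Rejection reasons,
#' in order of precedence: missing samples in the analysis window;
#' saccade onset before `min_srt` ms (anticipation; onset exactly at
#' `min_srt` is accepted); gaze farther than `fixation_radius_deg`
#' from the screen centre at any point in the first `fixation_window`
#' ms after stimulus onset; no detected saccade. Accepted trials get
#' the onset as SRT and are correct when the saccade direction matches
#' the target hemifield.
#'
#' @param event a `saccade_event` from [detect_onset()], or `NULL`.
#' @param trace the corresponding [gaze_trace()].
#' @param config a [detection_config()].
#' @param target_hemifield `"left"` or `"right"`.
#' @return A list of class `"trial_result"`: `status` (`"accepted"`,
#'   `"rejected_anticipation"`, `"rejected_fixation"`,
#'   `"rejected_no_saccade"`, `"rejected_missing"`), `srt`,
#'   `direction`, `correct` (all `NA` unless accepted).
#' @export
apply_rejection_filters <- function(event, trace,
                                    config = detection_config(),
                                    target_hemifield = NA_character_) {
  result <- function(status, srt = NA_real_, direction = NA_character_,
                     correct = NA) {
    structure(list(status = status, srt = srt, direction = direction,
                   correct = correct), class = "trial_result")
  }
  if (anyNA(trace$x) || anyNA(trace$y))
    return(result("rejected_missing"))
  if (!is.null(event) && event$onset < config$min_srt)
    return(result("rejected_anticipation"))
  rel <- trace$t - trace$stimulus_onset
  fix <- rel >= 0 & rel < config$fixation_window
  ctr <- config$geometry$center
  dist <- sqrt((trace$x[fix] - ctr[1])^2 + (trace$y[fix] - ctr[2])^2)
  if (any(dist > deg_to_px(config$fixation_radius_deg, config$geometry)))
    return(result("rejected_fixation"))
  if (is.null(event))
    return(result("rejected_no_saccade"))
  result("accepted", srt = event$onset, direction = event$direction,
         correct = if (is.na(target_hemifield)) NA
                   else event$direction == target_hemifield)
}

#' Detect saccades for every trial of a dataset
#'
#' Runs [detect_onset()] and [apply_rejection_filters()] on each trace
#' and binds the outcomes to the trial metadata. Per-trial errors are
#' converted into rejections (`status = "rejected_missing"`) with the
#' condition message in the `reason` column.
#'
#' @param dataset a `saccade_dataset` from [simulate_experiment()], or
#'   any list with `trials` (with `trial_id`, `task`,
#'   `target_hemifield`) and `traces` (named by `trial_id`).
#' @param config a [detection_config()].
#' @return Data frame with one row per trial (metadata plus `status`,
#'   `srt`, `direction`, `correct`, `reason`); the per-task rejection
#'   summary is attached as attribute `"rejection_summary"`.
#' @export
detect_all <- function(dataset, config = detection_config()) {
  trials <- dataset$trials
  res <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    trace <- dataset$traces[[trials$trial_id[i]]]
    r <- tryCatch({
      ev <- detect_onset(trace, config)
      tr <- apply_rejection_filters(ev, trace, config,
                                    trials$target_hemifield[i])
      data.frame(status = tr$status, srt = tr$srt, direction = tr$direction,
                 correct = tr$correct, reason = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(status = "rejected_missing", srt = NA_real_,
                 direction = NA_character_, correct = NA,
                 reason = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res[[i]] <- r
  }
  out <- cbind(trials, do.call(rbind, res))
  rownames(out) <- NULL
  summary <- as.data.frame(table(task = out$task, status = out$status),
                           stringsAsFactors = FALSE)
  attr(out, "rejection_summary") <- summary
  out
}
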