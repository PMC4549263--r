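# On-disk formats: tidy gaze CSV, an Eyelink-ASC-like text dialect,
# trial/ground-truth tables and a YAML simulation config.

#' Write a simulated dataset to a directory
#'
#' Writes `trials.csv` (trial metadata), `ground_truth.csv` (planted
#' parameters), `params.yaml` (geometry, noise and artifact settings)
#' and the gaze samples as `gaze.csv` (tidy long format: `subject`,
#' `block`, `trial`, `t_ms`, `x_px`, `y_px`, times relative to
#' stimulus onset) and/or `gaze.asc` (see [write_asc()]).
#'
#' @param dataset a `saccade_dataset` from [simulate_experiment()].
#' @param dir output directory (created if needed).
#' @param formats subset of `c("csv", "asc")`.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, formats = c("csv", "asc")) {
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(dataset$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  g <- dataset$geometry
  yaml::write_yaml(list(
    geometry = list(screen = g$screen, px_per_deg = g$px_per_deg,
                    eccentricity_deg = g$eccentricity_deg,
                    image_size_deg = g$image_size_deg,
                    viewing_distance_cm = g$viewing_distance_cm),
    noise = unclass(dataset$noise),
    artifacts = unclass(dataset$artifacts),
    seed = dataset$seed), file.path(dir, "params.yaml"))
  if ("csv" %in% formats) write_gaze_csv(dataset, file.path(dir, "gaze.csv"))
  if ("asc" %in% formats) write_asc(dataset, file.path(dir, "gaze.asc"))
  invisible(dir)
}

#' Write gaze samples as tidy CSV
#'
#' @param dataset a `saccade_dataset`.
#' @param file destination path.
#' @return `file`, invisibly.
#' @export
write_gaze_csv <- function(dataset, file) {
  rows <- lapply(seq_len(nrow(dataset$trials)), function(i) {
    tr <- dataset$trials[i, ]
    trace <- dataset$traces[[tr$trial_id]]
    data.frame(subject = tr$subject, block = tr$block,
               trial = tr$trial_index,
               t_ms = trace$t - trace$stimulus_onset,
               x_px = round(trace$x, 2), y_px = round(trace$y, 2))
  })
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}

#' Read gaze traces from tidy CSV
#'
#' @param file a file written by [write_gaze_csv()] (times relative to
#'   stimulus onset).
#' @param geometry a [display_geometry()] to attach to the traces.
#' @return Named list of [gaze_trace()] objects keyed
#'   `"<subject>_t<trial>"`.
#' @export
read_gaze_csv <- function(file, geometry = display_geometry()) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  d$trial_id <- sprintf("%s_t%03d", d$subject, d$trial)
  lapply(split(d, d$trial_id), function(g)
    gaze_trace(g$t_ms, g$x_px, g$y_px, stimulus_onset = 0,
               geometry = geometry))
}

#' Write gaze samples in an Eyelink-ASC-like dialect
#'
#' One text file for the whole dataset. Each trial is a block of the
#' form:
#' \preformatted{MSG <t> TRIALID <id>
#' START <t>
#' <t> <x> <y>
#' ...
#' MSG <t> STIMONSET
#' ...
#' END <t>}
#' with absolute integer timestamps (trials are laid out sequentially
#' with a gap); the `STIMONSET` message marks stimulus onset inline at
#' its true time.
#'
#' @param dataset a `saccade_dataset`.
#' @param file destination path.
#' @return `file`, invisibly.
#' @export
write_asc <- function(dataset, file) {
  con <- file(file, "w")
  on.exit(close(con))
  clock <- 0L
  for (i in seq_len(nrow(dataset$trials))) {
    id <- dataset$trials$trial_id[i]
    trace <- dataset$traces[[id]]
    base <- clock + 1000L  # inter-trial gap
    t_abs <- base + (trace$t - trace$t[1])
    onset_abs <- base + (trace$stimulus_onset - trace$t[1])
    writeLines(c(sprintf("MSG %d TRIALID %s", base, id),
                 sprintf("START %d", t_abs[1])), con)
    samples <- sprintf("%d %.2f %.2f", t_abs, trace$x, trace$y)
    pre <- t_abs < onset_abs
    writeLines(samples[pre], con)
    writeLines(sprintf("MSG %d STIMONSET", onset_abs), con)
    writeLines(samples[!pre], con)
    writeLines(sprintf("END %d", t_abs[length(t_abs)]), con)
    clock <- t_abs[length(t_abs)]
  }
  invisible(file)
}

#' Read gaze traces from the ASC-like dialect
#'
#' Parses the format written by [write_asc()]. Sample times are
#' re-expressed relative to each trial's `STIMONSET` message.
#'
#' @param file path to an ASC-like file.
#' @param geometry a [display_geometry()] to attach to the traces.
#' @return Named list of [gaze_trace()] objects keyed by trial ID.
#' @export
read_asc <- function(file, geometry = display_geometry()) {
  lines <- readLines(file)
  out <- list()
  id <- NULL; onset <- NA_real_; buf_t <- buf_x <- buf_y <- numeric(0)
  flush <- function() {
    if (is.null(id)) return()
    if (is.na(onset)) stop("trial ", id, " has no STIMONSET message")
    out[[id]] <<- gaze_trace(buf_t - onset, buf_x, buf_y,
                             stimulus_onset = 0, geometry = geometry)
  }
  for (ln in lines) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) == 0) next
    if (f[1] == "MSG") {
      if (length(f) >= 4 && f[3] == "TRIALID") {
        flush()
        id <- f[4]; onset <- NA_real_
        buf_t <- buf_x <- buf_y <- numeric(0)
      } else if (length(f) >= 3 && f[3] == "STIMONSET") {
        onset <- as.numeric(f[2])
      }
    } else if (f[1] %in% c("START", "END")) {
      next
    } else if (length(f) >= 3 && !is.na(suppressWarnings(as.numeric(f[1])))) {
      buf_t <- c(buf_t, as.numeric(f[1]))
      buf_x <- c(buf_x, as.numeric(f[2]))
      buf_y <- c(buf_y, as.numeric(f[3]))
    }
  }
  flush()
  out
}
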