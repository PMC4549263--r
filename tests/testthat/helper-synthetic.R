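# Shared fixtures and independent oracles, all generated in code.

# A constant-latency model (degenerate truncated normal).
latency_constant <- function(ms) latency_truncnorm(ms, 1e-9, min = 0)

quiet_noise <- function() noise_model(0, 0, 0)
no_artifacts <- function() artifact_model(0, 0)

# Simulate a batch of trials from a 1-subject design subset and run
# detection; returns detection results merged with planted truth.
simulate_and_detect <- function(n_trials, seed,
                                noise = noise_model(),
                                artifacts = no_artifacts(),
                                condition_params = reference_condition_params(),
                                config = detection_config()) {
  design <- build_design(1, seed = seed)
  idx <- seq_len(min(n_trials, nrow(design$trials)))
  design$trials <- design$trials[idx, , drop = FALSE]
  ds <- simulate_experiment(design, condition_params = condition_params,
                            noise = noise, artifacts = artifacts,
                            seed = seed + 1)
  merge(detect_all(ds, config), ds$truth, by = "trial_id")
}

# Independent brute-force evaluation of the onset rule: linear scans
# only, no vectorized shortcuts shared with the implementation.
oracle_onset <- function(trace, config) {
  n <- length(trace$t)
  # crossing: first post-onset sample at/over a border
  cross_i <- NA
  for (i in seq_len(n)) {
    if (trace$t[i] < trace$stimulus_onset) next
    if (trace$x[i] <= config$border_x_left ||
        trace$x[i] >= config$border_x_right) { cross_i <- i; break }
  }
  if (is.na(cross_i)) return(NULL)
  v <- numeric(n); v[1] <- NA
  for (i in 2:n)
    v[i] <- sqrt((trace$x[i] - trace$x[i - 1])^2 +
                   (trace$y[i] - trace$y[i - 1])^2)
  base <- c()
  for (i in 2:n) {
    rel <- trace$t[i] - trace$stimulus_onset
    if (rel <= 0 && rel > -config$baseline_window) base <- c(base, v[i])
  }
  thr <- config$velocity_sigma * sd(base)
  cand <- c()
  for (i in 2:cross_i) {
    rel <- trace$t[i] - trace$stimulus_onset
    if (rel >= 0 && v[i] > thr) cand <- c(cand, i)
  }
  if (length(cand) == 0) return(NULL)
  sgn <- function(i) sign(trace$x[i] - trace$x[i - 1])
  # last post-onset sample where the derivative sign changed and then
  # stayed equal to the sign at the crossing
  last_change <- NA
  for (i in 3:cross_i) {
    if (trace$t[i] - trace$stimulus_onset <= 0) next
    if (sgn(i) != sgn(i - 1)) {
      constant <- TRUE
      for (j in i:cross_i) if (sgn(j) != sgn(cross_i)) { constant <- FALSE; break }
      if (constant) last_change <- i
    }
  }
  pick <- NA
  if (!is.na(last_change)) {
    for (i in cand) if (i >= last_change) { pick <- i; break }
  }
  if (is.na(pick)) pick <- cand[1]
  trace$t[pick] - trace$stimulus_onset
}

# Fabricate an accepted-trials results table (detect_all format) with
# planted accuracy/SRT structure, bypassing trace simulation.
make_results <- function(n_subjects = 4, trials_per_subject = NULL,
                         seed = 1,
                         task_logit = c(FamiliarFace_vs_Object = 2.5,
                                        Object_vs_FamiliarFace = 1.8,
                                        UnknownFace_vs_Object = 2.5,
                                        Object_vs_UnknownFace = 1.8,
                                        FamiliarFace_vs_UnknownFace = 0.5,
                                        UnknownFace_vs_FamiliarFace = 0.2),
                         task_ms = c(FamiliarFace_vs_Object = 172,
                                     Object_vs_FamiliarFace = 216,
                                     UnknownFace_vs_Object = 171,
                                     Object_vs_UnknownFace = 200,
                                     FamiliarFace_vs_UnknownFace = 191,
                                     UnknownFace_vs_FamiliarFace = 195),
                         subject_sd = 0.3, item_sd = 0,
                         rt_subject_sd = 0.05, rt_sigma = 0.15,
                         trial_slope = 0, pos_log_ratio = 0) {
  set.seed(seed)
  d <- build_design(n_subjects, seed = seed)$trials
  if (!is.null(trials_per_subject)) {
    keep <- unlist(lapply(split(seq_len(nrow(d)), d$subject),
                          sample, trials_per_subject))
    d <- d[keep, , drop = FALSE]
  }
  d$status <- "accepted"
  subj <- factor(d$subject)
  u_s <- rnorm(nlevels(subj), 0, subject_sd)
  u_t <- rnorm(27, 0, item_sd)
  names(u_t) <- unlist(lapply(c("FamiliarFace", "UnknownFace", "Object"),
                              image_ids))
  eta <- task_logit[d$task] + u_s[as.integer(subj)] + u_t[d$target_image]
  d$correct <- runif(nrow(d)) < plogis(eta)
  tz <- as.numeric(scale(d$trial_index))
  mu <- log(task_ms[d$task]) + rnorm(nlevels(subj), 0, rt_subject_sd)[as.integer(subj)] +
    trial_slope * tz + pos_log_ratio * (d$target_hemifield == "right")
  d$srt <- exp(mu + rnorm(nrow(d), 0, rt_sigma))
  d$direction <- ifelse(d$correct, d$target_hemifield,
                        ifelse(d$target_hemifield == "left", "right", "left"))
  d$reason <- NA_character_
  d
}
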