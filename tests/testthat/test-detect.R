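make_trace <- function(x, y = rep(300, length(x)), t0 = -200) {
  t <- seq(t0, by = 1, length.out = length(x))
  gaze_trace(t, x, y, stimulus_onset = 0)
}

test_that("velocity matches brute-force point-to-point speed", {
  n <- 400
  tr <- make_trace(rep(400, n))
  expect_true(all(compute_velocity(tr) == 0))
  ramp <- make_trace(400 + 2 * seq_len(n))
  expect_true(all(compute_velocity(ramp) == 2))
  set.seed(2)
  rnd <- make_trace(400 + cumsum(rnorm(n)), 300 + cumsum(rnorm(n)))
  v <- compute_velocity(rnd)
  brute <- sapply(2:n, function(i)
    sqrt((rnd$x[i] - rnd$x[i - 1])^2 + (rnd$y[i] - rnd$y[i - 1])^2))
  expect_equal(as.numeric(v), brute)
  expect_error(compute_velocity(gaze_trace(c(1, 2, 4), 1:3, 1:3)),
               "constant step")
})

test_that("border crossings are found with the correct side and time", {
  cfg <- detection_config()
  n <- 500
  expect_null(find_border_crossing(make_trace(rep(400, n)), cfg))
  # crosses the left border (360 px) at t = 210
  x <- rep(400, n); x[(201 + 210):n] <- 350
  cr <- find_border_crossing(make_trace(x), cfg)
  expect_equal(cr$time, 210)
  expect_equal(cr$direction, "left")
  # samples before stimulus onset never count as crossings
  x2 <- rep(400, n); x2[1:50] <- 100; x2[(201 + 150):n] <- 460
  cr2 <- find_border_crossing(make_trace(x2), cfg)
  expect_equal(cr2$time, 150)
  expect_equal(cr2$direction, "right")
})

test_that("onset detection recovers noiseless planted saccades", {
  s <- simulate_trial(list(target_hemifield = "left"),
                      latency_constant(150), error_constant(0),
                      noise = quiet_noise(), artifacts = no_artifacts(),
                      seed = 2)
  ev <- detect_onset(s$trace)
  expect_equal(ev$direction, "left")
  expect_lte(abs(ev$onset - 150), 2)
  expect_lt(ev$onset, ev$border_crossing)
})

test_that("no supra-threshold sample means no detected onset", {
  # crossing exists, but the post-onset drift (0.5 px/ms) stays below
  # the threshold set by a jagged baseline (speeds alternating 0 and
  # 4 px/ms give 3 SD = 6 px/ms)
  n <- 700
  base <- 400 + cumsum(rep(c(4, -4, 0, 0), 50))  # oscillates in [400, 404]
  x <- c(base, base[200] - cumsum(rep(0.5, n - 200)))
  tr <- make_trace(x)
  expect_false(is.null(find_border_crossing(tr)))
  expect_null(detect_onset(tr))
})

test_that("monotone traces fall back to the first candidate", {
  n <- 600
  x <- 400 + c(rep(0, 200), cumsum(rep(0.8, n - 200)))  # moves from t=0
  ev <- detect_onset(make_trace(x))
  expect_false(is.null(ev))
  expect_equal(ev$onset, 0)  # the ramp's first step spans (-1, 0]
})

test_that("onset equals exhaustive brute-force evaluation of the rule", {
  cfg <- detection_config()
  set.seed(31)
  for (i in 1:25) {
    hemi <- sample(c("left", "right"), 1)
    s <- simulate_trial(list(target_hemifield = hemi),
                        latency_lognormal(180, 40), error_constant(0.2),
                        artifacts = no_artifacts())
    ev <- detect_onset(s$trace, cfg)
    oracle <- oracle_onset(s$trace, cfg)
    if (is.null(ev)) expect_null(oracle) else expect_equal(ev$onset, oracle)
  }
})

test_that("lowering the velocity threshold never delays the onset", {
  set.seed(17)
  for (i in 1:10) {
    s <- simulate_trial(list(target_hemifield = "right"),
                        latency_lognormal(200, 30), error_constant(0),
                        artifacts = no_artifacts())
    onsets <- sapply(c(4, 3, 2, 1), function(sg) {
      ev <- detect_onset(s$trace, detection_config(velocity_sigma = sg))
      if (is.null(ev)) Inf else ev$onset
    })
    expect_true(all(diff(onsets) <= 0))
  }
})

test_that("rejection filters enforce the 80 ms boundary conventions", {
  cfg <- detection_config()
  quiet <- simulate_trial(list(target_hemifield = "right"),
                          latency_constant(200), error_constant(0),
                          noise = quiet_noise(),
                          artifacts = no_artifacts(), seed = 1)$trace
  ev79 <- structure(list(onset = 79, direction = "right",
                         border_crossing = 120), class = "saccade_event")
  expect_equal(apply_rejection_filters(ev79, quiet, cfg, "right")$status,
               "rejected_anticipation")
  ev80 <- structure(list(onset = 80, direction = "right",
                         border_crossing = 120), class = "saccade_event")
  r80 <- apply_rejection_filters(ev80, quiet, cfg, "right")
  expect_equal(r80$status, "accepted")
  expect_equal(r80$srt, 80)
  expect_true(r80$correct)
  expect_equal(apply_rejection_filters(NULL, quiet, cfg, "right")$status,
               "rejected_no_saccade")
  # fixation break: 3 deg vertical excursion inside the first 80 ms
  broken <- quiet
  broken$y[broken$t >= 20 & broken$t < 60] <- 300 + deg_to_px(3)
  ev <- detect_onset(broken, cfg)
  expect_equal(apply_rejection_filters(ev, broken, cfg, "right")$status,
               "rejected_fixation")
  # missing samples are their own rejection reason
  gap <- quiet; gap$x[300] <- NA
  expect_equal(apply_rejection_filters(ev80, gap, cfg, "right")$status,
               "rejected_missing")
})

test_that("planted anticipations are rejected at their planted rate", {
  m <- simulate_and_detect(250, seed = 51, noise = quiet_noise(),
                           artifacts = artifact_model(0.1, 0))
  k <- sum(m$status == "rejected_anticipation")
  planted <- sum(m$artifact == "anticipation")
  expect_equal(k, planted)  # zero noise: filter matches the plant exactly
  ci <- binom.test(k, nrow(m), 0.1)$conf.int
  expect_true(ci[1] <= 0.1 && 0.1 <= ci[2])
})

test_that("detect_all recovers onsets and directions on a synthetic batch", {
  m <- simulate_and_detect(150, seed = 61)
  acc <- m[m$status == "accepted", ]
  expect_gt(nrow(acc), 100)
  expect_true(all(acc$direction == acc$true_direction))
  err <- acc$srt - acc$true_onset
  expect_lte(median(abs(err)), 5)
  # noiseless: zero rejections and exact direction agreement
  m0 <- simulate_and_detect(60, seed = 62, noise = quiet_noise())
  expect_true(all(m0$status == "accepted"))
  expect_true(all(m0$direction == m0$true_direction))
  expect_true(all(m0$correct == (m0$true_direction == m0$target_hemifield)))
})
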