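# The mixed-model workflow. Fits are kept small: a handful of
# subjects and a few hundred trials are enough to exercise selection,
# reparameterization, deviance analysis and the bootstrap.

test_that("random-effect selection keeps real effects and tie-breaks to the
           first candidate", {
  # strong subject variance on log-RT, no item variance
  d <- make_results(6, 150, seed = 3, rt_subject_sd = 0.3, rt_sigma = 0.1)
  md <- prepare_model_data(d)
  md <- md[md$correct, ]
  sel <- select_random_effects(md, "rt")
  expect_equal(sort(unique(sel$lrt$df)), 1)
  subj_row <- sel$lrt[grepl("subject", sel$lrt$term), ][1, ]
  expect_lt(subj_row$p_value, 0.001)

  # two identical candidate structures tie exactly; the first wins
  sel_tie <- select_random_effects(
    md, "rt", candidates = list(a = "subject", b = "subject"))
  expect_equal(diff(sel_tie$candidate_loglik), 0, ignore_attr = TRUE)
  expect_equal(names(sel_tie$candidate_loglik)[
    which.max(sel_tie$candidate_loglik)], "a")
})

test_that("subject LRT is near-nominal under zero subject variance and
           powerful under strong item variance", {
  set.seed(77)
  null_sig <- replicate(24, {
    d <- make_results(6, 50, seed = sample.int(1e6, 1), subject_sd = 0,
                      rt_subject_sd = 0, rt_sigma = 0.12)
    md <- prepare_model_data(d)
    sel <- select_random_effects(md[md$correct, ], "rt")
    any(sel$lrt$p_value[grepl("^subject$", sel$lrt$term)] < 0.05)
  })
  # naive chi-square(1) reference on a boundary null: rejection rate
  # should be at or below the nominal 5% (about half of it)
  expect_lte(mean(null_sig), 0.15)

  set.seed(78)
  item_kept <- replicate(12, {
    d <- make_results(5, 120, seed = sample.int(1e6, 1),
                      rt_subject_sd = 0.1, rt_sigma = 0.1)
    md <- prepare_model_data(d)
    md <- md[md$correct, ]
    # plant strong distractor-item variance on log-RT
    u <- rnorm(nlevels(md$distractor_image), 0, 0.2)
    md$srt <- md$srt * exp(u[as.integer(md$distractor_image)])
    sel <- select_random_effects(md, "rt")
    any(sel$lrt$significant[grepl("distractor_image", sel$lrt$term)])
  })
  expect_gte(mean(item_kept), 0.9)
})

test_that("Type III deviance test holds its nominal size on null data", {
  set.seed(5150)
  p_pos <- replicate(100, {
    d <- make_results(5, 60, seed = sample.int(1e6, 1), rt_subject_sd = 0.1,
                      rt_sigma = 0.12, pos_log_ratio = 0)
    md <- prepare_model_data(d)
    a <- sacchoice:::type3_anova("log(srt)", "subject", md[md$correct, ])
    a$p_value[a$effect == "target_position"]
  })
  rate <- mean(p_pos < 0.05)
  expect_gte(rate, 0.005)
  expect_lte(rate, 0.12)
})

test_that("accuracy model recovers planted log-odds and flags chance tasks", {
  # one task at chance (log-odds 0), one at 73.1% correct (log-odds
  # ~1); modest subject variance as in real data
  logits <- c(FamiliarFace_vs_Object = 2.5, Object_vs_FamiliarFace = 1.8,
              UnknownFace_vs_Object = 2.5, Object_vs_UnknownFace = 1.8,
              FamiliarFace_vs_UnknownFace = 1.0,
              UnknownFace_vs_FamiliarFace = 0.0)
  d <- make_results(4, 360, seed = 11, task_logit = logits,
                    subject_sd = 0.25)
  md <- prepare_model_data(d)
  fit <- fit_accuracy_model(md, re_terms = "subject", n_boot = 60, seed = 2)
  est <- fit$estimates
  uf <- est[est$parameter == "taskUnknownFace_vs_FamiliarFace" &
              est$reference_position == "left", ]
  expect_lt(abs(uf$estimate), 0.4)
  expect_true(uf$ci_lo <= 0 && uf$ci_hi >= 0)
  ff <- est[est$parameter == "taskFamiliarFace_vs_UnknownFace" &
              est$reference_position == "left", ]
  expect_lt(abs(ff$estimate - 1.0), 0.5)
  expect_true(ff$ci_lo <= 1.0 & 1.0 <= ff$ci_hi)
  expect_true("UnknownFace_vs_FamiliarFace" %in% fit$chance_tasks)
  expect_false("FamiliarFace_vs_Object" %in% fit$chance_tasks)
  expect_true(all(c("task", "target_position", "task:target_position",
                    "trial_z") %in% fit$anova$effect))
})

test_that("accuracy model recovers a planted negative trial-number slope", {
  set.seed(91)
  signs <- replicate(10, {
    d <- make_results(5, 160, seed = sample.int(1e6, 1), subject_sd = 0.2)
    md <- prepare_model_data(d)
    eta <- qlogis(0.85) - 0.4 * md$trial_z
    md$correct <- runif(nrow(md)) < plogis(eta)
    f <- sacchoice:::fit_mixed("correct", "task * target_position + trial_z",
                               "subject", md)
    unname(lme4::fixef(f)["trial_z"] < 0)
  })
  expect_gte(mean(signs), 0.9)
})

test_that("RT model recovers planted task means and their ratio", {
  ms <- c(FamiliarFace_vs_Object = 170, Object_vs_FamiliarFace = 200,
          UnknownFace_vs_Object = 170, Object_vs_UnknownFace = 200,
          FamiliarFace_vs_UnknownFace = 190,
          UnknownFace_vs_FamiliarFace = 190)
  d <- make_results(4, 200, seed = 13, task_ms = ms, rt_subject_sd = 0,
                    rt_sigma = 1e-6)
  md <- prepare_model_data(d)
  fit <- fit_rt_model(md, re_terms = "subject",
                      exclude_tasks = "UnknownFace_vs_FamiliarFace",
                      n_boot = 40, seed = 3)
  est <- fit$estimates[fit$estimates$reference_position == "left", ]
  e_ffo <- est$exp_estimate[est$parameter == "taskFamiliarFace_vs_Object"]
  e_off <- est$exp_estimate[est$parameter == "taskObject_vs_FamiliarFace"]
  expect_equal(e_ffo, 170, tolerance = 1e-3)
  expect_equal(e_off / e_ffo, 200 / 170, tolerance = 1e-3)
  expect_false("taskUnknownFace_vs_FamiliarFace" %in% est$parameter)
  expect_error(fit_rt_model(transform(md, srt = srt - 500),
                            re_terms = "subject"),
               "non-positive")
})

test_that("RT model recovers a planted hemifield multiplier", {
  d <- make_results(7, NULL, seed = 17, rt_subject_sd = 0.05,
                    rt_sigma = 0.12, pos_log_ratio = log(1.025))
  md <- prepare_model_data(d)
  md <- md[md$correct, ]
  f <- sacchoice:::fit_mixed("log(srt)", "task * target_position + trial_z",
                             "subject", md, reml = TRUE)
  ci <- parametric_bootstrap_ci(f, n_boot = 150, seed = 9)
  row <- ci[ci$parameter == "target_positionright", ]
  expect_true(row$ci_lo <= log(1.025) && log(1.025) <= row$ci_hi)
  expect_lt(abs(exp(row$estimate) - 1.025), 0.02)
})

test_that("with/without intercept and either reference level are the same
           model", {
  d <- make_results(5, 120, seed = 23)
  md <- prepare_model_data(d)
  mdr <- md[md$correct, ]
  with_int <- sacchoice:::fit_mixed("log(srt)",
                                    "task * target_position + trial_z",
                                    "subject", mdr)
  no_int <- sacchoice:::fit_mixed(
    "log(srt)", "0 + task + target_position + task:target_position + trial_z",
    "subject", mdr)
  expect_equal(as.numeric(logLik(with_int)), as.numeric(logLik(no_int)),
               tolerance = 1e-6)
  expect_equal(fitted(with_int), fitted(no_int), tolerance = 1e-6)
  mdr2 <- mdr
  mdr2$target_position <- relevel(mdr2$target_position, "right")
  refl <- sacchoice:::fit_mixed(
    "log(srt)", "0 + task + target_position + task:target_position + trial_z",
    "subject", mdr2)
  expect_equal(as.numeric(logLik(no_int)), as.numeric(logLik(refl)),
               tolerance = 1e-6)
  expect_equal(unname(fitted(no_int)), unname(fitted(refl)),
               tolerance = 1e-6)
})

test_that("parametric bootstrap is seed-deterministic and degenerates with
           the noise", {
  d <- make_results(5, 80, seed = 29)
  md <- prepare_model_data(d)
  f <- sacchoice:::fit_mixed("log(srt)", "task + trial_z", "subject",
                             md[md$correct, ])
  a <- parametric_bootstrap_ci(f, n_boot = 30, seed = 5)
  b <- parametric_bootstrap_ci(f, n_boot = 30, seed = 5)
  expect_identical(a, b)
  c <- parametric_bootstrap_ci(f, n_boot = 30, seed = 6)
  expect_false(identical(a$ci_lo, c$ci_lo))
  expect_true(all(a$ci_lo <= a$estimate & a$estimate <= a$ci_hi))

  d0 <- make_results(4, 60, seed = 31, rt_subject_sd = 0, rt_sigma = 1e-7)
  md0 <- prepare_model_data(d0)
  f0 <- sacchoice:::fit_mixed("log(srt)", "task", "subject",
                              md0[md0$correct, ])
  ci0 <- parametric_bootstrap_ci(f0, n_boot = 30, seed = 7)
  expect_true(all(ci0$ci_hi - ci0$ci_lo < 1e-4))
})
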