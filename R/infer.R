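# Mixed-effects inference workflow: random-effect selection by
# likelihood-ratio tests, Type III analysis of deviance for fixed
# effects, no-intercept reparameterization with reference-level
# switching, and parametric-bootstrap confidence intervals.

#' Prepare accepted-trial results for model fitting
#'
#' Keeps accepted trials, coerces the design variables to factors and
#' standardizes the trial number (z-score) to keep the fixed-effects
#' design well conditioned.
#'
#' @param results data frame as returned by [detect_all()] (or with
#'   the same columns).
#' @return Data frame with factor columns `subject`, `task`,
#'   `target_position`, `target_image`, `distractor_image`, numeric
#'   `trial_z`, logical `correct` and numeric `srt`.
#' @export
prepare_model_data <- function(results) {
  d <- results[results$status == "accepted", , drop = FALSE]
  if (nrow(d) == 0) stop("no accepted trials")
  data.frame(subject = factor(d$subject),
             task = factor(d$task),
             target_position = factor(d$target_hemifield,
                                      levels = c("left", "right")),
             target_image = factor(d$target_image),
             distractor_image = factor(d$distractor_image),
             trial_z = as.numeric(scale(d$trial_index)),
             correct = as.logical(d$correct),
             srt = d$srt)
}

re_formula <- function(terms) paste(sprintf("(1 | %s)", terms), collapse = " + ")

fit_mixed <- function(response, fixed, re_terms, data, reml = FALSE) {
  fml <- stats::as.formula(paste(response, "~", fixed, "+",
                                 re_formula(re_terms)))
  binom <- response == "correct"
  # convergence is judged by likelihood comparisons and the bootstrap,
  # not by post-hoc gradient checks; skipping the optional derivative
  # pass makes bootstrap refits dramatically cheaper
  opts <- list(calc.derivs = FALSE, check.conv.singular = "ignore",
               check.conv.grad = "ignore", check.conv.hess = "ignore")
  withCallingHandlers(
    if (binom) {
      # bobyqa for both phases: the default second-phase Nelder-Mead
      # is an order of magnitude slower near variance boundaries
      lme4::glmer(fml, data = data, family = stats::binomial,
                  control = do.call(lme4::glmerControl,
                                    c(opts, optimizer = "bobyqa")))
    } else {
      lme4::lmer(fml, data = data, REML = reml,
                 control = do.call(lme4::lmerControl, opts))
    },
    message = function(m) invokeRestart("muffleMessage"))
}

#' Select the random-effect structure
#'
#' Follows the two-stage procedure used for both the accuracy and the
#' reaction-time analyses. Two candidate structures with the same
#' number of parameters are fitted by maximum likelihood: fully
#' crossed intercepts for subject, target item and distractor item,
#' versus subject plus the subject-by-target and subject-by-distractor
#' combinations. The structure with the higher log-likelihood wins
#' (first candidate on ties). Each retained random effect is then
#' tested by a likelihood-ratio test of the full model against the
#' model without it, on a naive chi-square(1) reference as
#' conventionally reported (set `boundary_mixture = TRUE` for the
#' 50:50 mixture correction appropriate to a variance on the boundary).
#'
#' @param data a [prepare_model_data()] frame.
#' @param response `"accuracy"` (logit model on `correct`) or `"rt"`
#'   (linear model on `log(srt)`; supply correct trials only).
#' @param fixed right-hand side of the fixed-effects formula.
#' @param boundary_mixture halve the LRT p-values (boundary-corrected
#'   mixture reference)?
#' @param candidates named list of candidate random-effect structures
#'   (character vectors of grouping terms); all candidates must have
#'   the same number of variance parameters for the log-likelihood
#'   comparison to be fair.
#' @return List with `structure` (character vector of retained random
#'   effects), `candidate_loglik` (named numeric), `lrt` (data frame:
#'   `term`, `chisq`, `df`, `p_value`, `significant`) and `model`
#'   (the chosen full ML fit).
#' @export
select_random_effects <- function(data,
                                  response = c("accuracy", "rt"),
                                  fixed = "task * target_position + trial_z",
                                  boundary_mixture = FALSE,
                                  candidates = list(
                                    crossed = c("subject", "target_image",
                                                "distractor_image"),
                                    subject_combinations =
                                      c("subject", "subject:target_image",
                                        "subject:distractor_image"))) {
  response <- match.arg(response)
  resp <- if (response == "accuracy") "correct" else "log(srt)"
  fits <- lapply(candidates, function(re)
    fit_mixed(resp, fixed, re, data))
  ll <- vapply(fits, function(f) as.numeric(stats::logLik(f)), numeric(1))
  best <- which.max(ll)  # ties resolved to the first candidate
  re_terms <- candidates[[best]]
  full <- fits[[best]]
  ll_full <- as.numeric(stats::logLik(full))

  lrt <- do.call(rbind, lapply(seq_along(re_terms), function(i) {
    reduced <- if (length(re_terms) > 1) {
      fit_mixed(resp, fixed, re_terms[-i], data)
    } else {
      # removing the only random effect leaves a fixed-effects model
      if (resp == "correct")
        stats::glm(stats::as.formula(paste(resp, "~", fixed)),
                   data = data, family = stats::binomial)
      else stats::lm(stats::as.formula(paste(resp, "~", fixed)), data = data)
    }
    chisq <- max(0, 2 * (ll_full - as.numeric(stats::logLik(reduced))))
    p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
    if (boundary_mixture) p <- p / 2
    data.frame(term = re_terms[i], chisq = chisq, df = 1, p_value = p,
               stringsAsFactors = FALSE)
  }))
  lrt$significant <- lrt$p_value < 0.05
  list(structure = re_terms,
       candidate_loglik = ll,
       lrt = lrt,
       model = full)
}

#' Parametric-bootstrap confidence intervals for a mixed model
#'
#' Simulates `n_boot` response vectors from the fitted model's own
#' estimates, refits the model to each, and returns percentile
#' intervals of the fixed-effect estimates. Replicates whose refit
#' fails are dropped (their count is reported); more than
#' `max_fail_frac` failures is an error.
#'
#' @param fit a fitted `merMod` (from \pkg{lme4}).
#' @param n_boot number of bootstrap replicates.
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @param max_fail_frac largest tolerated fraction of failed refits.
#' @return Data frame with `parameter`, `estimate`, `ci_lo`, `ci_hi`;
#'   attributes `n_fail` and `n_boot`.
#' @export
parametric_bootstrap_ci <- function(fit, n_boot = 1000, seed = 1,
                                    level = 0.95, max_fail_frac = 0.1) {
  stopifnot(n_boot >= 2)
  set.seed(as.integer(seed))
  sims <- stats::simulate(fit, nsim = n_boot)
  est <- lme4::fixef(fit)
  boots <- matrix(NA_real_, n_boot, length(est),
                  dimnames = list(NULL, names(est)))
  for (b in seq_len(n_boot)) {
    r <- tryCatch(
      suppressWarnings(suppressMessages(lme4::refit(fit, sims[[b]]))),
      error = function(e) NULL)
    if (!is.null(r)) boots[b, ] <- lme4::fixef(r)
  }
  ok <- stats::complete.cases(boots)
  n_fail <- sum(!ok)
  if (n_fail > max_fail_frac * n_boot)
    stop("parametric bootstrap: ", n_fail, " of ", n_boot,
         " refits failed (more than ", 100 * max_fail_frac, "%)")
  a <- (1 - level) / 2
  qs <- apply(boots[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(a, 1 - a))
  out <- data.frame(parameter = names(est), estimate = unname(est),
                    ci_lo = qs[1, ], ci_hi = qs[2, ],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_fail") <- n_fail
  attr(out, "n_boot") <- n_boot
  out
}

type3_anova <- function(response, re_terms, data, reml = FALSE) {
  # Type III tests require sum-to-zero contrasts
  d <- data
  stats::contrasts(d$task) <- stats::contr.sum(nlevels(d$task))
  stats::contrasts(d$target_position) <-
    stats::contr.sum(nlevels(d$target_position))
  m <- fit_mixed(response, "task * target_position + trial_z", re_terms, d,
                 reml = reml)
  a <- car::Anova(m, type = "III")
  data.frame(effect = rownames(a), chisq = a[["Chisq"]], df = a[["Df"]],
             p_value = a[["Pr(>Chisq)"]], row.names = NULL,
             stringsAsFactors = FALSE)
}

no_intercept_fits <- function(response, re_terms, data, reml = FALSE) {
  fixed0 <- "0 + task + target_position + task:target_position + trial_z"
  left <- fit_mixed(response, fixed0, re_terms, data, reml = reml)
  d2 <- data
  d2$target_position <- stats::relevel(d2$target_position, "right")
  right <- fit_mixed(response, fixed0, re_terms, d2, reml = reml)
  list(left = left, right = right)
}

boot_estimates <- function(fits, n_boot, seed, task_levels) {
  out <- lapply(names(fits), function(ref) {
    ci <- parametric_bootstrap_ci(fits[[ref]], n_boot = n_boot, seed = seed)
    ci$reference_position <- ref
    ci
  })
  do.call(rbind, out)
}

#' Logit mixed model of trial accuracy
#'
#' Fits the full accuracy workflow: selection (or use) of the random
#' effect structure, Type III analysis of deviance for the fixed
#' effects (task, target position, their interaction, scaled trial
#' number), then a refit without intercept — so that each task's
#' coefficient is its log-odds of a correct saccade in the reference
#' hemifield, testable against 0 = chance — repeated with both
#' hemifields as reference level, with parametric-bootstrap CIs for
#' all parameters. Tasks whose bootstrap CI (in either hemifield)
#' contains 0 are flagged as not above chance.
#'
#' @param data a [prepare_model_data()] frame.
#' @param re_terms random-effect terms (character); `NULL` to select
#'   them with [select_random_effects()].
#' @param n_boot bootstrap replicates (1,000 by default; use 10,000
#'   for final reported intervals).
#' @param seed integer seed.
#' @return Object of class `"fit_report"`: list with `response`,
#'   `re_terms`, `re_selection` (LRT table or `NULL`), `anova`
#'   (Type III table), `estimates` (per parameter and reference
#'   hemifield, with bootstrap CIs), `chance_tasks` (character),
#'   `separation` (tasks with 0/100% cells), `models`.
#' @export
fit_accuracy_model <- function(data, re_terms = NULL, n_boot = 1000,
                               seed = 1) {
  sel <- NULL
  if (is.null(re_terms)) {
    sel <- select_random_effects(data, "accuracy")
    re_terms <- sel$structure
  }
  cell_acc <- tapply(data$correct, list(data$task, data$target_position), mean)
  sep <- rownames(cell_acc)[apply(cell_acc, 1,
                                  function(r) any(r %in% c(0, 1)))]
  if (length(sep) > 0)
    warning("complete separation risk: task cell(s) at 0% or 100% ",
            "accuracy: ", paste(sep, collapse = ", "))
  anova <- type3_anova("correct", re_terms, data)
  fits <- no_intercept_fits("correct", re_terms, data)
  est <- boot_estimates(fits, n_boot, seed, levels(data$task))
  task_rows <- est[grepl("^task", est$parameter) &
                     !grepl(":", est$parameter), ]
  chance <- unique(sub("^task", "", task_rows$parameter[
    task_rows$ci_lo <= 0 & task_rows$ci_hi >= 0]))
  structure(list(response = "accuracy", re_terms = re_terms,
                 re_selection = if (is.null(sel)) NULL else sel$lrt,
                 anova = anova, estimates = est,
                 chance_tasks = chance, separation = sep,
                 models = fits, n_boot = n_boot, seed = seed),
            class = "fit_report")
}

#' Linear mixed model of log saccadic reaction times
#'
#' Fits the reaction-time workflow on correct trials only, with any
#' chance-level task removed: the response is `log(srt)` (the log
#' transform absorbs the right skew of SRT distributions), fixed and
#' random effects as in [fit_accuracy_model()]. Model comparisons
#' (random-effect selection, Type III analysis of deviance) use
#' maximum likelihood; the final estimates come from a REML refit.
#' Estimates and bootstrap CI bounds are reported both on the log-ms
#' scale and exponentiated (`exp_estimate`): a task coefficient
#' exponentiates to its mean SRT in ms in the reference hemifield, and
#' contrast-type coefficients to multiplicative ratios.
#'
#' @inheritParams fit_accuracy_model
#' @param exclude_tasks tasks to drop before fitting (typically those
#'   found at chance by the accuracy analysis).
#' @return A `"fit_report"` (see [fit_accuracy_model()]); `estimates`
#'   gains `exp_estimate`, `exp_ci_lo`, `exp_ci_hi`.
#' @export
fit_rt_model <- function(data, re_terms = NULL,
                         exclude_tasks = character(),
                         n_boot = 1000, seed = 1) {
  d <- data[data$correct & !(as.character(data$task) %in% exclude_tasks), ,
            drop = FALSE]
  if (nrow(d) == 0) stop("no correct trials left after exclusions")
  if (any(d$srt <= 0)) stop("non-positive SRTs: log transform undefined")
  d$task <- droplevels(d$task)
  d$target_image <- droplevels(d$target_image)
  d$distractor_image <- droplevels(d$distractor_image)
  sel <- NULL
  if (is.null(re_terms)) {
    sel <- select_random_effects(d, "rt")
    re_terms <- sel$structure
  }
  anova <- type3_anova("log(srt)", re_terms, d, reml = FALSE)
  fits <- no_intercept_fits("log(srt)", re_terms, d, reml = TRUE)
  est <- boot_estimates(fits, n_boot, seed, levels(d$task))
  est$exp_estimate <- exp(est$estimate)
  est$exp_ci_lo <- exp(est$ci_lo)
  est$exp_ci_hi <- exp(est$ci_hi)
  structure(list(response = "rt", re_terms = re_terms,
                 re_selection = if (is.null(sel)) NULL else sel$lrt,
                 anova = anova, estimates = est,
                 chance_tasks = character(0), separation = character(0),
                 models = fits, n_boot = n_boot, seed = seed,
                 excluded_tasks = exclude_tasks),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat("Mixed-effects fit report (", x$response, ")\n", sep = "")
  cat("Random effects:", paste(x$re_terms, collapse = ", "), "\n")
  cat("\nType III analysis of deviance:\n")
  print(x$anova, row.names = FALSE)
  cat("\nNo-intercept estimates with ", 100 * 0.95,
      "% parametric-bootstrap CIs (n_boot = ", x$n_boot, "):\n", sep = "")
  print(x$estimates, row.names = FALSE, digits = 4)
  if (length(x$chance_tasks) > 0)
    cat("\nTasks not above chance:", paste(x$chance_tasks, collapse = ", "),
        "\n")
  invisible(x)
}
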