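# Minimum reliably-accurate SRT: 10 ms left-inclusive latency bins,
# per-bin Monte Carlo chi-square tests of correct vs incorrect counts,
# and the five-consecutive-significant-bins rule.

#' Assign latencies to 10 ms bins
#'
#' Bins are left-inclusive and centred on multiples of 10: the bin
#' centred at `c` covers `[c - 5, c + 5)` ms, so e.g. the 120 ms bin
#' contains saccades launched between 115 and 124 ms.
#'
#' @param srt vector of saccadic reaction times, ms (>= 0).
#' @return Vector of bin centres (multiples of 10).
#' @examples
#' bin_srt(c(115, 124, 125))  # 120 120 130
#' @export
bin_srt <- function(srt) {
  if (any(is.na(srt)) || any(srt < 0)) stop("SRTs must be non-negative")
  10 * floor((srt + 5) / 10)
}

#' Monte Carlo chi-square test of a correct/incorrect split
#'
#' Tests the observed (correct, incorrect) counts against an equal
#' 50/50 split with the chi-square goodness-of-fit statistic, with the
#' null distribution obtained by Monte Carlo simulation of binomial
#' counts and the add-one p-value estimator
#' `p = (1 + #{simulated >= observed}) / (n_replications + 1)`,
#' which never returns exactly 0.
#'
#' @param n_correct,n_incorrect observed counts.
#' @param n_replications Monte Carlo replications (default 2000).
#' @param seed optional integer seed.
#' @return The Monte Carlo p-value (in (0, 1]); the observed statistic
#'   is attached as attribute `"statistic"`.
#' @export
mc_chisq_bin <- function(n_correct, n_incorrect, n_replications = 2000,
                         seed = NULL) {
  stopifnot(n_correct >= 0, n_incorrect >= 0, n_replications >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- n_correct + n_incorrect
  if (n == 0) {
    warning("empty bin: chi-square test undefined, returning p = 1")
    return(structure(1, statistic = NA_real_))
  }
  stat_obs <- (n_correct - n_incorrect)^2 / n
  sim <- stats::rbinom(n_replications, n, 0.5)
  stat_sim <- (2 * sim - n)^2 / n
  p <- (1 + sum(stat_sim >= stat_obs)) / (n_replications + 1)
  structure(p, statistic = stat_obs)
}

#' Minimum reliably accurate SRT for one task
#'
#' Bins the accepted trials' SRTs into 10 ms left-inclusive bins (from
#' the `min_srt_floor` bin up to the last bin containing data), tests
#' each bin with [mc_chisq_bin()], and flags a bin as significant when
#' `p < alpha` *and* correct trials outnumber incorrect ones (the
#' chi-square being two-sided). Empty bins are non-significant and
#' break runs. The minimum SRT is the centre of the first bin of the
#' first run of at least `run_length` consecutive significant bins, or
#' `NA` if no such run exists.
#'
#' @param results data frame of accepted trials for a single task,
#'   with columns `srt` (ms) and `correct` (logical).
#' @param alpha significance level per bin (default 0.05).
#' @param run_length required number of consecutive significant bins
#'   (default 5).
#' @param n_replications Monte Carlo replications per bin.
#' @param seed integer seed for the Monte Carlo tests.
#' @param min_srt_floor first bin centre scanned, ms (default 80, the
#'   trial-acceptance floor).
#' @return Object of class `"min_srt_result"`: list with `min_srt`
#'   (ms or `NA`), `bins` (data frame: `bin_center`, `n_correct`,
#'   `n_incorrect`, `p_value`, `significant`), `alpha`,
#'   `run_length`, `n_replications`.
#' @export
minimum_srt <- function(results, alpha = 0.05, run_length = 5,
                        n_replications = 2000, seed = 1,
                        min_srt_floor = 80) {
  stopifnot(nrow(results) > 0, all(c("srt", "correct") %in% names(results)))
  set.seed(as.integer(seed))
  centers_obs <- bin_srt(results$srt)
  centers <- seq(min_srt_floor, max(centers_obs), by = 10)
  bins <- data.frame(bin_center = centers)
  bins$n_correct <- vapply(centers, function(ct)
    sum(centers_obs == ct & results$correct), numeric(1))
  bins$n_incorrect <- vapply(centers, function(ct)
    sum(centers_obs == ct & !results$correct), numeric(1))
  bins$p_value <- NA_real_
  bins$significant <- FALSE
  for (i in seq_len(nrow(bins))) {
    if (bins$n_correct[i] + bins$n_incorrect[i] == 0) {
      bins$p_value[i] <- 1
      next
    }
    p <- as.numeric(mc_chisq_bin(bins$n_correct[i], bins$n_incorrect[i],
                                 n_replications = n_replications))
    bins$p_value[i] <- p
    bins$significant[i] <- p < alpha && bins$n_correct[i] > bins$n_incorrect[i]
  }
  min_srt <- NA_real_
  run <- rle(bins$significant)
  ends <- cumsum(run$lengths)
  hit <- which(run$values & run$lengths >= run_length)
  if (length(hit) > 0)
    min_srt <- bins$bin_center[ends[hit[1]] - run$lengths[hit[1]] + 1]
  structure(list(min_srt = min_srt, bins = bins, alpha = alpha,
                 run_length = run_length, n_replications = n_replications),
            class = "min_srt_result")
}

#' @export
print.min_srt_result <- function(x, ...) {
  cat("Minimum reliably accurate SRT:",
      if (is.na(x$min_srt)) "none (no run of significant bins)"
      else paste0(x$min_srt, " ms"), "\n")
  cat("  ", sum(x$bins$significant), "of", nrow(x$bins),
      "bins significant at alpha =", x$alpha,
      "(run length", x$run_length, ")\n")
  invisible(x)
}

#' Condition summary table (accuracy and mean SRT)
#'
#' Summarizes accepted trials per task and target hemifield (plus an
#' overall row per task): percent-correct accuracy and mean SRT. By
#' convention the mean SRT uses correct trials only (set
#' `srt_trials = "all"` to include errors) and is suppressed (`NA`)
#' for tasks listed in `chance_tasks`, i.e. tasks whose accuracy the
#' inference workflow found not to exceed chance.
#'
#' @param results data frame of accepted trials with columns `task`,
#'   `target_hemifield`, `correct`, `srt`.
#' @param chance_tasks character vector of tasks at chance accuracy.
#' @param srt_trials `"correct"` (default) or `"all"`.
#' @return Data frame with columns `task`, `target_position`
#'   (`"overall"`, `"left"`, `"right"`), `n`, `accuracy` (percent),
#'   `mean_srt` (ms or `NA`).
#' @export
summarize_conditions <- function(results, chance_tasks = character(),
                                 srt_trials = c("correct", "all")) {
  srt_trials <- match.arg(srt_trials)
  stopifnot(all(c("task", "target_hemifield", "correct", "srt")
                %in% names(results)))
  one <- function(df, task, pos) {
    rt <- if (srt_trials == "correct") df$srt[df$correct] else df$srt
    data.frame(task = task, target_position = pos, n = nrow(df),
               accuracy = 100 * mean(df$correct),
               mean_srt = if (task %in% chance_tasks || nrow(df) == 0)
                 NA_real_ else mean(rt),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(split(results, results$task), function(df) {
    task <- df$task[1]
    rbind(one(df, task, "overall"),
          one(df[df$target_hemifield == "left", ], task, "left"),
          one(df[df$target_hemifield == "right", ], task, "right"))
  }))
  rownames(out) <- NULL
  out
}
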