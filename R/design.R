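#' @keywords internal
"_PACKAGE"

# Stimulus categories and the six ordered (target, distractor) tasks.
SACC_CATEGORIES <- c("FamiliarFace", "UnknownFace", "Object")

#' Names of the six target-vs-distractor tasks
#'
#' Every ordered pair of distinct stimulus categories defines one task,
#' written `"<target>_vs_<distractor>"` (e.g.
#' `"FamiliarFace_vs_UnknownFace"`: familiar-face targets with
#' unknown-face distractors).
#'
#' @return Character vector of length 6.
#' @export
task_names <- function() {
  pairs <- expand.grid(distractor = SACC_CATEGORIES,
                       target = SACC_CATEGORIES,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$target != pairs$distractor, ]
  sort(paste0(pairs$target, "_vs_", pairs$distractor))
}

#' Image identifiers for one category
#'
#' Each category has nine images: three identities photographed in
#' three head orientations.
#'
#' @param category one of `"FamiliarFace"`, `"UnknownFace"`, `"Object"`.
#' @return Character vector of 9 image IDs.
#' @export
image_ids <- function(category) {
  category <- match.arg(category, SACC_CATEGORIES)
  as.vector(outer(paste0(category, "_id", 1:3), paste0("_or", 1:3), paste0))
}

#' Build a balanced saccadic-choice experimental design
#'
#' Generates the full trial list for `n_subjects` subjects. Each
#' subject runs 6 blocks, one per ordered (target category, distractor
#' category) pair, in a randomized order. Within a block every
#' combination of the 9 target images, 9 distractor images and 2 target
#' hemifields occurs exactly once (162 trials), in a seeded random
#' order, so each image is shown 18 times per block and exactly half
#' the trials have the target on the left. Each trial draws a fixation
#' duration uniformly from 800--1600 ms; the blank gap before stimulus
#' onset is 200 ms and the stimulus stays on for 400 ms.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param seed integer seed; the design is fully reproducible given it.
#' @return An object of class `"experiment_design"`: a list with
#'   element `trials` (a data frame with one row per trial: `subject`,
#'   `block`, `trial_index`, `task`, `target_category`,
#'   `distractor_category`, `target_hemifield`, `target_image`,
#'   `distractor_image`, `fixation_duration`, `blank_duration`,
#'   `stimulus_duration`) plus the design constants.
#' @examples
#' d <- build_design(1, seed = 1)
#' nrow(d$trials)            # 972
#' table(d$trials$block)     # 162 each
#' @export
build_design <- function(n_subjects, seed) {
  stopifnot(is.numeric(n_subjects), n_subjects >= 1, !is.na(seed))
  n_subjects <- as.integer(n_subjects)
  set.seed(as.integer(seed))

  tasks <- task_names()
  per_subject <- lapply(seq_len(n_subjects), function(s) {
    block_tasks <- sample(tasks)
    blocks <- lapply(seq_along(block_tasks), function(b) {
      task <- block_tasks[b]
      parts <- strsplit(task, "_vs_", fixed = TRUE)[[1]]
      grid <- expand.grid(target_image = image_ids(parts[1]),
                          distractor_image = image_ids(parts[2]),
                          target_hemifield = c("left", "right"),
                          stringsAsFactors = FALSE)
      grid <- grid[sample.int(nrow(grid)), , drop = FALSE]
      data.frame(subject = sprintf("S%02d", s),
                 block = b,
                 task = task,
                 target_category = parts[1],
                 distractor_category = parts[2],
                 grid,
                 row.names = NULL,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, blocks)
    out$trial_index <- seq_len(nrow(out))
    out
  })
  trials <- do.call(rbind, per_subject)
  trials$fixation_duration <- round(stats::runif(nrow(trials), 800, 1600))
  trials$blank_duration <- 200
  trials$stimulus_duration <- 400
  cols <- c("subject", "block", "trial_index", "task", "target_category",
            "distractor_category", "target_hemifield", "target_image",
            "distractor_image", "fixation_duration", "blank_duration",
            "stimulus_duration")
  trials <- trials[, cols]
  rownames(trials) <- NULL
  structure(list(trials = trials,
                 n_subjects = n_subjects,
                 blocks_per_subject = 6L,
                 trials_per_block = 162L,
                 categories = SACC_CATEGORIES,
                 seed = as.integer(seed)),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Saccadic-choice experimental design\n")
  cat("  subjects:", x$n_subjects,
      " blocks/subject:", x$blocks_per_subject,
      " trials/block:", x$trials_per_block, "\n")
  cat("  total trials:", nrow(x$trials), "\n")
  invisible(x)
}
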