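#' Construct a trial design for a motion task
#'
#' Builds the factorial trial schedule of one task: per block, a fixed number
#' of repetitions of each (difficulty level x motion direction) cell plus
#' catch trials showing unambiguous motion. Defaults follow the study design:
#' 4 blocks of 9 x 2 x 2 + 2 = 38 trials, i.e. 152 trials per task. The
#' schedule is shuffled uniformly within block using the supplied seed.
#'
#' @param task `"motion_coherence"` (difficulty = coherence %, defaults 30
#'   and 75) or `"direction_integration"` (difficulty = direction SD in
#'   degrees, defaults 70 and 30; larger SD is harder).
#' @param blocks number of blocks.
#' @param repetitions repetitions per (difficulty x direction) cell per block.
#' @param catch catch trials per block.
#' @param difficulty_values named numeric vector `c(difficult = , easy = )`
#'   giving the physical difficulty values; defaults depend on `task`.
#' @param deadline response deadline in seconds.
#' @param rt_floor minimum credible RT in seconds (faster responses are
#'   excluded from modelling).
#' @param seed integer seed for the within-block shuffle.
#' @return A `trial_design` object: a list with the design settings and a
#'   `schedule` data.frame (columns `block`, `trial`, `difficulty`,
#'   `direction`, `difficulty_value`).
#' @examples
#' d <- build_design("motion_coherence", seed = 1)
#' nrow(d$schedule)  # 152
#' @export
build_design <- function(task = c("motion_coherence", "direction_integration"),
                         blocks = 4, repetitions = 9, catch = 2,
                         difficulty_values = NULL, deadline = 2.5,
                         rt_floor = 0.2, seed = 1) {
  task <- match.arg(task)
  stopifnot(blocks >= 0, repetitions >= 0, catch >= 0, rt_floor < deadline)
  if (is.null(difficulty_values)) {
    difficulty_values <- switch(task,
      motion_coherence      = c(difficult = 30, easy = 75),
      direction_integration = c(difficult = 70, easy = 30))
  }
  stopifnot(all(c("difficult", "easy") %in% names(difficulty_values)))
  one_block <- function() {
    cells <- expand.grid(difficulty = c("difficult", "easy"),
                         direction = c("left", "right"),
                         rep = seq_len(repetitions),
                         stringsAsFactors = FALSE)
    cells <- cells[, c("difficulty", "direction")]
    if (catch > 0) {
      cdir <- rep(c("left", "right"), length.out = catch)
      cells <- rbind(cells,
                     data.frame(difficulty = "catch", direction = cdir,
                                stringsAsFactors = FALSE))
    }
    cells
  }
  sched <- NULL
  rng <- local_rng(seed)
  for (b in seq_len(blocks)) {
    blk <- one_block()
    if (nrow(blk) > 0) {
      blk <- blk[sample.int(nrow(blk)), , drop = FALSE]
      blk$block <- b
      sched <- rbind(sched, blk)
    }
  }
  restore_rng(rng)
  if (is.null(sched)) {
    sched <- data.frame(difficulty = character(), direction = character(),
                        block = integer(), stringsAsFactors = FALSE)
  }
  sched$trial <- seq_len(nrow(sched))
  sched$difficulty_value <- ifelse(sched$difficulty == "catch", NA_real_,
                                   difficulty_values[sched$difficulty])
  rownames(sched) <- NULL
  structure(list(task = task, blocks = blocks, repetitions = repetitions,
                 catch = catch, difficulty_values = difficulty_values,
                 deadline = deadline, rt_floor = rt_floor, seed = seed,
                 schedule = sched[, c("block", "trial", "difficulty",
                                      "direction", "difficulty_value")]),
            class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf("Trial design: %s\n", x$task))
  cat(sprintf("  %d blocks x (%d reps x 2 difficulties x 2 directions + %d catch) = %d trials\n",
              x$blocks, x$repetitions, x$catch, nrow(x$schedule)))
  cat(sprintf("  deadline %.3g s, rt floor %.3g s\n", x$deadline, x$rt_floor))
  invisible(x)
}

# save/restore the global RNG so seeded helpers do not disturb callers
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}
restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Filter a trial table for modelling
#'
#' Marks implausibly fast responses (RT below `rt_floor`) as excluded
#' (retained in the table with a reason, not deleted) and no-response trials
#' as censored; censored trials stay in the likelihood through the survivor
#' function. Idempotent: re-filtering a filtered table changes nothing.
#'
#' @param trials a trial table (columns `participant`, `group`, `difficulty`,
#'   `direction`, `response`, `rt`; `response == "none"` marks timeouts).
#' @param rt_floor exclusion threshold in seconds.
#' @param deadline response deadline in seconds.
#' @return The table with logical columns `censored`, `excluded` and a
#'   character `exclude_reason`, plus an attribute `"exclusion_report"`:
#'   per-group percentages of excluded and censored trials.
#' @export
filter_trials <- function(trials, rt_floor = 0.2, deadline = 2.5) {
  stopifnot(rt_floor < deadline)
  need <- c("participant", "group", "difficulty", "response", "rt")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trial table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(trials$rt < 0, na.rm = TRUE))
    stop("corrupt input: negative RT", call. = FALSE)
  censored <- trials$response == "none"
  excluded <- !censored & !is.na(trials$rt) & trials$rt < rt_floor
  trials$censored <- censored
  trials$excluded <- excluded
  trials$exclude_reason <- ifelse(excluded, "rt_floor", NA_character_)
  rep <- aggregate(cbind(excluded = trials$excluded,
                         censored = trials$censored),
                   by = list(group = trials$group), FUN = mean)
  rep$excluded <- 100 * rep$excluded
  rep$censored <- 100 * rep$censored
  names(rep)[2:3] <- c("pct_excluded", "pct_censored")
  attr(trials, "exclusion_report") <- rep
  trials
}

#' Block efficiency score
#'
#' Points awarded for one block: `round((1 / median RT) * n_correct * 2)`,
#' floored at 10 so that participants are never demotivated by a very low
#' score. The median RT is taken over correct responded trials by default
#' (the score rewards speed and accuracy together); set
#' `median_over = "responded"` to use all responded trials.
#'
#' @param trials rows of a trial table for one block. Needs columns
#'   `response`, `direction`, `rt`.
#' @param median_over `"correct"` or `"responded"`.
#' @param floor minimum score.
#' @return Integer points.
#' @examples
#' blk <- data.frame(response = rep("left", 30), direction = rep("left", 30),
#'                   rt = rep(0.5, 30))
#' efficiency_score(blk)  # 120
#' @export
efficiency_score <- function(trials, median_over = c("correct", "responded"),
                             floor = 10) {
  median_over <- match.arg(median_over)
  if (nrow(trials) == 0L) stop("empty block", call. = FALSE)
  responded <- trials$response %in% c("left", "right")
  correct <- responded & trials$response == trials$direction
  n_correct <- sum(correct)
  rts <- if (median_over == "correct") trials$rt[correct]
         else trials$rt[responded]
  if (length(rts) == 0L || n_correct == 0L) return(as.integer(floor))
  raw <- round((1 / median(rts)) * n_correct * 2)
  as.integer(max(raw, floor))
}

#' Permute group labels for blind modelling
#'
#' Randomly permutes group membership at the participant level (every trial
#' of a participant receives the same permuted label), storing the original
#' labels as an unblinding key. Group sizes are preserved.
#'
#' @param trials a trial table with `participant` and `group` columns.
#' @param seed integer seed.
#' @return The table with permuted `group`; the attribute
#'   `"unblinding_key"` is a data.frame mapping `participant` to the true
#'   and blinded labels.
#' @export
blind_labels <- function(trials, seed) {
  ids <- unique(trials$participant)
  if (length(ids) < 2L) stop("need at least 2 participants", call. = FALSE)
  true_lab <- trials$group[match(ids, trials$participant)]
  rng <- local_rng(seed)
  perm <- sample.int(length(ids))
  restore_rng(rng)
  blind_lab <- true_lab[perm]
  key <- data.frame(participant = ids, group_true = true_lab,
                    group_blinded = blind_lab, stringsAsFactors = FALSE)
  trials$group <- blind_lab[match(trials$participant, ids)]
  attr(trials, "unblinding_key") <- key
  trials
}

#' Restore true group labels after blind modelling
#'
#' @param trials a table returned by [blind_labels()].
#' @param key an unblinding key; defaults to the one stored on `trials`.
#' @return The table with original group labels.
#' @export
unblind_labels <- function(trials, key = attr(trials, "unblinding_key")) {
  if (is.null(key)) stop("no unblinding key available", call. = FALSE)
  trials$group <- key$group_true[match(trials$participant, key$participant)]
  attr(trials, "unblinding_key") <- NULL
  trials
}

#' Read / write a trial table as CSV
#'
#' Column dictionary: `participant` (id), `group` (label), `task`, `block`,
#' `trial`, `difficulty` (`difficult`/`easy`/`catch`), `direction`
#' (`left`/`right`), `response` (`left`/`right`/`none`), `rt` (seconds, NA
#' for no response), `censored`, `excluded`, `exclude_reason`.
#'
#' @param trials a trial table.
#' @param path file path.
#' @return `read_trials` returns a data.frame; `write_trials` returns the
#'   path invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
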