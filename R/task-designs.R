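#' @useDynLib affbias, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom qnorm pnorm dnorm cor cor.test
#'   sd var aggregate approx integrate pf qf pt t.test complete.cases setNames
#' @importFrom utils read.csv write.csv head
NULL

GNG_CUES <- c("go_to_win", "nogo_to_win", "go_to_avoid", "nogo_to_avoid")
AM_SIZES <- c("small", "mid", "large")

#' Generate a go/no-go task schedule
#'
#' Builds the interleaved four-cue schedule: by default 160 trials, each of
#' the four fractal cues (go-to-win, no-go-to-win, go-to-avoid,
#' no-go-to-avoid) appearing 40 times in a seeded random order.  Feedback is
#' probabilistic: on a veridical trial the correct response (go or no-go,
#' fixed by the cue) is followed by the associated feedback; on the remaining
#' trials feedback is misleading.  The veridical trials are scheduled as an
#' exact per-cue proportion (32 of 40 at the default 0.8) and then shuffled,
#' so design counts are exact for every seed; set `iid = TRUE` for
#' independent Bernoulli sampling instead.
#'
#' @param seed integer seed; the same seed always yields the same schedule.
#' @param n_per_cue trials per cue type (default 40).
#' @param veridical_prop proportion of trials per cue with veridical feedback
#'   (default 0.8).
#' @param iid if `TRUE`, veridical flags are i.i.d. Bernoulli(`veridical_prop`)
#'   rather than an exact shuffled proportion.
#' @return A `gonogo_schedule` data frame with columns `trial` (0-based),
#'   `cue_type`, `correct_action`, `veridical`, `circle_side`.
#' @export
generate_gonogo_schedule <- function(seed, n_per_cue = 40, veridical_prop = 0.8,
                                     iid = FALSE) {
  stopifnot(n_per_cue >= 1, veridical_prop > 0, veridical_prop <= 1)
  n_ver_raw <- n_per_cue * veridical_prop
  n_ver <- round(n_ver_raw)
  if (abs(n_ver_raw - n_ver) > 1e-9)
    message(sprintf("veridical count %.3f per cue rounded to %d", n_ver_raw, n_ver))
  withr_seed(seed, {
    per_cue <- lapply(GNG_CUES, function(cue) {
      ver <- if (iid) runif(n_per_cue) < veridical_prop
             else sample(rep(c(TRUE, FALSE), c(n_ver, n_per_cue - n_ver)))
      data.frame(cue_type = cue, veridical = ver)
    })
    sched <- do.call(rbind, per_cue)
    sched <- sched[sample.int(nrow(sched)), , drop = FALSE]
    sched$circle_side <- sample(c("left", "right"), nrow(sched), replace = TRUE)
  })
  sched$correct_action <- ifelse(sched$cue_type %in% c("go_to_win", "go_to_avoid"),
                                 "go", "nogo")
  sched <- data.frame(trial = seq_len(nrow(sched)) - 1L,
                      cue_type = sched$cue_type,
                      correct_action = sched$correct_action,
                      veridical = sched$veridical,
                      circle_side = sched$circle_side,
                      row.names = NULL)
  structure(sched, class = c("gonogo_schedule", "data.frame"), seed = seed)
}

#' Go/no-go feedback rule
#'
#' Pure function mapping a trial and an action to a points outcome.  Win cues
#' pay +10 or 0; avoid cues pay 0 or -10.  The associated (better) feedback
#' is delivered iff the action is correct XOR the trial is non-veridical.
#'
#' @param trial one row of a [generate_gonogo_schedule()] schedule (or any
#'   list with `cue_type` and `veridical`).
#' @param action `"go"` or `"nogo"`.
#' @return points: one of +10, 0, -10.
#' @export
gonogo_feedback <- function(trial, action) {
  cue <- as.character(trial$cue_type)
  stopifnot(cue %in% GNG_CUES, action %in% c("go", "nogo"))
  correct <- if (cue %in% c("go_to_win", "go_to_avoid")) "go" else "nogo"
  assoc <- xor(action == correct, !trial$veridical)
  if (cue %in% c("go_to_win", "nogo_to_win")) {
    if (assoc) 10 else 0
  } else {
    if (assoc) 0 else -10
  }
}

#' Generate an ambiguous-midpoint task schedule
#'
#' Builds the training phase (20 trials by default, alternating small/large in
#' a seeded random order with exactly 10 of each) and the main task (by
#' default 120 trials: 40 small, 40 mid, 40 large, seeded order).  Small and
#' large circles always reward their trained key ($1 for the low key, $4 for
#' the high key); the ambiguous mid circle rewards the high key on exactly
#' half of its trials.  The task shows the same randomized order to every
#' participant, so one seeded schedule is shared across a cohort.
#'
#' @param seed integer seed.
#' @param n_training number of training trials (default 20; equal small/large
#'   split).
#' @param n_per_size main-task trials per circle size (default 40; must be
#'   even so the mid 50/50 reward split is exact).
#' @return An `am_schedule` list with data frames `training` and `main`, each
#'   with columns `trial` (0-based), `circle_size`, `rewarded_key`,
#'   `reward_magnitude`.
#' @export
generate_am_schedule <- function(seed, n_training = 20, n_per_size = 40) {
  stopifnot(n_training >= 1, n_per_size >= 1)
  if (n_per_size %% 2 != 0)
    stop("n_per_size must be even so mid trials can be rewarded 50/50")
  n_half_tr <- floor(n_training / 2)
  withr_seed(seed, {
    tr_sizes <- sample(rep(c("small", "large"), c(n_half_tr, n_training - n_half_tr)))
    mid_high <- sample(rep(c(TRUE, FALSE), each = n_per_size / 2))
    main <- data.frame(
      circle_size = c(rep("small", n_per_size), rep("large", n_per_size),
                      rep("mid", n_per_size)),
      rewarded_key = c(rep("key_low", n_per_size), rep("key_high", n_per_size),
                       ifelse(mid_high, "key_high", "key_low")))
    main <- main[sample.int(nrow(main)), , drop = FALSE]
  })
  training <- data.frame(trial = seq_len(n_training) - 1L,
                         circle_size = tr_sizes,
                         rewarded_key = ifelse(tr_sizes == "large", "key_high", "key_low"))
  training$reward_magnitude <- ifelse(training$rewarded_key == "key_high", 4, 1)
  main <- data.frame(trial = seq_len(nrow(main)) - 1L,
                     circle_size = main$circle_size,
                     rewarded_key = main$rewarded_key,
                     row.names = NULL)
  main$reward_magnitude <- ifelse(main$rewarded_key == "key_high", 4, 1)
  structure(list(training = training, main = main, seed = seed),
            class = "am_schedule")
}

#' Ambiguous-midpoint feedback rule
#'
#' Reward is delivered iff the pressed key equals the trial's scheduled
#' rewarded key; the magnitude follows the key's trained association ($4 for
#' the high key, $1 for the low key).  Otherwise the trial times out.
#'
#' @param trial one row of an [generate_am_schedule()] schedule.
#' @param pressed_key `"key_low"` or `"key_high"`.
#' @return one of `"win_1"`, `"win_4"`, `"timeout_incorrect"`.
#' @export
am_feedback <- function(trial, pressed_key) {
  stopifnot(pressed_key %in% c("key_low", "key_high"))
  if (pressed_key == as.character(trial$rewarded_key)) {
    if (pressed_key == "key_high") "win_4" else "win_1"
  } else {
    "timeout_incorrect"
  }
}

#' Write a task schedule to CSV
#'
#' Flat export with columns `task`, `trial_index` (0-based), `condition`,
#' `correct_action_or_rewarded_key`, `veridical`, `extra` (circle side or
#' reward magnitude).
#'
#' @param schedule a `gonogo_schedule` or `am_schedule`.
#' @param path output CSV path.
#' @return the written data frame, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  if (inherits(schedule, "gonogo_schedule")) {
    out <- data.frame(task = "gonogo", trial_index = schedule$trial,
                      condition = schedule$cue_type,
                      correct_action_or_rewarded_key = schedule$correct_action,
                      veridical = schedule$veridical,
                      extra = schedule$circle_side)
  } else if (inherits(schedule, "am_schedule")) {
    both <- rbind(cbind(schedule$training, phase = "training"),
                  cbind(schedule$main, phase = "main"))
    out <- data.frame(task = paste0("ambiguous_midpoint_", both$phase),
                      trial_index = both$trial,
                      condition = both$circle_size,
                      correct_action_or_rewarded_key = both$rewarded_key,
                      veridical = NA,
                      extra = both$reward_magnitude)
  } else stop("unknown schedule class")
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}
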