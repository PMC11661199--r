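# Summary-statistic indices of affective bias and the participant-exclusion
# filters applied before any reliability analysis.

#' Per-condition accuracies for a go/no-go session
#'
#' Accuracy counts go responses on go cues and withheld responses on no-go
#' cues; denominators are the per-cue trial counts.  A trial without a
#' keypress is a no-go choice (the task's action space is respond /
#' don't-respond), so denominators are never reduced.
#'
#' @param session go/no-go session data frame (`condition`, `choice`).
#' @return named vector: `acc_go_to_win`, `acc_nogo_to_win`,
#'   `acc_go_to_avoid`, `acc_nogo_to_avoid`.
#' @export
condition_accuracies <- function(session) {
  missing <- setdiff(GNG_CUES, unique(as.character(session$condition)))
  if (length(missing) > 0)
    stop("session is missing cue type(s): ", paste(missing, collapse = ", "))
  acc <- vapply(GNG_CUES, function(cue) {
    d <- session[session$condition == cue, ]
    correct <- if (cue %in% c("go_to_win", "go_to_avoid")) "go" else "nogo"
    mean(d$choice == correct)
  }, 0)
  setNames(acc, paste0("acc_", GNG_CUES))
}

#' Proportion of high-reward responses to the ambiguous circle
#'
#' p(high|mid): among mid trials with a response, the fraction answered with
#' the key associated with the larger reward.  1 - p(high|mid) is the
#' negative-affective-bias reading.  If no mid trial was responded to the
#' index is undefined and `NA` is returned (never 0).
#'
#' @param session ambiguous-midpoint session data frame (`condition`,
#'   `choice`; `NA` choice = no response).
#' @return proportion in `[0, 1]`, or `NA` if undefined.
#' @export
p_high_given_mid <- function(session) {
  mid <- session[session$condition == "mid", ]
  if (nrow(mid) < 1) stop("session has no mid trials")
  responded <- mid[!is.na(mid$choice), ]
  if (nrow(responded) == 0) return(NA_real_)
  mean(responded$choice == "key_high")
}

#' Summary-statistic table for a cohort
#'
#' One row per subject-session with the five affective-bias indices (four
#' go/no-go condition accuracies and p(high|mid)) and their denominators;
#' indices for the task a cohort lacks are `NA`.
#'
#' @param trials trials data frame (`subject`, `session`, `task`,
#'   `condition`, `choice`, ...) or a `cohort_data` object.
#' @return data frame of per-session summaries.
#' @export
session_summaries <- function(trials) {
  if (inherits(trials, "cohort_data")) trials <- trials$trials
  do.call(rbind, lapply(
    split(trials, list(trials$subject, trials$session), drop = TRUE),
    function(d) {
      row <- data.frame(subject = d$subject[1], session = d$session[1],
                        acc_go_to_win = NA_real_, acc_nogo_to_win = NA_real_,
                        acc_go_to_avoid = NA_real_, acc_nogo_to_avoid = NA_real_,
                        p_high_mid = NA_real_, n_gng = 0L, n_mid_responded = 0L)
      gng <- d[d$task == "gonogo", ]
      if (nrow(gng) > 0) {
        acc <- condition_accuracies(gng)
        row[names(acc)] <- as.list(acc)
        row$n_gng <- nrow(gng)
      }
      am <- d[d$task == "ambiguous_midpoint", ]
      if (nrow(am) > 0) {
        row$p_high_mid <- p_high_given_mid(am)
        row$n_mid_responded <- sum(am$condition == "mid" & !is.na(am$choice))
      }
      rownames(row) <- NULL
      row
    })) -> out
  rownames(out) <- NULL
  out[order(out$session, out$subject), ]
}

#' Apply the study's participant-exclusion rules
#'
#' A subject is removed iff any rule fires in either session:
#' zero accuracy on go-to-win trials; no responses at all in a task;
#' only one response key used in the ambiguous-midpoint task; never the
#' high-reward key on mid trials; duplicated (subject, session, trial) rows
#' (data that cannot be modelled).
#'
#' @param cohort a `cohort_data` object or a trials data frame.
#' @return list: `trials` (filtered), `report` (one row per subject:
#'   `subject`, `excluded`, `reasons`).
#' @export
apply_exclusions <- function(cohort) {
  trials <- if (inherits(cohort, "cohort_data")) cohort$trials else cohort
  report <- do.call(rbind, lapply(split(trials, trials$subject), function(d) {
    reasons <- character(0)
    key <- paste(d$session, d$task, d$trial)
    if (anyDuplicated(key)) reasons <- c(reasons, "duplicate_trials")
    for (ses in unique(d$session)) {
      ds <- d[d$session == ses, ]
      gng <- ds[ds$task == "gonogo", ]
      if (nrow(gng) > 0) {
        gtw <- gng[gng$condition == "go_to_win", ]
        if (nrow(gtw) > 0 && !any(gtw$choice == "go", na.rm = TRUE))
          reasons <- c(reasons, "zero_go_to_win_accuracy")
        if (!any(gng$choice == "go", na.rm = TRUE))
          reasons <- c(reasons, "no_responses_any_task")
      }
      am <- ds[ds$task == "ambiguous_midpoint", ]
      if (nrow(am) > 0) {
        resp <- am$choice[!is.na(am$choice)]
        if (length(resp) == 0)
          reasons <- c(reasons, "no_responses_any_task")
        else if (length(unique(resp)) == 1)
          reasons <- c(reasons, "single_key_am")
        mid <- am[am$condition == "mid" & !is.na(am$choice), ]
        if (nrow(am[am$condition == "mid", ]) > 0 &&
            !any(mid$choice == "key_high"))
          reasons <- c(reasons, "never_high_on_mid")
      }
    }
    reasons <- unique(reasons)
    data.frame(subject = d$subject[1], excluded = length(reasons) > 0,
               reasons = paste(reasons, collapse = ";"))
  }))
  rownames(report) <- NULL
  keep <- report$subject[!report$excluded]
  list(trials = trials[trials$subject %in% keep, , drop = FALSE],
       report = report)
}
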