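# Two-session synthetic cohorts with known generating parameters and a known
# cross-session correlation per parameter.  The correlation is induced on the
# unconstrained scale -- where the hierarchical and embedded models assume
# normality -- and then mapped to the native scale through the same links the
# models use.

#' Default generating distributions for a task's parameters
#'
#' Group means and sds on the unconstrained scale, centred on plausible
#' values from the task literatures (moderate learning rate, small lapse,
#' positive Pavlovian biases and outcome sensitivities around 4 for the
#' go/no-go learner; boundary near 1.5, unbiased start, mildly optimistic
#' drift and 300 ms non-decision time for the diffusion model).  These are
#' configuration defaults, not estimates.
#'
#' @param task `"gonogo"` or `"ambiguous_midpoint"`.
#' @return data frame: `parameter`, `link`, `mean`, `sd` (unconstrained scale).
#' @export
default_group_params <- function(task = c("gonogo", "ambiguous_midpoint")) {
  task <- match.arg(task)
  if (task == "gonogo") {
    data.frame(
      parameter = GNG_PARAM_NAMES,
      link = c("probit", "identity", "identity", "identity", "log", "log",
               "probit"),
      mean = c(qnorm(0.2), 0.3, 0.5, 0.5, log(4), log(4), qnorm(0.05)),
      sd = c(0.5, 0.5, 0.5, 0.5, 0.4, 0.4, 0.4))
  } else {
    data.frame(
      parameter = c("alpha", "beta", "delta", "tau"),
      link = c("log", "probit", "identity", "log"),
      mean = c(log(1.5), 0, 0.5, log(0.3)),
      sd = c(0.25, 0.3, 0.8, 0.15))
  }
}

#' Cohort configuration
#'
#' @param task `"gonogo"` or `"ambiguous_midpoint"`.
#' @param n_subjects cohort size (default 58, the study's analysed sample).
#' @param group_params data frame as returned by [default_group_params()]
#'   (columns `parameter`, `link`, `mean`, `sd` on the unconstrained scale).
#' @param cross_session_r cross-session correlation per parameter on the
#'   unconstrained scale; a single value is recycled (default 0.7).
#' @param seed integer master seed; all cohort randomness derives from it.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(task = c("gonogo", "ambiguous_midpoint"),
                          n_subjects = 58,
                          group_params = default_group_params(task),
                          cross_session_r = 0.7,
                          seed = 1) {
  task <- match.arg(task)
  stopifnot(n_subjects >= 1, all(group_params$sd > 0),
            all(abs(cross_session_r) <= 1))
  r <- rep_len(cross_session_r, nrow(group_params))
  structure(list(task = task, n_subjects = n_subjects,
                 group_params = group_params, cross_session_r = r,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Sample paired (session 1, session 2) subject parameters
#'
#' For each parameter the subject's pair is drawn from a bivariate normal on
#' the unconstrained scale with the configured correlation, then mapped to
#' the native scale (inverse-probit for probability-type parameters,
#' exponential for positive ones).
#'
#' @param config a [cohort_config()].
#' @return data frame: `subject`, `parameter`, `session1`, `session2`
#'   (native scale); the unconstrained pairs are attached as attribute
#'   `"unconstrained"`.
#' @export
sample_paired_params <- function(config) {
  gp <- config$group_params
  n <- config$n_subjects
  subj <- sprintf("s%03d", seq_len(n))
  withr_seed(config$seed, {
    rows <- lapply(seq_len(nrow(gp)), function(p) {
      r <- config$cross_session_r[p]
      z1 <- rnorm(n)
      z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
      t1 <- gp$mean[p] + gp$sd[p] * z1
      t2 <- gp$mean[p] + gp$sd[p] * z2
      to_native <- switch(gp$link[p], probit = pnorm, log = exp,
                          identity = identity)
      data.frame(subject = subj, parameter = gp$parameter[p],
                 session1 = to_native(t1), session2 = to_native(t2),
                 u1 = t1, u2 = t2)
    })
  })
  out <- do.call(rbind, rows)
  uncons <- out[c("subject", "parameter", "u1", "u2")]
  out$u1 <- NULL; out$u2 <- NULL
  attr(out, "unconstrained") <- uncons
  out
}

#' Simulate one go/no-go agent on a schedule
#'
#' Choices are sampled trial by trial from the model's p(go)
#' ([gng_p_go()]), feedback follows the schedule's veridical flags
#' ([gonogo_feedback()]), and the latent state is updated after each outcome
#' ([gng_update_state()]).
#'
#' @param params a [gng_params()] vector.
#' @param schedule a [generate_gonogo_schedule()] schedule.
#' @param seed integer seed for the choice draws.
#' @return session data frame: `trial`, `condition`, `choice`, `rt` (NA for
#'   this task), `outcome` (points).
#' @export
simulate_gng_agent <- function(params, schedule, seed) {
  n <- nrow(schedule)
  withr_seed(seed, u <- runif(n))
  cue <- match(as.character(schedule$cue_type), GNG_CUES)
  sim <- .gng_simulate(unclass(params)[GNG_PARAM_NAMES], as.integer(cue),
                       as.integer(schedule$veridical), u)
  data.frame(trial = schedule$trial,
             condition = as.character(schedule$cue_type),
             choice = ifelse(sim$choice == 1, "go", "nogo"),
             rt = NA_real_,
             outcome = 10 * sim$outcome)
}

#' Simulate one diffusion agent on an ambiguous-midpoint schedule
#'
#' Mid-trial choices and RTs are exact draws from the first-passage
#' distribution of the Wiener process (upper boundary = high-reward key)
#' plus the non-decision time.  Small/large trials -- nearly deterministic
#' after training -- are simulated from the same diffusion with the drift
#' magnitude replaced by `trained_drift` toward the trained key.
#'
#' @param params a [ddm_params()] vector (governs the mid trials).
#' @param schedule an [generate_am_schedule()] schedule (main phase used).
#' @param seed integer seed.
#' @param trained_drift drift magnitude on small/large trials (default 3).
#' @return session data frame: `trial`, `condition`, `choice`, `rt`,
#'   `outcome` (reward in dollars: 0, 1 or 4).
#' @export
simulate_ddm_agent <- function(params, schedule, seed, trained_drift = 3) {
  main <- schedule$main
  n <- nrow(main)
  withr_seed(seed, {
    mid_idx <- which(main$circle_size == "mid")
    draws_mid <- rwiener_fp(length(mid_idx), params)
    up_small <- ddm_params(params[["alpha"]], params[["beta"]],
                           -trained_drift, params[["tau"]])
    up_large <- ddm_params(params[["alpha"]], params[["beta"]],
                           trained_drift, params[["tau"]])
    small_idx <- which(main$circle_size == "small")
    large_idx <- which(main$circle_size == "large")
    draws_small <- rwiener_fp(length(small_idx), up_small)
    draws_large <- rwiener_fp(length(large_idx), up_large)
  })
  choice <- character(n); rt <- numeric(n)
  put <- function(idx, d) {
    choice[idx] <<- ifelse(d$boundary == "upper", "key_high", "key_low")
    rt[idx] <<- d$rt
  }
  put(mid_idx, draws_mid); put(small_idx, draws_small); put(large_idx, draws_large)
  fb <- ifelse(choice == main$rewarded_key,
               ifelse(choice == "key_high", 4, 1), 0)
  data.frame(trial = main$trial, condition = main$circle_size,
             choice = choice, rt = rt, outcome = fb)
}

#' Simulate a full two-session cohort
#'
#' Draws paired subject parameters via [sample_paired_params()], simulates
#' every subject on both sessions' schedules, and keeps the generating
#' parameters alongside for recovery scoring.
#'
#' @param config a [cohort_config()].
#' @param schedules list with elements `session1` and `session2` (task
#'   schedules); by default generated from the config seed.  The
#'   ambiguous-midpoint schedule is shared across subjects within a session,
#'   as in the task design.
#' @return a `cohort_data` list: `trials` (subject, session, task, trial,
#'   condition, choice, rt, outcome), `true_params`, `config`, `schedules`.
#' @export
simulate_cohort <- function(config, schedules = NULL) {
  if (is.null(schedules)) {
    gen <- if (config$task == "gonogo") generate_gonogo_schedule
           else generate_am_schedule
    schedules <- list(session1 = gen(config$seed + 101L),
                      session2 = gen(config$seed + 202L))
  }
  pars <- sample_paired_params(config)
  subj <- unique(pars$subject)
  withr_seed(config$seed + 7L,
             sub_seeds <- matrix(sample.int(.Machine$integer.max - 1,
                                            2 * length(subj)),
                                 ncol = 2))
  task_label <- config$task
  rows <- vector("list", 2 * length(subj))
  k <- 0
  for (i in seq_along(subj)) {
    for (ses in 1:2) {
      pv <- setNames(pars[pars$subject == subj[i],
                          c("session1", "session2")[ses]],
                     pars$parameter[pars$subject == subj[i]])
      sched <- schedules[[ses]]
      ses_df <- if (config$task == "gonogo") {
        simulate_gng_agent(do.call(gng_params, as.list(pv)), sched,
                           sub_seeds[i, ses])
      } else {
        simulate_ddm_agent(do.call(ddm_params, as.list(pv)), sched,
                           sub_seeds[i, ses])
      }
      k <- k + 1
      rows[[k]] <- cbind(subject = subj[i], session = ses, task = task_label,
                         ses_df)
    }
  }
  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL
  structure(list(trials = trials, true_params = pars, config = config,
                 schedules = schedules),
            class = "cohort_data")
}
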