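# Readers/writers and the end-to-end orchestrator: simulate -> exclude ->
# summarise -> two-stage reliability -> (optionally) fit, transfer and embed.

TRIALS_COLS <- c("subject", "session", "task", "trial", "condition", "choice",
                 "rt", "outcome")

#' Read a trials table
#'
#' CSV with columns subject, session, task, trial (0-based), condition,
#' choice, rt (seconds; may be empty for go/no-go rows), outcome.  Malformed
#' rows and duplicate (subject, session, task, trial) keys are reported with
#' their line numbers.
#'
#' @param path CSV path.
#' @return validated trials data frame.
#' @export
read_trials <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(TRIALS_COLS, names(d))
  if (length(missing) > 0)
    stop("trials file is missing column(s): ", paste(missing, collapse = ", "))
  bad <- which(is.na(d$subject) | is.na(d$session) | is.na(d$trial) |
                 is.na(d$task))
  if (length(bad) > 0)
    stop("malformed rows (missing keys) at line(s): ",
         paste(bad + 1, collapse = ", "))
  key <- paste(d$subject, d$session, d$task, d$trial)
  dup <- which(duplicated(key))
  if (length(dup) > 0)
    stop("duplicate (subject, session, task, trial) keys at line(s): ",
         paste(dup + 1, collapse = ", "))
  # an all-missing rt column (go/no-go data) must still be numeric
  d$rt <- as.numeric(d$rt)
  d$outcome <- as.numeric(d$outcome)
  d
}

#' Write a trials table
#'
#' @param x a `cohort_data` object or a trials data frame.
#' @param path CSV path.
#' @return the written data frame, invisibly.
#' @export
write_trials <- function(x, path) {
  d <- if (inherits(x, "cohort_data")) x$trials else x
  stopifnot(all(TRIALS_COLS %in% names(d)))
  write.csv(d[TRIALS_COLS], path, row.names = FALSE)
  invisible(d[TRIALS_COLS])
}

#' Pipeline configuration
#'
#' All seeds are explicit; the configuration round-trips losslessly through
#' YAML ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param task `"gonogo"` or `"ambiguous_midpoint"`.
#' @param n_subjects cohort size.
#' @param cross_session_r generating cross-session correlation.
#' @param seed master seed.
#' @param exclusions apply participant-exclusion rules.
#' @param fit_models run hierarchical fits, transfer and embedded stages.
#' @param chains,warmup,iter MCMC settings for all fits.
#' @param model_id go/no-go family member for model-based stages.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(task = "gonogo", n_subjects = 58,
                            cross_session_r = 0.7, seed = 1,
                            exclusions = TRUE, fit_models = FALSE,
                            chains = 2, warmup = 500, iter = 500,
                            model_id = "rw_b_pavsep_rhosep") {
  structure(list(task = task, n_subjects = n_subjects,
                 cross_session_r = cross_session_r, seed = as.integer(seed),
                 exclusions = exclusions, fit_models = fit_models,
                 chains = chains, warmup = warmup, iter = iter,
                 model_id = model_id),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(config)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Simulates a two-session cohort, applies exclusions, computes summary
#' statistics and the two-stage reliability table, and (when
#' `fit_models = TRUE`) the hierarchical fits, posterior-predictive transfer
#' tests and the embedded-correlation comparison.  Every table is written as
#' CSV to `out_dir`, with a JSON manifest recording the configuration and
#' seeds.  A stage failure aborts with the stage name; artifacts written up
#' to that point are kept.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @return (invisibly) a list of the produced tables.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  results <- list()

  cohort <- stage("simulate", {
    cc <- cohort_config(task = config$task, n_subjects = config$n_subjects,
                        cross_session_r = config$cross_session_r,
                        seed = config$seed)
    simulate_cohort(cc)
  })
  write_trials(cohort, file.path(out_dir, "trials.csv"))
  write.csv(cohort$true_params, file.path(out_dir, "true_params.csv"),
            row.names = FALSE)

  excl <- stage("exclusions", {
    if (config$exclusions) apply_exclusions(cohort)
    else list(trials = cohort$trials,
              report = data.frame(subject = unique(cohort$trials$subject),
                                  excluded = FALSE, reasons = ""))
  })
  write.csv(excl$report, file.path(out_dir, "exclusion_report.csv"),
            row.names = FALSE)
  trials <- excl$trials

  summaries <- stage("summaries", session_summaries(trials))
  write.csv(summaries, file.path(out_dir, "session_summaries.csv"),
            row.names = FALSE)

  rel <- stage("reliability", {
    meas <- if (config$task == "gonogo")
      c("acc_go_to_win", "acc_nogo_to_win", "acc_go_to_avoid",
        "acc_nogo_to_avoid") else "p_high_mid"
    m1 <- summaries[summaries$session == 1, c("subject", meas)]
    m2 <- summaries[summaries$session == 2, c("subject", meas)]
    reliability_table(m1, m2)
  })
  write.csv(rel, file.path(out_dir, "reliability_summary_stats.csv"),
            row.names = FALSE)
  results <- list(cohort = cohort, exclusions = excl$report,
                  summaries = summaries, reliability = rel)

  if (isTRUE(config$fit_models)) {
    mc <- mcmc_config(chains = config$chains, warmup = config$warmup,
                      iter = config$iter, seed = config$seed + 11L)
    model <- if (config$task == "gonogo") config$model_id else "ddm"
    s1 <- trials[trials$session == 1, ]
    s2 <- trials[trials$session == 2, ]
    fits <- stage("fit", {
      fit_one <- function(d) {
        if (model == "ddm") fit_hierarchical_ddm(d, mcmc = mc)
        else fit_hierarchical_gng(d, model_id = model, mcmc = mc,
                                  pointwise = FALSE)
      }
      list(s1 = fit_one(s1), s2 = fit_one(s2))
    })
    for (ses in c("s1", "s2")) {
      sm <- data.frame(subject = fits[[ses]]$subjects,
                       fits[[ses]]$subject_means)
      write.csv(sm, file.path(out_dir, paste0("subject_params_", ses, ".csv")),
                row.names = FALSE)
    }

    rel_par <- stage("reliability_parameters", {
      m1 <- data.frame(subject = fits$s1$subjects, fits$s1$subject_means)
      m2 <- data.frame(subject = fits$s2$subjects, fits$s2$subject_means)
      reliability_table(m1, m2)
    })
    write.csv(rel_par, file.path(out_dir, "reliability_parameters.csv"),
              row.names = FALSE)

    transfer <- stage("transfer", {
      tt <- transfer_table(fits$s1, fits$s2, s1, s2,
                           model = if (model == "ddm") "ddm" else "gonogo",
                           force = TRUE)
      list(table = tt, tests = transfer_tests(tt))
    })
    write.csv(transfer$table, file.path(out_dir, "transfer_likelihoods.csv"),
              row.names = FALSE)
    write.csv(transfer$tests, file.path(out_dir, "transfer_tests.csv"),
              row.names = FALSE)

    embedded <- stage("embedded", {
      fit_embedded(trials, embedded_spec(model = model, mcmc = mc))
    })
    write.csv(embedded$estimates, file.path(out_dir, "embedded_reliability.csv"),
              row.names = FALSE)
    results <- c(results, list(fits = fits, reliability_parameters = rel_par,
                               transfer = transfer, embedded = embedded))
  }

  manifest <- list(config = unclass(config),
                   package_version = as.character(utils::packageVersion("affbias")),
                   created = format(Sys.time(), tz = "UTC", usetz = TRUE),
                   tables = list.files(out_dir, pattern = "\\.csv$"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
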