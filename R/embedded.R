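# Joint two-session generative modelling with the between-session
# correlation estimated inside the model.  Per parameter, the subject-level
# unconstrained values (theta_i1, theta_i2) are bivariate normal with
# session-specific means and sds and a correlation r_p carrying an LKJ(eta)
# prior (uniform over (-1, 1) at the default eta = 1).  This propagates
# estimation uncertainty into the reliability estimate rather than
# correlating noisy per-session point estimates.

#' Specification of an embedded-correlation fit
#'
#' @param model a go/no-go family id (see [gng_model_family()]) or `"ddm"`.
#' @param lkj_eta LKJ shape for the correlation prior (default 1 = uniform).
#' @param mcmc an [mcmc_config()].
#' @return an `embedded_spec` list.
#' @export
embedded_spec <- function(model = "rw_b_pavsep_rhosep", lkj_eta = 1,
                          mcmc = mcmc_config()) {
  stopifnot(lkj_eta > 0, model %in% c(gng_model_family(), "ddm"))
  structure(list(model = model, lkj_eta = lkj_eta, mcmc = mcmc),
            class = "embedded_spec")
}

#' Fit the joint two-session model with embedded correlations
#'
#' Both sessions' behavioural likelihoods enter one model; the posterior
#' over each parameter's cross-session correlation is the fully Bayesian
#' reliability estimate.  Session-level means and sds are free per session
#' (allowing practice effects), so r_p is a consistency-like quantity.
#'
#' @param cohort a `cohort_data` object, or a trials data frame with
#'   `subject` and `session` columns; every subject must have both sessions.
#' @param spec an [embedded_spec()].
#' @return an `embedded_result`: data frame `estimates` (`parameter`,
#'   `r_mean`, `r_ci_low`, `r_ci_high`), posterior `draws`, `rhat`,
#'   `converged`.
#' @export
fit_embedded <- function(cohort, spec = embedded_spec()) {
  trials <- if (inherits(cohort, "cohort_data")) cohort$trials else cohort
  s1 <- trials[trials$session == 1, ]
  s2 <- trials[trials$session == 2, ]
  miss <- union(setdiff(unique(s1$subject), unique(s2$subject)),
                setdiff(unique(s2$subject), unique(s1$subject)))
  if (length(miss) > 0)
    stop("subjects missing a session: ", paste(miss, collapse = ", "))

  if (spec$model == "ddm") {
    prep1 <- ddm_prepare(s1); prep2 <- ddm_prepare(s2)
    stopifnot(identical(prep1$subjects, prep2$subjects))
    pspec1 <- ddm_pspec(prep1$minrt)
    pspec2 <- ddm_pspec(prep2$minrt)
    ll1 <- function(nat) .ddm_loglik_batch(nat, prep1$rt, prep1$choice,
                                           prep1$start, prep1$len)
    ll2 <- function(nat) .ddm_loglik_batch(nat, prep2$rt, prep2$choice,
                                           prep2$start, prep2$len)
    subjects <- prep1$subjects
  } else {
    prep1 <- gng_prepare(s1); prep2 <- gng_prepare(s2)
    stopifnot(identical(prep1$subjects, prep2$subjects))
    pspec1 <- pspec2 <- gng_pspec(spec$model)
    ll1 <- function(nat) .gng_loglik_batch(gng_to_full(nat, pspec1), prep1$cue,
                                           prep1$choice, prep1$outcome,
                                           prep1$start, prep1$len)
    ll2 <- function(nat) .gng_loglik_batch(gng_to_full(nat, pspec2), prep2$cue,
                                           prep2$choice, prep2$outcome,
                                           prep2$start, prep2$len)
    subjects <- prep1$subjects
  }

  draws <- fit_mcmc_embedded(ll1, ll2, length(subjects), pspec1, spec$mcmc,
                             lkj_eta = spec$lkj_eta, pspec2 = pspec2)
  P <- length(pspec1$names)
  est <- do.call(rbind, lapply(seq_len(P), function(p) {
    rd <- as.vector(draws$r[, , p])
    data.frame(parameter = pspec1$names[p], r_mean = mean(rd),
               r_ci_low = unname(quantile(rd, 0.025)),
               r_ci_high = unname(quantile(rd, 0.975)))
  }))
  converged <- all(is.finite(draws$rhat)) && max(draws$rhat) <= 1.05
  structure(list(estimates = est, draws = draws, rhat = draws$rhat,
                 converged = converged, model = spec$model,
                 subjects = subjects, spec = spec),
            class = "embedded_result")
}

#' Two-stage vs embedded reliability, side by side
#'
#' Runs the two-stage pipeline (per-session hierarchical fits, Pearson
#' correlation of subject-level posterior means) and the embedded fit on the
#' same cohort, returning one table per parameter with both estimates and
#' their 95% intervals.
#'
#' @param cohort a `cohort_data` object (or trials data frame with both
#'   sessions).
#' @param spec an [embedded_spec()]; its model id drives both pipelines.
#' @param mcmc_two_stage MCMC settings for the per-session fits (defaults to
#'   the spec's settings).
#' @return data frame: `parameter`, `two_stage_r`, `two_stage_ci_low`,
#'   `two_stage_ci_high`, `embedded_r`, `embedded_ci_low`,
#'   `embedded_ci_high`.
#' @export
compare_two_stage_vs_embedded <- function(cohort, spec = embedded_spec(),
                                          mcmc_two_stage = spec$mcmc) {
  trials <- if (inherits(cohort, "cohort_data")) cohort$trials else cohort
  s1 <- trials[trials$session == 1, ]
  s2 <- trials[trials$session == 2, ]
  fit_one <- function(d) {
    if (spec$model == "ddm") fit_hierarchical_ddm(d, mcmc = mcmc_two_stage)
    else fit_hierarchical_gng(d, model_id = spec$model, mcmc = mcmc_two_stage,
                              pointwise = FALSE)
  }
  f1 <- fit_one(s1); f2 <- fit_one(s2)
  stopifnot(identical(f1$subjects, f2$subjects))
  two_stage <- do.call(rbind, lapply(f1$param_names, function(p) {
    pm <- paired_measures(f1$subjects, f1$subject_means[, p],
                          f2$subject_means[, p])
    e <- pearson_reliability(pm)
    data.frame(parameter = p, two_stage_r = e$coefficient,
               two_stage_ci_low = e$ci_low, two_stage_ci_high = e$ci_high)
  }))
  emb <- fit_embedded(trials, spec)
  out <- merge(two_stage, setNames(emb$estimates,
                                   c("parameter", "embedded_r",
                                     "embedded_ci_low", "embedded_ci_high")),
               by = "parameter", sort = FALSE)
  attr(out, "fits") <- list(session1 = f1, session2 = f2, embedded = emb)
  out
}

#' @importFrom stats quantile
NULL
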