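# Cross-session posterior-predictive transfer: how well one session's
# best-fitting parameters (subject-level posterior means) predict the choices
# actually made in the other session, and whether individual parameters beat
# the group-mean parameters (a shrinkage check).

#' Mean trialwise likelihood of a session's choices under fixed parameters
#'
#' For the go/no-go model the latent state is evolved with the target
#' session's observed choices and outcomes, and the likelihood of each
#' observed choice is averaged over trials.  For the diffusion model the
#' average is over responded mid trials of the closed-form probability of
#' the observed key (marginal over RT), so chance is exactly 0.5.
#'
#' @param params a [gng_params()] or [ddm_params()] vector (or a named
#'   vector with the canonical parameter names).
#' @param session target session data frame.
#' @param model `"gonogo"` or `"ddm"`.
#' @return mean trialwise likelihood in `[0, 1]`.
#' @export
transfer_likelihood <- function(params, session, model = c("gonogo", "ddm")) {
  model <- match.arg(model)
  if (nrow(session) == 0) stop("empty target session")
  if (model == "gonogo") {
    enc <- gng_encode(session)
    mean(.gng_trialwise_p(unclass(params)[GNG_PARAM_NAMES], enc$cue,
                          enc$choice, enc$outcome))
  } else {
    mid <- am_session_mid(session)
    if (nrow(mid) == 0) stop("no responded mid trials in target session")
    pu <- ddm_choice_probability(params)
    mean(ifelse(mid$choice == "key_high", pu, 1 - pu))
  }
}

#' Group-mean parameter vector from a hierarchical fit
#'
#' The arithmetic mean across subjects of the subject-level posterior means,
#' per parameter, on the native scale.
#'
#' @param fit a `gng_fit` or `ddm_fit`.
#' @param force extract even if convergence diagnostics failed.
#' @return named numeric vector (canonical parameter space).
#' @export
group_mean_params <- function(fit, force = FALSE) {
  if (!fit$converged && !force)
    stop("fit did not pass convergence diagnostics (max R-hat = ",
         round(max(fit$rhat), 3), "); pass force = TRUE to override")
  colMeans(fit$subject_means_full)
}

#' Trialwise transfer likelihoods for all directions
#'
#' Crosses sessions (s1->s2, s2->s1, and the own-session baselines s1->s1,
#' s2->s2) with the parameter source (each individual's own posterior means
#' vs the group mean).
#'
#' @param fit1,fit2 hierarchical fits of session 1 and session 2.
#' @param data1,data2 the corresponding trials data (data frame with
#'   `subject` column, one session each).
#' @param model `"gonogo"` or `"ddm"`.
#' @param force passed to [group_mean_params()].
#' @return data frame: `subject`, `direction`, `parameter_source`,
#'   `mean_trialwise_likelihood`.
#' @export
transfer_table <- function(fit1, fit2, data1, data2, model = c("gonogo", "ddm"),
                           force = FALSE) {
  model <- match.arg(model)
  stopifnot(identical(fit1$subjects, fit2$subjects))
  split1 <- split(data1, data1$subject)[fit1$subjects]
  split2 <- split(data2, data2$subject)[fit2$subjects]
  gm1 <- group_mean_params(fit1, force)
  gm2 <- group_mean_params(fit2, force)
  dirs <- list(c(1, 2), c(2, 1), c(1, 1), c(2, 2))
  out <- do.call(rbind, lapply(dirs, function(d) {
    fit_from <- if (d[1] == 1) fit1 else fit2
    gm <- if (d[1] == 1) gm1 else gm2
    target <- if (d[2] == 1) split1 else split2
    lab <- sprintf("s%d->s%d", d[1], d[2])
    do.call(rbind, lapply(seq_along(fit_from$subjects), function(i) {
      ind <- transfer_likelihood(fit_from$subject_means_full[i, ],
                                 target[[i]], model)
      grp <- transfer_likelihood(gm, target[[i]], model)
      data.frame(subject = rep(fit_from$subjects[i], 2),
                 direction = lab,
                 parameter_source = c("individual", "group_mean"),
                 mean_trialwise_likelihood = c(ind, grp))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' t-tests on transfer likelihoods
#'
#' Per direction: a two-tailed one-sample t-test of the individual-parameter
#' mean trialwise likelihoods against chance (0.5), and a two-tailed paired
#' t-test of (individual - group-mean) likelihoods against 0.  No
#' multiple-comparison correction is applied.
#'
#' @param tab output of [transfer_table()].
#' @return data frame: `direction`, `test`, `mean`, `t`, `df`, `p_value`.
#' @export
transfer_tests <- function(tab) {
  dirs <- unique(tab$direction)
  out <- do.call(rbind, lapply(dirs, function(d) {
    ind <- tab$mean_trialwise_likelihood[tab$direction == d &
                                           tab$parameter_source == "individual"]
    grp <- tab$mean_trialwise_likelihood[tab$direction == d &
                                           tab$parameter_source == "group_mean"]
    if (length(ind) < 3 || length(grp) < 3)
      stop("need at least 3 subjects per direction")
    t1 <- safe_t(ind - 0.5)
    t2 <- safe_t(ind - grp)
    data.frame(direction = rep(d, 2),
               test = c("vs_chance", "individual_vs_group_mean"),
               mean = c(mean(ind), mean(ind - grp)),
               t = c(t1$t, t2$t), df = c(t1$df, t2$df),
               p_value = c(t1$p, t2$p))
  }))
  rownames(out) <- NULL
  out
}

# one-sample t on a difference vector; exactly-zero variance with zero mean
# is t = 0, p = 1 (all values at the null)
safe_t <- function(x) {
  if (sd(x) == 0) {
    if (mean(x) == 0) return(list(t = 0, df = length(x) - 1, p = 1))
    return(list(t = Inf * sign(mean(x)), df = length(x) - 1, p = 0))
  }
  tt <- t.test(x)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}
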