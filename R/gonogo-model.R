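# Pavlovian-bias reinforcement-learning model family for the go/no-go task.
# The canonical (richest) parameterization has seven parameters: a learning
# rate, a go bias, separate Pavlovian approach and avoid biases, separate
# reward and punishment sensitivities, and a lapse governing how
# deterministically choices follow the learned action weights.

GNG_PARAM_NAMES <- c("epsilon", "b", "pi_approach", "pi_avoid",
                     "rho_rew", "rho_pun", "xi")

#' Construct a go/no-go model parameter vector
#'
#' @param epsilon learning rate in (0, 1).
#' @param b additive go bias (real).
#' @param pi_approach Pavlovian approach bias applied on win cues (real).
#' @param pi_avoid Pavlovian avoid bias applied on avoid cues (real).
#' @param rho_rew reward sensitivity (> 0); scales +10 outcomes.
#' @param rho_pun punishment sensitivity (> 0); scales -10 outcomes.
#' @param xi lapse in (0, 1): probability mass on uniform random responding.
#' @return a named numeric vector of class `gng_params`.
#' @export
gng_params <- function(epsilon, b = 0, pi_approach = 0, pi_avoid = 0,
                       rho_rew = 1, rho_pun = 1, xi = 0) {
  stopifnot(epsilon >= 0, epsilon <= 1, rho_rew > 0, rho_pun > 0,
            xi >= 0, xi <= 1)
  structure(c(epsilon = epsilon, b = b, pi_approach = pi_approach,
              pi_avoid = pi_avoid, rho_rew = rho_rew, rho_pun = rho_pun,
              xi = xi), class = "gng_params")
}

#' Fresh latent state for the go/no-go learner
#'
#' Action values Q(action, cue) and Pavlovian stimulus values V(cue), all
#' initialized to zero.
#' @return a `gng_state` list with a 2 x 4 `Q` matrix (rows go/nogo) and a
#'   length-4 `V` vector, columns/entries named by cue.
#' @export
gng_new_state <- function() {
  Q <- matrix(0, 2, 4, dimnames = list(c("go", "nogo"), GNG_CUES))
  V <- setNames(numeric(4), GNG_CUES)
  structure(list(Q = Q, V = V), class = "gng_state")
}

#' Probability of a go response
#'
#' The go action weight is W(go) = Q(go, cue) + b + pi_cue * V(cue), where
#' pi_cue is the approach bias on win cues and the avoid bias on avoid cues;
#' W(nogo) = Q(nogo, cue).  The choice rule mixes a logistic of the weight
#' difference with a uniform lapse:
#' p(go) = xi/2 + (1 - xi) * logistic(W(go) - W(nogo)), so p(go) is bounded
#' in [xi/2, 1 - xi/2].
#'
#' @param state a `gng_state`.
#' @param params a [gng_params()] vector.
#' @param cue one of `"go_to_win"`, `"nogo_to_win"`, `"go_to_avoid"`,
#'   `"nogo_to_avoid"`.
#' @return probability of responding go.
#' @export
gng_p_go <- function(state, params, cue) {
  stopifnot(cue %in% GNG_CUES)
  pav <- if (cue %in% c("go_to_win", "nogo_to_win")) params[["pi_approach"]]
         else params[["pi_avoid"]]
  w <- state$Q["go", cue] + params[["b"]] + pav * state$V[[cue]] -
    state$Q["nogo", cue]
  unname(params[["xi"]] / 2 + (1 - params[["xi"]]) * stats::plogis(w))
}

#' Rescorla-Wagner state update after feedback
#'
#' The outcome in points is mapped to r in \{-1, 0, +1\} and scaled by the
#' matching sensitivity (u = rho_rew * r for rewards, rho_pun * r for
#' punishments, 0 for neutral feedback).  Only the taken action's Q value is
#' updated; the Pavlovian stimulus value V updates regardless of action:
#' Q <- Q + epsilon * (u - Q), V <- V + epsilon * (u - V).
#'
#' @param state a `gng_state`.
#' @param params a [gng_params()] vector.
#' @param cue cue type of the trial.
#' @param action `"go"` or `"nogo"`.
#' @param outcome points: +10, 0 or -10.
#' @return the updated `gng_state`.
#' @export
gng_update_state <- function(state, params, cue, action, outcome) {
  stopifnot(cue %in% GNG_CUES, action %in% c("go", "nogo"),
            outcome %in% c(-10, 0, 10))
  r <- sign(outcome)
  u <- if (r > 0) params[["rho_rew"]] else if (r < 0) -params[["rho_pun"]] else 0
  eps <- params[["epsilon"]]
  state$Q[action, cue] <- state$Q[action, cue] + eps * (u - state$Q[action, cue])
  state$V[[cue]] <- state$V[[cue]] + eps * (u - state$V[[cue]])
  state
}

# Encode a session data frame into integer arrays for the C++ likelihood.
gng_encode <- function(session) {
  need <- c("condition", "choice", "outcome")
  if (!all(need %in% names(session)))
    stop("session needs columns: ", paste(need, collapse = ", "))
  if ("trial" %in% names(session)) session <- session[order(session$trial), ]
  cue <- match(as.character(session$condition), GNG_CUES)
  if (anyNA(cue)) stop("unknown cue codes in condition column")
  ch <- as.character(session$choice)
  if (!all(ch %in% c("go", "nogo"))) stop("invalid choice codes for go-nogo data")
  list(cue = as.integer(cue),
       choice = as.integer(ch == "go"),
       outcome = as.integer(sign(session$outcome)))
}

#' Session log-likelihood under the go/no-go model
#'
#' Sum over trials of log p(observed choice), with the latent state evolved
#' using the observed choices and outcomes.
#'
#' @param params a [gng_params()] vector (canonical 7-parameter form).
#' @param session a data frame with columns `condition`, `choice`
#'   (`"go"`/`"nogo"`), `outcome` (points) and optionally `trial` for
#'   ordering.
#' @return scalar log-likelihood.
#' @export
gng_session_loglik <- function(params, session) {
  enc <- gng_encode(session)
  as.numeric(.gng_loglik_batch(matrix(unclass(params)[GNG_PARAM_NAMES], 1),
                               enc$cue, enc$choice, enc$outcome,
                               0L, length(enc$cue)))
}

# --- model family -----------------------------------------------------------

#' The go/no-go model family
#'
#' Nested reinforcement-learning models, from a bare Rescorla-Wagner learner
#' to the richest model with separate Pavlovian biases and separate outcome
#' sensitivities (the one favoured by model comparison on this task family):
#' `rw` (learning rate, lapse, single sensitivity), `rw_b` (+ go bias),
#' `rw_b_pav` (+ single Pavlovian bias), `rw_b_pav_rhosep` (split
#' reward/punishment sensitivity), `rw_b_pavsep_rhosep` (split
#' approach/avoid bias; 7 parameters).
#'
#' @return character vector of model ids in increasing complexity.
#' @export
gng_model_family <- function() {
  c("rw", "rw_b", "rw_b_pav", "rw_b_pav_rhosep", "rw_b_pavsep_rhosep")
}

# Parameter block (names + links) for one family member, and the mapping of
# its native parameters onto the canonical 7-parameter vector.
gng_pspec <- function(model_id) {
  pars <- switch(model_id,
    rw = c("epsilon", "xi", "rho"),
    rw_b = c("epsilon", "xi", "b", "rho"),
    rw_b_pav = c("epsilon", "xi", "b", "pi", "rho"),
    rw_b_pav_rhosep = c("epsilon", "xi", "b", "pi", "rho_rew", "rho_pun"),
    rw_b_pavsep_rhosep = c("epsilon", "xi", "b", "pi_approach", "pi_avoid",
                           "rho_rew", "rho_pun"),
    stop("unknown model_id: ", model_id))
  link <- ifelse(pars %in% c("epsilon", "xi"), "probit",
                 ifelse(pars %in% c("rho", "rho_rew", "rho_pun"), "log",
                        "identity"))
  list(names = pars, link = link, model_id = model_id)
}

# native (n x P_model) -> canonical 7-column matrix
gng_to_full <- function(native, pspec) {
  g <- function(nm, default = 0) {
    if (nm %in% pspec$names) native[, nm]
    else rep(default, nrow(native))
  }
  rho_r <- if ("rho_rew" %in% pspec$names) native[, "rho_rew"] else g("rho", 1)
  rho_p <- if ("rho_pun" %in% pspec$names) native[, "rho_pun"] else g("rho", 1)
  pi_ap <- if ("pi_approach" %in% pspec$names) native[, "pi_approach"] else g("pi", 0)
  pi_av <- if ("pi_avoid" %in% pspec$names) native[, "pi_avoid"] else g("pi", 0)
  out <- cbind(epsilon = native[, "epsilon"], b = g("b", 0),
               pi_approach = pi_ap, pi_avoid = pi_av,
               rho_rew = rho_r, rho_pun = rho_p, xi = native[, "xi"])
  out
}

# Split a trials table into per-subject encoded arrays for one session.
gng_prepare <- function(sessions) {
  if (is.data.frame(sessions)) {
    stopifnot("subject" %in% names(sessions))
    sessions <- split(sessions, sessions$subject)
  }
  enc <- lapply(sessions, gng_encode)
  len <- vapply(enc, function(e) length(e$cue), 0L)
  list(subjects = names(sessions),
       cue = unlist(lapply(enc, `[[`, "cue"), use.names = FALSE),
       choice = unlist(lapply(enc, `[[`, "choice"), use.names = FALSE),
       outcome = unlist(lapply(enc, `[[`, "outcome"), use.names = FALSE),
       start = c(0L, cumsum(len)[-length(len)]),
       len = len)
}

#' Hierarchical Bayesian fit of a go/no-go model to one session
#'
#' Subject-level parameters are drawn from group-level normal distributions
#' on an unconstrained scale (probabilities via inverse-probit, sensitivities
#' via a log link) and estimated by adaptive Metropolis-within-Gibbs MCMC.
#' Convergence is assessed by split-chain potential scale reduction on the
#' group-level parameters; fits with any R-hat above 1.05 are flagged.
#'
#' @param sessions a list of per-subject session data frames, or one trials
#'   data frame for a single session with a `subject` column.
#' @param model_id a member of [gng_model_family()] (default: the
#'   7-parameter winning model).
#' @param mcmc an [mcmc_config()].
#' @param pointwise keep thinned trialwise likelihood draws for model
#'   comparison via WAIC (default TRUE).
#' @return a `gng_fit` object: posterior draws, native-scale subject-level
#'   posterior means (`$subject_means`, and `$subject_means_full` mapped to
#'   the canonical 7-parameter space), group-level summaries, R-hat
#'   diagnostics and a `converged` flag.
#' @export
fit_hierarchical_gng <- function(sessions, model_id = "rw_b_pavsep_rhosep",
                                 mcmc = mcmc_config(), pointwise = TRUE) {
  prep <- gng_prepare(sessions)
  n <- length(prep$subjects)
  if (n < 2) stop("hierarchical fitting needs at least 2 subjects")
  pspec <- gng_pspec(model_id)
  loglik <- function(native)
    .gng_loglik_batch(gng_to_full(native, pspec), prep$cue, prep$choice,
                      prep$outcome, prep$start, prep$len)
  draws <- fit_mcmc_hier(loglik, n, pspec, mcmc)
  sm <- subject_posterior_means(draws, pspec)
  rownames(sm) <- prep$subjects
  smf <- gng_to_full(sm, pspec)
  rownames(smf) <- prep$subjects

  pw <- NULL
  if (pointwise) {
    keep <- thin_index(dim(draws$theta)[1], dim(draws$theta)[2], 300)
    pw <- matrix(NA_real_, nrow(keep), sum(prep$len))
    for (d in seq_len(nrow(keep))) {
      th <- matrix(draws$theta[keep[d, 1], keep[d, 2], , ],
                   n, length(pspec$names))
      full <- gng_to_full(link_to_native(th, pspec), pspec)
      row <- numeric(0)
      for (s in seq_len(n)) {
        idx <- prep$start[s] + seq_len(prep$len[s])
        row <- c(row, log(.gng_trialwise_p(full[s, ], prep$cue[idx],
                                           prep$choice[idx], prep$outcome[idx])))
      }
      pw[d, ] <- row
    }
  }

  converged <- all(is.finite(draws$rhat)) && max(draws$rhat) <= 1.05
  structure(list(model_id = model_id, task = "gonogo",
                 param_names = pspec$names, draws = draws,
                 subject_means = sm, subject_means_full = smf,
                 subjects = prep$subjects, n_subjects = n,
                 rhat = draws$rhat, converged = converged,
                 pointwise_ll = pw, mcmc = mcmc,
                 data_checksum = data_checksum(prep[c("cue", "choice",
                                                      "outcome", "len")])),
            class = c("gng_fit", "affbias_fit"))
}

# draw indices (draw, chain) thinned to at most k rows
thin_index <- function(iters, chains, k) {
  all <- expand.grid(draw = seq_len(iters), chain = seq_len(chains))
  if (nrow(all) <= k) return(as.matrix(all))
  as.matrix(all[round(seq(1, nrow(all), length.out = k)), ])
}

#' Compare go/no-go family fits by WAIC
#'
#' Ranks fits of different models to the same data by the widely applicable
#' information criterion computed from trialwise pointwise log-likelihood
#' draws, with a standard error from the pointwise variance.
#'
#' @param fits list of `gng_fit` objects fit to identical data with
#'   `pointwise = TRUE`.
#' @return data frame with `model_id`, `waic`, `se`, `rank` (1 = best).
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1)
  hashes <- vapply(fits, `[[`, "", "data_checksum")
  if (length(unique(hashes)) != 1)
    stop("fits were not computed on identical data")
  stats_one <- function(fit) {
    pw <- fit$pointwise_ll
    if (is.null(pw)) stop("fit lacks pointwise likelihoods; refit with pointwise = TRUE")
    lppd_i <- apply(pw, 2, function(col) {
      m <- max(col); m + log(mean(exp(col - m)))
    })
    p_i <- apply(pw, 2, var)
    elpd_i <- lppd_i - p_i
    c(waic = -2 * sum(elpd_i), se = 2 * sqrt(length(elpd_i) * var(elpd_i)))
  }
  tab <- t(vapply(fits, stats_one, c(waic = 0, se = 0)))
  out <- data.frame(model_id = vapply(fits, `[[`, "", "model_id"),
                    waic = tab[, "waic"], se = tab[, "se"])
  out$rank <- rank(out$waic, ties.method = "min")
  out[order(out$rank), ]
}
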