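# Drift-diffusion treatments of the ambiguous-midpoint task: the EZ
# closed-form estimator (drift, boundary, non-decision time from accuracy and
# RT moments) and a 4-parameter Wiener-likelihood model (boundary separation
# alpha, starting-point bias beta, drift delta, non-decision time tau) fit
# hierarchically.  Boundary coding: the upper boundary is the high-reward
# response on mid trials, so a positive drift reads as an optimistic bias.

#' Construct a 4-parameter diffusion parameter vector
#'
#' @param alpha boundary separation (> 0).
#' @param beta starting-point bias in (0, 1); 0.5 is unbiased.
#' @param delta drift rate (real; positive drives the upper boundary).
#' @param tau non-decision time in seconds (>= 0).
#' @return a named numeric vector of class `ddm_params`.
#' @export
ddm_params <- function(alpha, beta = 0.5, delta = 0, tau = 0) {
  stopifnot(alpha > 0, beta > 0, beta < 1, tau >= 0)
  structure(c(alpha = alpha, beta = beta, delta = delta, tau = tau),
            class = "ddm_params")
}

#' EZ-diffusion moments
#'
#' @param Pc proportion of target (upper-boundary) responses.
#' @param VRT response-time variance (s^2).
#' @param MRT mean response time (s).
#' @param N trial count the moments were computed from.
#' @return an `ez_moments` list.
#' @export
ez_moments <- function(Pc, VRT, MRT, N) {
  stopifnot(Pc >= 0, Pc <= 1, MRT > 0, N >= 1)
  structure(list(Pc = Pc, VRT = VRT, MRT = MRT, N = N), class = "ez_moments")
}

#' EZ-diffusion closed-form estimates
#'
#' Maps (accuracy, RT variance, mean RT) to drift rate, boundary separation
#' and non-decision time.  With L = logit(Pc):
#' v = sign(Pc - 1/2) * s * (L * (Pc^2 L - Pc L + Pc - 1/2) / VRT)^(1/4),
#' a = s^2 L / v, and Ter = MRT - (a / 2v) * (1 - e^(-va/s^2)) / (1 + e^(-va/s^2)).
#' Pc of exactly 0 or 1 is edge-corrected to 1/(2N) from the boundary;
#' Pc = 0.5 gets a half-trial adjustment only when `edge_correct = TRUE`
#' (otherwise it is an error, since L = 0 is degenerate).
#'
#' @param m an [ez_moments()] object.
#' @param s diffusion scaling constant (default 1; 0.1 is the original EZ
#'   convention — estimates of v and a scale with s, Ter does not change).
#' @param edge_correct apply the Pc = 0.5 half-trial adjustment.
#' @return an `ez_estimates` list with `v`, `a`, `Ter` and `flags`.
#' @export
ez_ddm <- function(m, s = 1, edge_correct = TRUE) {
  stopifnot(inherits(m, "ez_moments"), m$VRT > 0)
  Pc <- m$Pc
  flags <- character(0)
  if (Pc <= 0) { Pc <- 1 / (2 * m$N); flags <- c(flags, "edge_corrected_low") }
  if (Pc >= 1) { Pc <- 1 - 1 / (2 * m$N); flags <- c(flags, "edge_corrected_high") }
  if (Pc == 0.5) {
    if (!edge_correct) stop("Pc = 0.5 is degenerate for EZ (L = 0); enable edge_correct")
    Pc <- 0.5 + 1 / (2 * m$N)
    flags <- c(flags, "edge_corrected_half")
  }
  L <- stats::qlogis(Pc)
  x <- L * (L * Pc^2 - L * Pc + Pc - 0.5) / m$VRT
  v <- sign(Pc - 0.5) * s * x^0.25
  a <- s^2 * L / v
  y <- -v * a / s^2
  mdt <- (a / (2 * v)) * (1 - exp(y)) / (1 + exp(y))
  Ter <- m$MRT - mdt
  if (Ter < 0) flags <- c(flags, "negative_Ter")
  structure(list(v = v, a = a, Ter = Ter, flags = flags),
            class = "ez_estimates")
}

#' Probability of absorption at the upper boundary
#'
#' Closed form for a Wiener process with unit diffusion between boundaries 0
#' and alpha, started at beta * alpha with drift delta:
#' P(upper) = (1 - e^(-2 delta alpha beta)) / (1 - e^(-2 delta alpha)); the
#' zero-drift limit is beta.
#'
#' @param p a [ddm_params()] vector.
#' @return probability of hitting the upper boundary.
#' @export
ddm_choice_probability <- function(p) {
  alpha <- p[["alpha"]]; beta <- p[["beta"]]; delta <- p[["delta"]]
  if (abs(delta * alpha) < 1e-10) return(beta)
  em <- exp(-2 * delta * alpha * beta)
  ef <- exp(-2 * delta * alpha)
  (1 - em) / (1 - ef)
}

#' Wiener first-passage log density
#'
#' Joint log density of (boundary, rt) under the 4-parameter diffusion model,
#' via the standard small-time/large-time series with truncation error below
#' 1e-7.  The lower-boundary density is the upper-boundary formula under the
#' reflection (delta, beta) -> (-delta, 1 - beta).  Densities for rt <= tau
#' are zero (returned as -Inf).
#'
#' @param rt response time(s) in seconds.
#' @param boundary_hit `"upper"` or `"lower"` (recycled).
#' @param p a [ddm_params()] vector.
#' @return vector of log densities.
#' @export
wiener_logdensity <- function(rt, boundary_hit, p) {
  stopifnot(all(boundary_hit %in% c("upper", "lower")))
  up <- as.integer(rep_len(boundary_hit, length(rt)) == "upper")
  dt <- rt - p[["tau"]]
  out <- rep(-Inf, length(rt))
  ok <- dt > 0
  if (any(ok))
    out[ok] <- .wiener_lpdf(dt[ok], up[ok], p[["alpha"]], p[["beta"]],
                            p[["delta"]])
  out
}

#' Sample first-passage times and boundaries from the diffusion model
#'
#' Exact rejection-free sampling: the boundary is drawn from the closed-form
#' absorption probability and the decision time from the conditional
#' first-passage distribution by inverse-CDF on an adaptive dense time grid
#' of the series density (grid interpolation is the only approximation).
#' Randomness comes from R's RNG; seed with `set.seed()` upstream.
#'
#' @param n number of draws.
#' @param p a [ddm_params()] vector.
#' @param grid_n grid resolution per boundary (default 2^13).
#' @return data frame with `rt` (seconds, includes tau) and `boundary`
#'   (`"upper"`/`"lower"`).
#' @export
rwiener_fp <- function(n, p, grid_n = 2^13) {
  pu <- ddm_choice_probability(p)
  upper <- runif(n) < pu
  rt <- numeric(n)
  for (b in c(TRUE, FALSE)) {
    k <- sum(if (b) upper else !upper)
    if (k == 0) next
    mass <- if (b) pu else 1 - pu
    tmax <- 2
    repeat {
      grid <- seq(1e-5, tmax, length.out = grid_n)
      dens <- exp(.wiener_lpdf(grid, rep(as.integer(b), grid_n),
                               p[["alpha"]], p[["beta"]], p[["delta"]]))
      cum <- c(0, cumsum((dens[-1] + dens[-grid_n]) / 2 * diff(grid)))
      if (cum[grid_n] >= mass * (1 - 1e-5) || tmax > 500) break
      tmax <- tmax * 2
    }
    if (cum[grid_n] <= 0) stop("first-passage sampler failed: zero density mass (pathological parameters)")
    u <- runif(k) * cum[grid_n]
    rt[if (b) upper else !upper] <- approx(cum, grid, xout = u, ties = "ordered")$y
  }
  data.frame(rt = rt + p[["tau"]],
             boundary = ifelse(upper, "upper", "lower"))
}

# --- per-session EZ and hierarchical fitting --------------------------------

am_session_mid <- function(session) {
  mid <- session[session$condition == "mid" & !is.na(session$choice), ,
                 drop = FALSE]
  if ("trial" %in% names(mid)) mid <- mid[order(mid$trial), ]
  mid
}

#' EZ estimates for every subject-session
#'
#' Computes EZ moments from responded mid trials (target = high-reward key)
#' and applies [ez_ddm()] with N-aware edge correction.  Subject-sessions
#' with degenerate moments (< 2 responded mid trials or zero RT variance)
#' are flagged and returned with NA estimates.
#'
#' @param trials data frame with columns `subject`, `session`, `condition`,
#'   `choice` (`"key_low"`/`"key_high"`), `rt` (seconds).
#' @param s diffusion scaling constant passed to [ez_ddm()].
#' @return data frame: `subject`, `session`, `v`, `a`, `Ter`, `flag`.
#' @export
ez_per_session <- function(trials, s = 1) {
  stopifnot(all(c("subject", "session", "condition", "choice", "rt") %in%
                  names(trials)))
  out <- do.call(rbind, lapply(
    split(trials, list(trials$subject, trials$session), drop = TRUE),
    function(d) {
      mid <- am_session_mid(d)
      row <- data.frame(subject = d$subject[1], session = d$session[1],
                        v = NA_real_, a = NA_real_, Ter = NA_real_, flag = "")
      if (nrow(mid) < 2 || var(mid$rt) <= 0) {
        row$flag <- "degenerate_moments"
        return(row)
      }
      m <- ez_moments(mean(mid$choice == "key_high"), var(mid$rt),
                      mean(mid$rt), nrow(mid))
      est <- ez_ddm(m, s = s, edge_correct = TRUE)
      row$v <- est$v; row$a <- est$a; row$Ter <- est$Ter
      row$flag <- paste(est$flags, collapse = ";")
      row
    }))
  rownames(out) <- NULL
  out[order(out$session, out$subject), ]
}

ddm_prepare <- function(sessions) {
  if (is.data.frame(sessions)) {
    stopifnot("subject" %in% names(sessions))
    sessions <- split(sessions, sessions$subject)
  }
  dat <- lapply(sessions, function(d) {
    mid <- am_session_mid(d)
    if (nrow(mid) == 0) stop("a subject has no responded mid trials")
    if (any(!is.finite(mid$rt)) || any(mid$rt <= 0))
      stop("non-positive or missing RTs on responded mid trials: ",
           paste(utils::head(which(!is.finite(mid$rt) | mid$rt <= 0)),
                 collapse = ", "))
    list(rt = mid$rt, choice = as.integer(mid$choice == "key_high"))
  })
  len <- vapply(dat, function(d) length(d$rt), 0L)
  list(subjects = names(sessions),
       rt = unlist(lapply(dat, `[[`, "rt"), use.names = FALSE),
       choice = unlist(lapply(dat, `[[`, "choice"), use.names = FALSE),
       start = c(0L, cumsum(len)[-length(len)]),
       len = len,
       minrt = vapply(dat, function(d) min(d$rt), 0))
}

#' Hierarchical Bayesian fit of the 4-parameter diffusion model
#'
#' Fits (alpha, beta, delta, tau) per subject with group-level normal
#' distributions on the unconstrained scale (log link for alpha, probit for
#' beta, identity for delta; tau is probit-scaled to (0, 0.95 * the
#' subject's minimum RT), keeping the likelihood proper).  Mid trials with a
#' response enter the likelihood, with the upper boundary coded as the
#' high-reward key.
#'
#' @param sessions list of per-subject session data frames (or one trials
#'   data frame for a single session with a `subject` column), each with
#'   `condition`, `choice`, `rt`.
#' @param mcmc an [mcmc_config()].
#' @return a `ddm_fit` object (see [fit_hierarchical_gng()] for the shape).
#' @export
fit_hierarchical_ddm <- function(sessions, mcmc = mcmc_config()) {
  prep <- ddm_prepare(sessions)
  n <- length(prep$subjects)
  if (n < 2) stop("hierarchical fitting needs at least 2 subjects")
  pspec <- ddm_pspec(prep$minrt)
  loglik <- function(native)
    .ddm_loglik_batch(native, prep$rt, prep$choice, prep$start, prep$len)
  draws <- fit_mcmc_hier(loglik, n, pspec, mcmc)
  sm <- subject_posterior_means(draws, pspec)
  rownames(sm) <- prep$subjects
  converged <- all(is.finite(draws$rhat)) && max(draws$rhat) <= 1.05
  structure(list(model_id = "ddm4", task = "ambiguous_midpoint",
                 param_names = pspec$names, draws = draws,
                 subject_means = sm, subject_means_full = sm,
                 subjects = prep$subjects, n_subjects = n,
                 rhat = draws$rhat, converged = converged,
                 pointwise_ll = NULL, mcmc = mcmc,
                 data_checksum = data_checksum(prep[c("rt", "choice", "len")])),
            class = c("ddm_fit", "affbias_fit"))
}

ddm_pspec <- function(minrt) {
  n <- length(minrt)
  upper <- matrix(1, n, 4)
  upper[, 4] <- 0.95 * minrt
  list(names = c("alpha", "beta", "delta", "tau"),
       link = c("log", "probit", "identity", "probit_range"),
       upper = upper)
}
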