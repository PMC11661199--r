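# Adaptive Metropolis-within-Gibbs machinery for hierarchical cognitive
# models.  Subject-level parameters live on an unconstrained scale where the
# group model is normal: theta_{i,p} ~ N(mu_p, sigma_p).  Native scales are
# reached by a per-parameter link (inverse-probit for probabilities, exp for
# positive parameters, identity for real ones, range-scaled inverse-probit
# for the non-decision time).  Subjects are conditionally independent given
# the group, so subject updates are proposed and accepted as vectors.

#' MCMC configuration
#'
#' @param chains number of chains (default 4).
#' @param warmup adaptation sweeps discarded per chain (default 1000).
#' @param iter retained sweeps per chain (default 1000).
#' @param seed integer RNG seed for the sampler.
#' @return an `mcmc_config` list.
#' @export
mcmc_config <- function(chains = 4, warmup = 1000, iter = 1000, seed = 1) {
  stopifnot(chains >= 1, warmup >= 50, iter >= 50)
  structure(list(chains = chains, warmup = warmup, iter = iter, seed = seed),
            class = "mcmc_config")
}

# --- links ------------------------------------------------------------------

# A pspec describes one model's parameter block: names, link per parameter,
# and any context the link needs (e.g. per-subject RT bounds).
link_to_native <- function(theta, pspec) {
  native <- theta
  for (p in seq_along(pspec$names)) {
    native[, p] <- switch(pspec$link[p],
      probit   = pnorm(theta[, p]),
      log      = exp(theta[, p]),
      identity = theta[, p],
      probit_range = pnorm(theta[, p]) * pspec$upper[, p],
      stop("unknown link"))
  }
  colnames(native) <- pspec$names
  native
}

link_from_native <- function(native, pspec) {
  theta <- native
  for (p in seq_along(pspec$names)) {
    theta[, p] <- switch(pspec$link[p],
      probit   = qnorm(pmin(pmax(native[, p], 1e-9), 1 - 1e-9)),
      log      = log(pmax(native[, p], 1e-12)),
      identity = native[, p],
      probit_range = qnorm(pmin(pmax(native[, p] / pspec$upper[, p], 1e-9), 1 - 1e-9)))
  }
  theta
}

prior_mu_sd_for <- function(link) {
  c(probit = 1, log = 1.5, identity = 2, probit_range = 1)[link]
}

# --- diagnostics ------------------------------------------------------------

# Split-chain potential scale reduction on a draws x chains matrix (a bare
# vector -- a single chain -- is treated as a one-column matrix).
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  m <- nrow(draws) %/% 2
  if (m < 2) return(NA_real_)
  halves <- cbind(draws[seq_len(m), , drop = FALSE],
                  draws[m + seq_len(m), , drop = FALSE])
  k <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, var)
  W <- mean(vars)
  B <- m * var(means)
  if (W <= 0) return(ifelse(B <= 1e-12, 1, Inf))
  sqrt(((m - 1) / m * W + B / m) / W)
}

# --- single-session hierarchical sampler ------------------------------------

# loglik: function(native matrix n x P) -> numeric n.
# Returns draws of group means/sds and subject-level parameters.
fit_mcmc_hier <- function(loglik, n_subjects, pspec, mcmc) {
  P <- length(pspec$names)
  n <- n_subjects
  prior_mu_sd <- prior_mu_sd_for(pspec$link)
  total <- mcmc$warmup + mcmc$iter

  mu_draws <- array(NA_real_, c(mcmc$iter, mcmc$chains, P))
  sigma_draws <- array(NA_real_, c(mcmc$iter, mcmc$chains, P))
  theta_draws <- array(NA_real_, c(mcmc$iter, mcmc$chains, n, P))

  for (ch in seq_len(mcmc$chains)) {
    set.seed(mcmc$seed + 1000L * ch)
    mu <- rnorm(P, 0, 0.2)
    sigma <- rep(0.5, P) * exp(rnorm(P, 0, 0.1))
    theta <- sweep(sweep(matrix(rnorm(n * P), n, P), 2, sigma, `*`), 2, mu, `+`)
    s_theta <- matrix(0.4, n, P)
    s_mu <- rep(0.2, P)
    s_sigma <- rep(0.2, P)
    s_mu_nc <- rep(0.1, P)
    s_sigma_nc <- rep(0.1, P)
    ll <- loglik(link_to_native(theta, pspec))
    for (it in seq_len(total)) {
      gamma <- if (it <= mcmc$warmup) min(0.5, 5 / sqrt(it)) else 0
      for (p in seq_len(P)) {
        prop <- theta
        prop[, p] <- theta[, p] + s_theta[, p] * rnorm(n)
        llp <- loglik(link_to_native(prop, pspec))
        la <- (llp - ll) +
          dnorm(prop[, p], mu[p], sigma[p], log = TRUE) -
          dnorm(theta[, p], mu[p], sigma[p], log = TRUE)
        la[is.na(la)] <- -Inf
        acc <- log(runif(n)) < la
        theta[acc, p] <- prop[acc, p]
        ll[acc] <- llp[acc]
        if (gamma > 0)
          s_theta[, p] <- s_theta[, p] * exp(gamma * (pmin(1, exp(la)) - 0.44))
      }
      for (p in seq_len(P)) {
        mup <- mu[p] + s_mu[p] * rnorm(1)
        la <- sum(dnorm(theta[, p], mup, sigma[p], log = TRUE)) -
          sum(dnorm(theta[, p], mu[p], sigma[p], log = TRUE)) +
          dnorm(mup, 0, prior_mu_sd[p], log = TRUE) -
          dnorm(mu[p], 0, prior_mu_sd[p], log = TRUE)
        if (is.na(la)) la <- -Inf
        if (is.finite(la) && log(runif(1)) < la) mu[p] <- mup
        if (gamma > 0)
          s_mu[p] <- s_mu[p] * exp(gamma * (min(1, exp(la)) - 0.44))

        sigp <- sigma[p] * exp(s_sigma[p] * rnorm(1))
        la <- sum(dnorm(theta[, p], mu[p], sigp, log = TRUE)) -
          sum(dnorm(theta[, p], mu[p], sigma[p], log = TRUE)) +
          dnorm(sigp, 0, 1, log = TRUE) - dnorm(sigma[p], 0, 1, log = TRUE) +
          log(sigp) - log(sigma[p])  # log-scale proposal Jacobian
        if (is.na(la)) la <- -Inf
        if (is.finite(la) && log(runif(1)) < la) sigma[p] <- sigp
        if (gamma > 0)
          s_sigma[p] <- s_sigma[p] * exp(gamma * (min(1, exp(la)) - 0.44))
      }
      # Interweaved non-centred group moves: holding the standardized
      # subject effects z = (theta - mu) / sigma fixed, shift mu (translating
      # all subjects) or rescale sigma.  This decouples the group scale from
      # the subject block and removes the funnel that slows centred updates
      # when sigma is small.
      for (p in seq_len(P)) {
        z <- (theta[, p] - mu[p]) / sigma[p]
        mup <- mu[p] + s_mu_nc[p] * rnorm(1)
        prop <- theta
        prop[, p] <- mup + sigma[p] * z
        llp <- loglik(link_to_native(prop, pspec))
        la <- sum(llp - ll) +
          dnorm(mup, 0, prior_mu_sd[p], log = TRUE) -
          dnorm(mu[p], 0, prior_mu_sd[p], log = TRUE)
        if (is.na(la)) la <- -Inf
        if (is.finite(la) && log(runif(1)) < la) {
          mu[p] <- mup; theta <- prop; ll <- llp
        }
        if (gamma > 0)
          s_mu_nc[p] <- s_mu_nc[p] * exp(gamma * (min(1, exp(la)) - 0.23))

        sigp <- sigma[p] * exp(s_sigma_nc[p] * rnorm(1))
        prop <- theta
        prop[, p] <- mu[p] + sigp * z
        llp <- loglik(link_to_native(prop, pspec))
        la <- sum(llp - ll) +
          dnorm(sigp, 0, 1, log = TRUE) - dnorm(sigma[p], 0, 1, log = TRUE) +
          log(sigp) - log(sigma[p])
        if (is.na(la)) la <- -Inf
        if (is.finite(la) && log(runif(1)) < la) {
          sigma[p] <- sigp; theta <- prop; ll <- llp
        }
        if (gamma > 0)
          s_sigma_nc[p] <- s_sigma_nc[p] * exp(gamma * (min(1, exp(la)) - 0.23))
      }
      if (it > mcmc$warmup) {
        k <- it - mcmc$warmup
        mu_draws[k, ch, ] <- mu
        sigma_draws[k, ch, ] <- sigma
        theta_draws[k, ch, , ] <- theta
      }
    }
  }

  rhat <- c(
    setNames(vapply(seq_len(P), function(p) split_rhat(mu_draws[, , p, drop = TRUE]),
                    0), paste0("mu_", pspec$names)),
    setNames(vapply(seq_len(P), function(p) split_rhat(sigma_draws[, , p, drop = TRUE]),
                    0), paste0("sigma_", pspec$names)))
  list(mu = mu_draws, sigma = sigma_draws, theta = theta_draws, rhat = rhat)
}

# Posterior mean of subject-level parameters on the native scale.
subject_posterior_means <- function(draws, pspec) {
  dims <- dim(draws$theta)  # iter x chains x n x P
  n <- dims[3]; P <- dims[4]
  acc <- matrix(0, n, P)
  ndr <- dims[1] * dims[2]
  for (k in seq_len(dims[1])) for (ch in seq_len(dims[2])) {
    acc <- acc + link_to_native(matrix(draws$theta[k, ch, , ], n, P), pspec)
  }
  out <- acc / ndr
  colnames(out) <- pspec$names
  out
}

# --- joint two-session sampler with embedded correlations -------------------

# Per parameter p, subject pairs (theta1, theta2) are bivariate normal with
# session-specific means/sds and correlation r_p under an LKJ(eta) prior
# (for 2x2 blocks: density proportional to (1 - r^2)^(eta - 1)).
dbvn_log <- function(t1, t2, m1, m2, s1, s2, r) {
  z1 <- (t1 - m1) / s1
  z2 <- (t2 - m2) / s2
  om <- 1 - r^2
  -log(2 * pi) - log(s1) - log(s2) - 0.5 * log(om) -
    (z1^2 - 2 * r * z1 * z2 + z2^2) / (2 * om)
}

fit_mcmc_embedded <- function(loglik1, loglik2, n_subjects, pspec, mcmc,
                              lkj_eta = 1, pspec2 = pspec) {
  P <- length(pspec$names)
  n <- n_subjects
  prior_mu_sd <- prior_mu_sd_for(pspec$link)
  total <- mcmc$warmup + mcmc$iter

  r_draws <- array(NA_real_, c(mcmc$iter, mcmc$chains, P))
  mu_draws <- array(NA_real_, c(mcmc$iter, mcmc$chains, 2, P))
  theta1_draws <- array(NA_real_, c(mcmc$iter, mcmc$chains, n, P))
  theta2_draws <- array(NA_real_, c(mcmc$iter, mcmc$chains, n, P))

  for (ch in seq_len(mcmc$chains)) {
    set.seed(mcmc$seed + 1000L * ch)
    mu1 <- rnorm(P, 0, 0.2); mu2 <- rnorm(P, 0, 0.2)
    sg1 <- rep(0.5, P); sg2 <- rep(0.5, P)
    r <- rep(0, P)
    th1 <- sweep(sweep(matrix(rnorm(n * P), n, P), 2, sg1, `*`), 2, mu1, `+`)
    th2 <- sweep(sweep(matrix(rnorm(n * P), n, P), 2, sg2, `*`), 2, mu2, `+`)
    s_th <- matrix(0.3, n, P)
    s_grp <- matrix(0.2, 5, P)  # rows: mu1, mu2, log sg1, log sg2, atanh r
    s_nc <- matrix(0.1, 4, P)   # non-centred: mu1, mu2, log sg1, log sg2
    ll1 <- loglik1(link_to_native(th1, pspec))
    ll2 <- loglik2(link_to_native(th2, pspec2))

    for (it in seq_len(total)) {
      gamma <- if (it <= mcmc$warmup) min(0.5, 5 / sqrt(it)) else 0
      for (p in seq_len(P)) {
        pr1 <- th1; pr2 <- th2
        pr1[, p] <- th1[, p] + s_th[, p] * rnorm(n)
        pr2[, p] <- th2[, p] + s_th[, p] * rnorm(n)
        llp1 <- loglik1(link_to_native(pr1, pspec))
        llp2 <- loglik2(link_to_native(pr2, pspec2))
        la <- (llp1 - ll1) + (llp2 - ll2) +
          dbvn_log(pr1[, p], pr2[, p], mu1[p], mu2[p], sg1[p], sg2[p], r[p]) -
          dbvn_log(th1[, p], th2[, p], mu1[p], mu2[p], sg1[p], sg2[p], r[p])
        la[is.na(la)] <- -Inf
        acc <- log(runif(n)) < la
        th1[acc, p] <- pr1[acc, p]; th2[acc, p] <- pr2[acc, p]
        ll1[acc] <- llp1[acc]; ll2[acc] <- llp2[acc]
        if (gamma > 0)
          s_th[, p] <- s_th[, p] * exp(gamma * (pmin(1, exp(la)) - 0.30))
      }
      for (p in seq_len(P)) {
        cur <- function(m1, m2, v1, v2, rr)
          sum(dbvn_log(th1[, p], th2[, p], m1, m2, v1, v2, rr))
        base <- cur(mu1[p], mu2[p], sg1[p], sg2[p], r[p])
        # session means
        for (side in 1:2) {
          m <- if (side == 1) mu1[p] else mu2[p]
          mp <- m + s_grp[side, p] * rnorm(1)
          la <- (if (side == 1) cur(mp, mu2[p], sg1[p], sg2[p], r[p])
                 else cur(mu1[p], mp, sg1[p], sg2[p], r[p])) - base +
            dnorm(mp, 0, prior_mu_sd[p], log = TRUE) -
            dnorm(m, 0, prior_mu_sd[p], log = TRUE)
          if (is.na(la)) la <- -Inf
          if (is.finite(la) && log(runif(1)) < la) {
            if (side == 1) mu1[p] <- mp else mu2[p] <- mp
            base <- cur(mu1[p], mu2[p], sg1[p], sg2[p], r[p])
          }
          if (gamma > 0)
            s_grp[side, p] <- s_grp[side, p] * exp(gamma * (min(1, exp(la)) - 0.44))
        }
        # session sds (log-scale walk)
        for (side in 1:2) {
          s <- if (side == 1) sg1[p] else sg2[p]
          sp <- s * exp(s_grp[2 + side, p] * rnorm(1))
          la <- (if (side == 1) cur(mu1[p], mu2[p], sp, sg2[p], r[p])
                 else cur(mu1[p], mu2[p], sg1[p], sp, r[p])) - base +
            dnorm(sp, 0, 1, log = TRUE) - dnorm(s, 0, 1, log = TRUE) +
            log(sp) - log(s)
          if (is.na(la)) la <- -Inf
          if (is.finite(la) && log(runif(1)) < la) {
            if (side == 1) sg1[p] <- sp else sg2[p] <- sp
            base <- cur(mu1[p], mu2[p], sg1[p], sg2[p], r[p])
          }
          if (gamma > 0)
            s_grp[2 + side, p] <- s_grp[2 + side, p] * exp(gamma * (min(1, exp(la)) - 0.44))
        }
        # correlation (atanh-scale walk, LKJ prior); several cheap updates
        # per sweep since no likelihood evaluation is involved
        for (rep in 1:5) {
          zp <- atanh(r[p]) + s_grp[5, p] * rnorm(1)
          rp <- tanh(zp)
          la <- cur(mu1[p], mu2[p], sg1[p], sg2[p], rp) - base +
            (lkj_eta - 1) * (log1p(-rp^2) - log1p(-r[p]^2)) +
            log1p(-rp^2) - log1p(-r[p]^2)  # Jacobian of tanh
          if (is.na(la)) la <- -Inf
          if (is.finite(la) && log(runif(1)) < la) {
            r[p] <- rp
            base <- cur(mu1[p], mu2[p], sg1[p], sg2[p], r[p])
          }
          if (gamma > 0)
            s_grp[5, p] <- s_grp[5, p] * exp(gamma * (min(1, exp(la)) - 0.44))
        }
      }
      # interweaved non-centred moves per session (see fit_mcmc_hier): the
      # standardized pair (z1, z2) keeps its bivariate N(0, R) prior, so
      # shifting a session mean or rescaling a session sd needs only that
      # session's likelihood and the group prior.
      for (p in seq_len(P)) {
        for (side in 1:2) {
          th <- if (side == 1) th1 else th2
          mu <- if (side == 1) mu1 else mu2
          sg <- if (side == 1) sg1 else sg2
          llc <- if (side == 1) ll1 else ll2
          lfun <- if (side == 1) loglik1 else loglik2
          psp <- if (side == 1) pspec else pspec2
          z <- (th[, p] - mu[p]) / sg[p]

          mup <- mu[p] + s_nc[side, p] * rnorm(1)
          prop <- th; prop[, p] <- mup + sg[p] * z
          llp <- lfun(link_to_native(prop, psp))
          la <- sum(llp - llc) +
            dnorm(mup, 0, prior_mu_sd[p], log = TRUE) -
            dnorm(mu[p], 0, prior_mu_sd[p], log = TRUE)
          if (is.na(la)) la <- -Inf
          if (is.finite(la) && log(runif(1)) < la) {
            mu[p] <- mup; th <- prop; llc <- llp
          }
          if (gamma > 0)
            s_nc[side, p] <- s_nc[side, p] * exp(gamma * (min(1, exp(la)) - 0.23))

          sgp <- sg[p] * exp(s_nc[2 + side, p] * rnorm(1))
          prop <- th; prop[, p] <- mu[p] + sgp * z
          llp <- lfun(link_to_native(prop, psp))
          la <- sum(llp - llc) +
            dnorm(sgp, 0, 1, log = TRUE) - dnorm(sg[p], 0, 1, log = TRUE) +
            log(sgp) - log(sg[p])
          if (is.na(la)) la <- -Inf
          if (is.finite(la) && log(runif(1)) < la) {
            sg[p] <- sgp; th <- prop; llc <- llp
          }
          if (gamma > 0)
            s_nc[2 + side, p] <- s_nc[2 + side, p] * exp(gamma * (min(1, exp(la)) - 0.23))

          if (side == 1) { th1 <- th; mu1 <- mu; sg1 <- sg; ll1 <- llc }
          else           { th2 <- th; mu2 <- mu; sg2 <- sg; ll2 <- llc }
        }
      }
      if (it > mcmc$warmup) {
        k <- it - mcmc$warmup
        r_draws[k, ch, ] <- r
        mu_draws[k, ch, 1, ] <- mu1
        mu_draws[k, ch, 2, ] <- mu2
        theta1_draws[k, ch, , ] <- th1
        theta2_draws[k, ch, , ] <- th2
      }
    }
  }

  rhat <- setNames(vapply(seq_len(P),
                          function(p) split_rhat(r_draws[, , p, drop = TRUE]), 0),
                   paste0("r_", pspec$names))
  list(r = r_draws, mu = mu_draws, theta1 = theta1_draws, theta2 = theta2_draws,
       rhat = rhat)
}

# Cheap content checksum for guarding that fits being compared saw the same
# data (not cryptographic).
data_checksum <- function(x) {
  r <- serialize(x, NULL, xdr = TRUE)
  paste0(length(r), "-", sum(as.double(r)) %% 1e9)
}
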