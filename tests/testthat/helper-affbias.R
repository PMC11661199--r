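# Shared fixtures and an independent plain-R oracle for the go/no-go
# likelihood.  Expensive objects (small hierarchical fits, small cohorts)
# are built once per test run and cached.

GNG_CUES_T <- c("go_to_win", "nogo_to_win", "go_to_avoid", "nogo_to_avoid")

quick_mcmc <- function(chains = 2, warmup = 150, iter = 150, seed = 1) {
  mcmc_config(chains = chains, warmup = warmup, iter = iter, seed = seed)
}

# Small two-session cohorts with reduced trial counts, for structural and
# smoke tests (recovery-quality runs live in test-acceptance.R).
small_cohort <- function(task = "gonogo", n = 10, seed = 5, r = 0.7,
                         group_params = NULL) {
  schedules <- if (task == "gonogo") {
    list(session1 = generate_gonogo_schedule(seed + 101L, n_per_cue = 20),
         session2 = generate_gonogo_schedule(seed + 202L, n_per_cue = 20))
  } else {
    list(session1 = generate_am_schedule(seed + 101L, n_per_size = 30),
         session2 = generate_am_schedule(seed + 202L, n_per_size = 30))
  }
  cfg <- if (is.null(group_params)) {
    cohort_config(task, n_subjects = n, cross_session_r = r, seed = seed)
  } else {
    cohort_config(task, n_subjects = n, group_params = group_params,
                  cross_session_r = r, seed = seed)
  }
  simulate_cohort(cfg, schedules = schedules)
}

.fixture_cache <- new.env(parent = emptyenv())
cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

gng_cohort_small <- function() cached_fixture("gng_cohort", small_cohort("gonogo"))
am_cohort_small <- function() {
  cached_fixture("am_cohort", small_cohort("ambiguous_midpoint", n = 8, seed = 6))
}

# Per-session hierarchical go/no-go fits of the small cohort (7-parameter
# model, short chains), shared by the transfer tests.
gng_fits_small <- function() {
  cached_fixture("gng_fits", {
    coh <- gng_cohort_small()
    list(
      s1 = fit_hierarchical_gng(coh$trials[coh$trials$session == 1, ],
                                mcmc = quick_mcmc(seed = 21), pointwise = FALSE),
      s2 = fit_hierarchical_gng(coh$trials[coh$trials$session == 2, ],
                                mcmc = quick_mcmc(seed = 22), pointwise = FALSE))
  })
}

# Independent plain-R recursion for the go/no-go model: per-trial
# probabilities of the observed choices, written from the model equations
# directly (no calls into the package's state machinery or C++ code).
oracle_gng_trial_p <- function(par, session) {
  session <- session[order(session$trial), ]
  Q <- matrix(0, 2, 4)     # rows: go, nogo; cols: cue types in GNG_CUES_T order
  V <- numeric(4)
  n <- nrow(session)
  p_obs <- numeric(n)
  for (t in seq_len(n)) {
    cue <- match(session$condition[t], GNG_CUES_T)
    pav <- if (cue %in% c(1, 2)) par[["pi_approach"]] else par[["pi_avoid"]]
    w <- Q[1, cue] + par[["b"]] + pav * V[cue] - Q[2, cue]
    pgo <- par[["xi"]] / 2 + (1 - par[["xi"]]) / (1 + exp(-w))
    go <- session$choice[t] == "go"
    p_obs[t] <- if (go) pgo else 1 - pgo
    r <- sign(session$outcome[t])
    u <- if (r > 0) par[["rho_rew"]] else if (r < 0) -par[["rho_pun"]] else 0
    a <- if (go) 1 else 2
    Q[a, cue] <- Q[a, cue] + par[["epsilon"]] * (u - Q[a, cue])
    V[cue] <- V[cue] + par[["epsilon"]] * (u - V[cue])
  }
  p_obs
}

random_gng_params <- function() {
  gng_params(epsilon = runif(1, 0.05, 0.6), b = rnorm(1, 0.3, 0.5),
             pi_approach = rnorm(1, 0.5, 0.5), pi_avoid = rnorm(1, 0.5, 0.5),
             rho_rew = exp(rnorm(1, log(4), 0.4)),
             rho_pun = exp(rnorm(1, log(4), 0.4)),
             xi = runif(1, 0.01, 0.2))
}
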