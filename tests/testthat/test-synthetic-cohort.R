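# Synthetic cohort generator: paired parameters, agent simulators, cohorts.

test_that("paired parameters honour the configured cross-session correlation", {
  # r = 1: sessions identical
  cfg1 <- cohort_config("gonogo", n_subjects = 50, cross_session_r = 1, seed = 2)
  p1 <- sample_paired_params(cfg1)
  expect_equal(p1$session1, p1$session2, tolerance = 1e-12)

  # r = 0: unconstrained pairs uncorrelated up to Monte-Carlo error
  cfg0 <- cohort_config("gonogo", n_subjects = 4000, cross_session_r = 0, seed = 3)
  u0 <- attr(sample_paired_params(cfg0), "unconstrained")
  r0 <- sapply(split(u0, u0$parameter), function(d) cor(d$u1, d$u2))
  expect_true(max(abs(r0)) < 0.08)

  # r = 0.7 recovered empirically at n = 5000
  cfg7 <- cohort_config("ambiguous_midpoint", n_subjects = 5000,
                        cross_session_r = 0.7, seed = 4)
  u7 <- attr(sample_paired_params(cfg7), "unconstrained")
  r7 <- sapply(split(u7, u7$parameter), function(d) cor(d$u1, d$u2))
  expect_true(all(abs(r7 - 0.7) < 0.04))
})

test_that("sampled parameters respect their native ranges", {
  p <- sample_paired_params(cohort_config("gonogo", n_subjects = 200, seed = 5))
  for (ses in c("session1", "session2")) {
    eps <- p[[ses]][p$parameter == "epsilon"]
    xi <- p[[ses]][p$parameter == "xi"]
    rho <- p[[ses]][p$parameter %in% c("rho_rew", "rho_pun")]
    expect_true(all(eps > 0 & eps < 1))
    expect_true(all(xi > 0 & xi < 1))
    expect_true(all(rho > 0))
  }
  q <- sample_paired_params(cohort_config("ambiguous_midpoint",
                                          n_subjects = 200, seed = 5))
  expect_true(all(q$session1[q$parameter == "alpha"] > 0))
  expect_true(all(q$session1[q$parameter == "tau"] > 0))
  b <- q$session1[q$parameter == "beta"]
  expect_true(all(b > 0 & b < 1))
})

test_that("a fully lapsing go/no-go agent responds at chance", {
  sched <- generate_gonogo_schedule(6)
  sim <- simulate_gng_agent(gng_params(epsilon = 0.2, xi = 1), sched, seed = 7)
  p_go <- mean(sim$choice == "go")
  # binomial 99.9% band around 0.5 at 160 trials
  expect_true(abs(p_go - 0.5) < 3.3 * sqrt(0.25 / 160))
})

test_that("an extreme go bias produces near-universal go responding", {
  sched <- generate_gonogo_schedule(6)
  par <- gng_params(epsilon = 0, b = 20, rho_rew = 1e-6, rho_pun = 1e-6, xi = 0)
  sim <- simulate_gng_agent(par, sched, seed = 8)
  expect_true(all(sim$choice == "go"))
})

test_that("simulated go/no-go outcomes obey the feedback rule", {
  sched <- generate_gonogo_schedule(9)
  set.seed(31)
  sim <- simulate_gng_agent(random_gng_params(), sched, seed = 10)
  recomputed <- vapply(seq_len(nrow(sched)), function(t) {
    gonogo_feedback(sched[t, ], sim$choice[t])
  }, 0)
  expect_equal(sim$outcome, recomputed)
})

test_that("go/no-go agent simulation is deterministic in the seed", {
  sched <- generate_gonogo_schedule(9)
  set.seed(99)
  par <- random_gng_params()
  expect_identical(simulate_gng_agent(par, sched, seed = 3),
                   simulate_gng_agent(par, sched, seed = 3))
  a <- simulate_gng_agent(par, sched, seed = 3)
  b <- simulate_gng_agent(par, sched, seed = 4)
  expect_false(identical(a$choice, b$choice))
})

test_that("higher Pavlovian avoid bias suppresses going on avoid cues", {
  sched <- generate_gonogo_schedule(12)
  lo <- gng_params(epsilon = 0.3, rho_rew = 4, rho_pun = 4, pi_avoid = 0, xi = 0.02)
  hi <- gng_params(epsilon = 0.3, rho_rew = 4, rho_pun = 4, pi_avoid = 3, xi = 0.02)
  go_rate <- function(par, seed) {
    sim <- simulate_gng_agent(par, sched, seed)
    avoid <- sim$condition %in% c("go_to_avoid", "nogo_to_avoid")
    mean(sim$choice[avoid] == "go")
  }
  rates <- vapply(1:10, function(s) c(go_rate(lo, s), go_rate(hi, s)), c(0, 0))
  expect_lt(mean(rates[2, ]), mean(rates[1, ]))
})

test_that("diffusion agent output is structurally sound and rewarded correctly", {
  sched <- generate_am_schedule(13, n_per_size = 30)
  par <- ddm_params(alpha = 1.5, beta = 0.5, delta = 0.5, tau = 0.3)
  sim <- simulate_ddm_agent(par, sched, seed = 14)
  expect_equal(nrow(sim), 90L)
  expect_true(all(sim$rt > par[["tau"]]))
  expect_true(all(sim$choice %in% c("key_low", "key_high")))
  # trained circles go overwhelmingly to the trained key
  expect_gt(mean(sim$choice[sim$condition == "large"] == "key_high"), 0.9)
  expect_gt(mean(sim$choice[sim$condition == "small"] == "key_low"), 0.9)
  # reward follows the schedule's feedback rule
  exp_fb <- ifelse(sim$choice == sched$main$rewarded_key,
                   ifelse(sim$choice == "key_high", 4, 1), 0)
  expect_equal(sim$outcome, exp_fb)
  expect_identical(sim, simulate_ddm_agent(par, sched, seed = 14))
})

test_that("cohort simulation has complete structure and is reproducible", {
  coh <- small_cohort("gonogo", n = 6, seed = 20)
  expect_s3_class(coh$trials, "data.frame")
  expect_equal(length(unique(coh$trials$subject)), 6L)
  expect_equal(nrow(unique(coh$trials[c("subject", "session")])), 12L)
  expect_equal(nrow(coh$true_params), 6L * 7L)
  expect_identical(coh$trials, small_cohort("gonogo", n = 6, seed = 20)$trials)
  coh2 <- small_cohort("ambiguous_midpoint", n = 4, seed = 21)
  expect_equal(nrow(coh2$trials), 4L * 2L * 90L)
  expect_true(all(coh2$trials$rt > 0))
})
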