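# Pavlovian-bias go/no-go model: choice rule, learning rule, likelihood,
# model family, hierarchical fit smoke tests and WAIC comparison.

test_that("the go probability follows the lapse-logistic rule", {
  st <- gng_new_state()
  expect_equal(gng_p_go(st, gng_params(0.1), "go_to_win"), 0.5)
  expect_equal(gng_p_go(st, gng_params(0.1, b = 0.7), "go_to_win"),
               plogis(0.7))
  # full lapse pins p(go) at 1/2 whatever the weights
  st$Q["go", "go_to_win"] <- 5
  expect_equal(gng_p_go(st, gng_params(0.1, xi = 1), "go_to_win"), 0.5)
})

test_that("p(go) is confined to [xi/2, 1 - xi/2] for random states", {
  set.seed(41)
  for (i in 1:50) {
    st <- gng_new_state()
    st$Q[] <- rnorm(8, sd = 4)
    st$V[] <- rnorm(4, sd = 4)
    par <- random_gng_params()
    cue <- sample(GNG_CUES_T, 1)
    p <- gng_p_go(st, par, cue)
    xi <- unclass(par)[["xi"]]
    expect_true(p >= xi / 2 - 1e-12 && p <= 1 - xi / 2 + 1e-12)
  }
})

test_that("the Rescorla-Wagner update matches hand arithmetic", {
  st <- gng_new_state()
  par <- gng_params(epsilon = 0.4, rho_rew = 2, rho_pun = 3)
  st1 <- gng_update_state(st, par, "go_to_win", "go", 10)
  expect_equal(unname(st1$Q["go", "go_to_win"]), 0.4 * 2)
  expect_equal(unname(st1$V[["go_to_win"]]), 0.4 * 2)
  expect_equal(unname(st1$Q["nogo", "go_to_win"]), 0)
  # punishment scales by rho_pun with negative sign
  st2 <- gng_update_state(st, par, "go_to_avoid", "nogo", -10)
  expect_equal(unname(st2$Q["nogo", "go_to_avoid"]), 0.4 * (-3))
  # neutral outcome decays toward zero; zero learning rate freezes the state
  st3 <- gng_update_state(st1, par, "go_to_win", "go", 0)
  expect_equal(unname(st3$Q["go", "go_to_win"]), 0.8 * (1 - 0.4))
  par0 <- gng_params(epsilon = 0, rho_rew = 2, rho_pun = 3)
  expect_equal(gng_update_state(st1, par0, "go_to_win", "go", 10), st1)
  expect_error(gng_update_state(st, par, "go_to_win", "go", 5))
})

test_that("the compiled session likelihood matches an independent R recursion", {
  sched <- generate_gonogo_schedule(50)
  set.seed(51)
  for (i in 1:5) {
    par <- random_gng_params()
    sim <- simulate_gng_agent(par, sched, seed = 60 + i)
    par2 <- random_gng_params()  # score under parameters != the generator's
    expect_equal(gng_session_loglik(par2, sim),
                 sum(log(oracle_gng_trial_p(par2, sim))), tolerance = 1e-10)
  }
})

test_that("a fully lapsing model scores every session at n log(1/2)", {
  sched <- generate_gonogo_schedule(52)
  sim <- simulate_gng_agent(gng_params(0.3, b = 1, rho_rew = 4), sched, seed = 53)
  expect_equal(gng_session_loglik(gng_params(0.2, xi = 1), sim),
               nrow(sim) * log(0.5))
})

test_that("the likelihood respects trial order", {
  sched <- generate_gonogo_schedule(54)
  set.seed(55)
  par <- random_gng_params()
  sim <- simulate_gng_agent(par, sched, seed = 56)
  shuffled <- sim[sample.int(nrow(sim)), ]
  # rows permuted but trial labels kept: reordered internally, same value
  expect_equal(gng_session_loglik(par, shuffled), gng_session_loglik(par, sim))
  # genuinely relabelling trial order changes the learning trajectory
  relabelled <- shuffled
  relabelled$trial <- seq_len(nrow(relabelled)) - 1L
  expect_false(isTRUE(all.equal(gng_session_loglik(par, relabelled),
                                gng_session_loglik(par, sim))))
})

test_that("reduced family members map correctly onto the canonical space", {
  expect_equal(gng_model_family()[1], "rw")
  expect_length(gng_model_family(), 5L)
  # shared rho and pi are duplicated into both canonical slots
  ps <- affbias:::gng_pspec("rw_b_pav")
  native <- matrix(c(0.3, 0.05, 0.2, 0.7, 4), 1,
                   dimnames = list(NULL, ps$names))
  full <- affbias:::gng_to_full(native, ps)
  expect_equal(unname(full[1, c("pi_approach", "pi_avoid")]), c(0.7, 0.7))
  expect_equal(unname(full[1, c("rho_rew", "rho_pun")]), c(4, 4))
  expect_equal(unname(full[1, "b"]), 0.2)
  expect_error(affbias:::gng_pspec("nope"), "unknown model_id")
})

test_that("the hierarchical go/no-go fit returns a well-formed posterior", {
  fit <- gng_fits_small()$s1
  expect_s3_class(fit, "gng_fit")
  expect_equal(dim(fit$subject_means), c(10L, 7L))
  expect_equal(rownames(fit$subject_means), sort(unique(gng_cohort_small()$trials$subject)))
  expect_true(all(is.finite(fit$rhat)))
  sm <- fit$subject_means
  expect_true(all(sm[, "epsilon"] > 0 & sm[, "epsilon"] < 1))
  expect_true(all(sm[, "xi"] > 0 & sm[, "xi"] < 1))
  expect_true(all(sm[, c("rho_rew", "rho_pun")] > 0))
  expect_equal(colnames(fit$subject_means_full),
               c("epsilon", "b", "pi_approach", "pi_avoid",
                 "rho_rew", "rho_pun", "xi"))
  expect_error(fit_hierarchical_gng(
    gng_cohort_small()$trials[gng_cohort_small()$trials$subject == "s001", ]),
    "at least 2 subjects")
})

test_that("WAIC comparison favours the model that generated the data", {
  gp <- default_group_params("gonogo")
  gp$mean[gp$parameter == "b"] <- 1.5
  gp$sd[gp$parameter == "b"] <- 0.3
  coh <- small_cohort("gonogo", n = 10, seed = 5, group_params = gp)
  s1 <- coh$trials[coh$trials$session == 1, ]
  mc <- quick_mcmc(seed = 9)
  f_rw <- fit_hierarchical_gng(s1, "rw", mc)
  f_rwb <- fit_hierarchical_gng(s1, "rw_b", mc)
  cmp <- compare_models(list(f_rw, f_rwb))
  expect_equal(cmp$model_id[cmp$rank == 1], "rw_b")
  expect_true(all(cmp$se > 0))

  # the same fit twice ties exactly
  tie <- compare_models(list(f_rw, f_rw))
  expect_equal(tie$waic[1], tie$waic[2])
  expect_equal(tie$rank, c(1L, 1L))

  # comparing fits of different data is refused
  other <- fit_hierarchical_gng(coh$trials[coh$trials$session == 2, ], "rw", mc)
  expect_error(compare_models(list(f_rw, other)), "identical data")
  expect_error(compare_models(list(gng_fits_small()$s1)), "pointwise")
})
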