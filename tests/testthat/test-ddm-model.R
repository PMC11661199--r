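# Diffusion treatments of the ambiguous-midpoint task: EZ closed form,
# Wiener first-passage density and sampler, hierarchical fit smoke tests.

test_that("ddm_params validates its ranges", {
  expect_error(ddm_params(alpha = -1))
  expect_error(ddm_params(alpha = 1, beta = 0))
  expect_error(ddm_params(alpha = 1, beta = 1))
  expect_error(ddm_params(alpha = 1, tau = -0.1))
  p <- ddm_params(1.5, 0.4, -0.3, 0.25)
  expect_equal(unname(unclass(p)), c(1.5, 0.4, -0.3, 0.25))
})

test_that("EZ estimates obey mirror symmetry and diffusion-constant scaling", {
  m_hi <- ez_moments(Pc = 0.8, VRT = 0.09, MRT = 0.7, N = 40)
  m_lo <- ez_moments(Pc = 0.2, VRT = 0.09, MRT = 0.7, N = 40)
  e_hi <- ez_ddm(m_hi); e_lo <- ez_ddm(m_lo)
  expect_equal(e_lo$v, -e_hi$v)
  expect_equal(e_lo$a, e_hi$a)
  expect_equal(e_lo$Ter, e_hi$Ter)
  # v and a scale with s; Ter does not
  e_s <- ez_ddm(m_hi, s = 0.1)
  expect_equal(e_s$v, 0.1 * e_hi$v)
  expect_equal(e_s$a, 0.1 * e_hi$a)
  expect_equal(e_s$Ter, e_hi$Ter)
})

test_that("EZ edge cases are corrected or refused", {
  m_half <- ez_moments(Pc = 0.5, VRT = 0.09, MRT = 0.7, N = 40)
  expect_error(ez_ddm(m_half, edge_correct = FALSE), "degenerate")
  e_half <- ez_ddm(m_half, edge_correct = TRUE)
  expect_true(is.finite(e_half$v))
  expect_true("edge_corrected_half" %in% e_half$flags)
  e_one <- ez_ddm(ez_moments(Pc = 1, VRT = 0.09, MRT = 0.7, N = 40))
  expect_true(is.finite(e_one$v))
  expect_true("edge_corrected_high" %in% e_one$flags)
  e_zero <- ez_ddm(ez_moments(Pc = 0, VRT = 0.09, MRT = 0.7, N = 40))
  expect_true("edge_corrected_low" %in% e_zero$flags)
  expect_equal(e_zero$v, -e_one$v)
})

test_that("the absorption probability matches the closed form", {
  expect_equal(ddm_choice_probability(ddm_params(2, 0.3, 0)), 0.3)
  expect_equal(ddm_choice_probability(ddm_params(2, 0.5, 1)),
               (1 - exp(-2)) / (1 - exp(-4)))
  expect_gt(ddm_choice_probability(ddm_params(2, 0.5, 10)), 0.999)
  expect_lt(ddm_choice_probability(ddm_params(2, 0.5, -10)), 0.001)
})

test_that("the Wiener density obeys the reflection identity", {
  rt <- seq(0.35, 3, length.out = 40)
  p <- ddm_params(1.7, 0.35, 0.8, 0.3)
  p_ref <- ddm_params(1.7, 1 - 0.35, -0.8, 0.3)
  expect_equal(wiener_logdensity(rt, "upper", p),
               wiener_logdensity(rt, "lower", p_ref), tolerance = 1e-12)
  expect_equal(wiener_logdensity(c(0.1, 0.3), "upper", p), c(-Inf, -Inf))
})

test_that("the density integrates to the absorption probability", {
  p <- ddm_params(1.5, 0.4, 0.7, 0.3)
  mass <- function(side) {
    integrate(function(t) exp(wiener_logdensity(t, side, p)),
              lower = p[["tau"]], upper = Inf, rel.tol = 1e-9)$value
  }
  expect_equal(mass("upper"), ddm_choice_probability(p), tolerance = 1e-6)
  expect_equal(mass("upper") + mass("lower"), 1, tolerance = 1e-6)
})

test_that("the first-passage sampler matches the closed-form boundary split", {
  set.seed(70)
  p <- ddm_params(1.5, 0.3, 0, 0.25)
  d <- rwiener_fp(2e4, p)
  expect_true(all(d$rt > p[["tau"]]))
  expect_equal(mean(d$boundary == "upper"), 0.3,
               tolerance = 4 * sqrt(0.3 * 0.7 / 2e4) / 0.3)
  set.seed(71)
  p2 <- ddm_params(2, 0.5, 1, 0)
  d2 <- rwiener_fp(2e4, p2)
  pu <- ddm_choice_probability(p2)
  expect_true(abs(mean(d2$boundary == "upper") - pu) <
                4 * sqrt(pu * (1 - pu) / 2e4))
})

test_that("per-session EZ estimates are deterministic and flag degeneracy", {
  coh <- am_cohort_small()
  ez <- ez_per_session(coh$trials)
  expect_equal(nrow(ez), 16L)  # 8 subjects x 2 sessions
  expect_true(all(ez$flag %in% c("", "edge_corrected_low",
                                 "edge_corrected_high", "edge_corrected_half",
                                 "negative_Ter")))
  # duplicated subject data yields identical estimates
  tr <- coh$trials[coh$trials$subject == "s001" & coh$trials$session == 1, ]
  twin <- tr; twin$subject <- "s999"
  both <- ez_per_session(rbind(tr, twin))
  expect_equal(both$v[1], both$v[2])
  expect_equal(both$a[1], both$a[2])
  # one responded mid trial -> degenerate moments
  degen <- tr[tr$condition == "mid", ][1, ]
  out <- ez_per_session(degen)
  expect_true(is.na(out$v))
  expect_equal(out$flag, "degenerate_moments")
})

test_that("the hierarchical diffusion fit returns a well-formed posterior", {
  coh <- am_cohort_small()
  s1 <- coh$trials[coh$trials$session == 1, ]
  fit <- cached_fixture("ddm_fit_small",
                        fit_hierarchical_ddm(s1, mcmc = quick_mcmc(seed = 23)))
  expect_s3_class(fit, "ddm_fit")
  expect_equal(colnames(fit$subject_means), c("alpha", "beta", "delta", "tau"))
  expect_equal(nrow(fit$subject_means), 8L)
  expect_true(all(fit$subject_means[, "alpha"] > 0))
  b <- fit$subject_means[, "beta"]
  expect_true(all(b > 0 & b < 1))
  # tau stays below each subject's fastest response
  minrt <- tapply(s1$rt[s1$condition == "mid"],
                  s1$subject[s1$condition == "mid"], min)
  expect_true(all(fit$subject_means[, "tau"] <
                    minrt[rownames(fit$subject_means)]))
  expect_true(all(is.finite(fit$rhat)))
})

test_that("diffusion data preparation rejects unusable sessions", {
  d <- data.frame(subject = "a", session = 1, condition = "small",
                  choice = "key_low", rt = 0.4, trial = 0)
  expect_error(affbias:::ddm_prepare(d), "no responded mid trials")
  d2 <- data.frame(subject = "a", session = 1,
                   condition = c("mid", "mid"), choice = c("key_low", "key_high"),
                   rt = c(0.4, -0.1), trial = 0:1)
  expect_error(affbias:::ddm_prepare(d2), "non-positive")
})
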