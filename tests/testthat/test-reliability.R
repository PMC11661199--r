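# Two-stage reliability statistics: Pearson, ICC(A,1), ICC(C,1).

test_that("paired measures are validated", {
  expect_error(paired_measures(c("a", "b"), 1:2, 1:2), "at least 3")
  expect_error(paired_measures(c("a", "b", "c"), c(1, NA, 3), 1:3), "missing")
  pm <- paired_measures(c("a", "b", "c"), 1:3, 3:1)
  expect_s3_class(pm, "paired_measures")
})

test_that("Pearson reliability hits the exact degenerate values", {
  pm_pos <- paired_measures(letters[1:4], c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_equal(pearson_reliability(pm_pos)$coefficient, 1)
  pm_neg <- paired_measures(letters[1:4], c(1, 2, 3, 4), c(8, 6, 4, 2))
  expect_equal(pearson_reliability(pm_neg)$coefficient, -1)
  pm_const <- paired_measures(letters[1:4], rep(2, 4), c(1, 2, 3, 4))
  e <- pearson_reliability(pm_const)
  expect_true(is.na(e$coefficient))
  expect_equal(e$flag, "undefined_constant")
})

test_that("Pearson reliability is invariant to positive affine transforms", {
  set.seed(80)
  x <- rnorm(30); y <- 0.6 * x + rnorm(30, sd = 0.7)
  r0 <- pearson_reliability(paired_measures(1:30, x, y))$coefficient
  r1 <- pearson_reliability(paired_measures(1:30, 3 * x - 2, 0.5 * y + 7))$coefficient
  expect_equal(r1, r0, tolerance = 1e-12)
})

test_that("the Fisher-z interval agrees with a percentile bootstrap", {
  set.seed(81)
  n <- 58
  x <- rnorm(n); y <- 0.7 * x + rnorm(n, sd = 0.8)
  est <- pearson_reliability(paired_measures(seq_len(n), x, y))
  B <- 2e4
  idx <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
  X <- matrix(x[idx], n, B); Y <- matrix(y[idx], n, B)
  cx <- sweep(X, 2, colMeans(X)); cy <- sweep(Y, 2, colMeans(Y))
  rb <- colSums(cx * cy) / sqrt(colSums(cx^2) * colSums(cy^2))
  boot_ci <- quantile(rb, c(0.025, 0.975))
  expect_lt(abs(est$ci_low - boot_ci[[1]]), 0.05)
  expect_lt(abs(est$ci_high - boot_ci[[2]]), 0.05)
})

test_that("ICC hits exact hand-computed values on toy data", {
  # identical sessions: perfect agreement and consistency
  pm_id <- paired_measures(letters[1:3], c(1, 2, 3), c(1, 2, 3))
  expect_equal(icc(pm_id, "agreement")$coefficient, 1)
  expect_equal(icc(pm_id, "consistency")$coefficient, 1)
  # constant shift: consistency 1, agreement 2/3 by hand ANOVA
  pm_sh <- paired_measures(letters[1:3], c(1, 2, 3), c(2, 3, 4))
  expect_equal(icc(pm_sh, "consistency")$coefficient, 1)
  expect_equal(icc(pm_sh, "agreement")$coefficient, 2 / 3)
  # no variance anywhere is undefined
  pm0 <- paired_measures(letters[1:3], rep(1, 3), rep(1, 3))
  expect_equal(icc(pm0, "agreement")$flag, "undefined_zero_variance")
})

test_that("ICCs match a from-scratch two-way ANOVA oracle on random data", {
  set.seed(82)
  for (i in 1:30) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- runif(1, 0.2, 0.9) * x + rnorm(n, sd = runif(1, 0.3, 1.5))
    pm <- paired_measures(seq_len(n), x, y)
    long <- data.frame(y = c(x, y),
                       subj = factor(rep(seq_len(n), 2)),
                       sess = factor(rep(1:2, each = n)))
    ms <- anova(lm(y ~ subj + sess, data = long))[["Mean Sq"]]
    MS_R <- ms[1]; MS_C <- ms[2]; MS_E <- ms[3]
    k <- 2
    icc_c <- (MS_R - MS_E) / (MS_R + (k - 1) * MS_E)
    icc_a <- (MS_R - MS_E) /
      (MS_R + (k - 1) * MS_E + (k / n) * (MS_C - MS_E))
    expect_equal(icc(pm, "consistency")$coefficient, icc_c, tolerance = 1e-10)
    expect_equal(icc(pm, "agreement")$coefficient, icc_a, tolerance = 1e-10)
    expect_equal(icc(pm, "consistency")$p_value,
                 pf(MS_R / MS_E, n - 1, n - 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("a session shift lowers agreement but not consistency", {
  set.seed(83)
  x <- rnorm(25); y <- 0.8 * x + rnorm(25, sd = 0.4)
  pm <- paired_measures(1:25, x, y)
  pm_sh <- paired_measures(1:25, x, y + 2)
  expect_equal(icc(pm_sh, "consistency")$coefficient,
               icc(pm, "consistency")$coefficient, tolerance = 1e-12)
  expect_lt(icc(pm_sh, "agreement")$coefficient,
            icc(pm, "agreement")$coefficient)
})

test_that("interval bands are labelled at the conventional cut points", {
  lab <- affbias:::band_label(c(0.9, 0.75, 0.5, 0.4, 0.1, NA))
  expect_equal(lab, c("excellent", "excellent", "moderate-good",
                      "moderate-good", "poor", NA))
})

test_that("the reliability table is complete and refuses mismatched subjects", {
  set.seed(84)
  m1 <- data.frame(subject = sprintf("s%02d", 1:20),
                   a = rnorm(20), b = rnorm(20))
  m2 <- data.frame(subject = sprintf("s%02d", 1:20),
                   a = rnorm(20), b = m1$b)  # b identical across sessions
  tab <- reliability_table(m1, m2)
  expect_equal(nrow(tab), 6L)
  expect_setequal(unique(tab$method), c("pearson", "icc_a1", "icc_c1"))
  b_rows <- tab[tab$measure == "b", ]
  expect_true(all(abs(b_rows$coefficient - 1) < 1e-12))
  expect_true(all(b_rows$band == "excellent"))
  # shuffled subject order is realigned, not misinterpreted
  m2_shuf <- m2[sample.int(20), ]
  tab2 <- reliability_table(m1, m2_shuf)
  expect_equal(tab2$coefficient, tab$coefficient, tolerance = 1e-12)
  m2_bad <- m2; m2_bad$subject[1] <- "s99"
  expect_error(reliability_table(m1, m2_bad), "s99")
})

test_that("two-stage correlation of noisy measures is attenuated on average", {
  set.seed(85)
  r_true <- 0.7
  atten <- replicate(40, {
    z1 <- rnorm(58)
    z2 <- r_true * z1 + sqrt(1 - r_true^2) * rnorm(58)
    cor(z1 + rnorm(58, sd = 0.6), z2 + rnorm(58, sd = 0.6))
  })
  expect_lt(mean(atten), r_true)
})
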