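# Two-stage test-retest reliability statistics: Pearson correlations and
# two-way single-measure intraclass correlations (absolute agreement
# ICC(A,1) and consistency ICC(C,1)) with F-based confidence intervals and
# p-values following McGraw & Wong's procedures (Satterthwaite degrees of
# freedom for the agreement interval).

#' Paired two-session measures
#'
#' @param subjects subject identifiers.
#' @param session1,session2 the measure at each session (same order).
#' @return a `paired_measures` data frame.
#' @export
paired_measures <- function(subjects, session1, session2) {
  stopifnot(length(subjects) == length(session1),
            length(session1) == length(session2))
  if (anyNA(session1) || anyNA(session2)) stop("missing pairs are not allowed")
  if (length(subjects) < 3) stop("need at least 3 complete pairs")
  structure(data.frame(subject = subjects, session1 = session1,
                       session2 = session2),
            class = c("paired_measures", "data.frame"))
}

rel_estimate <- function(method, coefficient, ci_low, ci_high, p_value,
                         flag = "") {
  structure(list(method = method, coefficient = coefficient,
                 ci_low = ci_low, ci_high = ci_high, p_value = p_value,
                 flag = flag),
            class = "reliability_estimate")
}

#' Pearson test-retest correlation
#'
#' Product-moment coefficient with a two-sided t-based p-value and a Fisher-z
#' confidence interval (as computed by [stats::cor.test()]).
#'
#' @param pm a [paired_measures()] object.
#' @param conf_level confidence level (default 0.95).
#' @return a `reliability_estimate`.
#' @export
pearson_reliability <- function(pm, conf_level = 0.95) {
  if (sd(pm$session1) == 0 || sd(pm$session2) == 0)
    return(rel_estimate("pearson", NA, NA, NA, NA, flag = "undefined_constant"))
  ct <- cor.test(pm$session1, pm$session2, conf.level = conf_level)
  rel_estimate("pearson", unname(ct$estimate), ct$conf.int[1], ct$conf.int[2],
               ct$p.value)
}

# Two-way mixed ANOVA mean squares for n subjects x k sessions.
anova_decomposition <- function(pm) {
  y <- cbind(pm$session1, pm$session2)
  n <- nrow(y); k <- ncol(y)
  grand <- mean(y)
  MS_R <- k * sum((rowMeans(y) - grand)^2) / (n - 1)
  MS_C <- n * sum((colMeans(y) - grand)^2) / (k - 1)
  SST <- sum((y - grand)^2)
  SSE <- SST - k * sum((rowMeans(y) - grand)^2) - n * sum((colMeans(y) - grand)^2)
  MS_E <- SSE / ((n - 1) * (k - 1))
  list(MS_R = MS_R, MS_C = MS_C, MS_E = max(MS_E, 0), n = n, k = k)
}

#' Two-way single-measure intraclass correlation
#'
#' From the two-way ANOVA decomposition (random subjects, fixed sessions):
#' consistency ICC(C,1) = (MS_R - MS_E) / (MS_R + (k-1) MS_E); absolute
#' agreement ICC(A,1) additionally charges the session mean-square:
#' (MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E)).  Confidence
#' intervals and p-values follow McGraw & Wong's F procedures; the agreement
#' interval uses Satterthwaite degrees of freedom.
#'
#' @param pm a [paired_measures()] object.
#' @param flavor `"agreement"` or `"consistency"`.
#' @param conf_level confidence level (default 0.95).
#' @return a `reliability_estimate` (`method` is `"icc_a1"` or `"icc_c1"`).
#' @export
icc <- function(pm, flavor = c("agreement", "consistency"),
                conf_level = 0.95) {
  flavor <- match.arg(flavor)
  ms <- anova_decomposition(pm)
  n <- ms$n; k <- ms$k
  alpha <- 1 - conf_level
  if (ms$MS_R <= 0 && ms$MS_C <= 0 && ms$MS_E <= 0)
    return(rel_estimate(ifelse(flavor == "agreement", "icc_a1", "icc_c1"),
                        NA, NA, NA, NA, flag = "undefined_zero_variance"))
  Fv <- ms$MS_R / ms$MS_E
  if (flavor == "consistency") {
    coef <- (ms$MS_R - ms$MS_E) / (ms$MS_R + (k - 1) * ms$MS_E)
    df2 <- (n - 1) * (k - 1)
    if (is.finite(Fv)) {
      FL <- Fv / qf(1 - alpha / 2, n - 1, df2)
      FU <- Fv * qf(1 - alpha / 2, df2, n - 1)
      ci <- c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
      p <- pf(Fv, n - 1, df2, lower.tail = FALSE)
    } else { ci <- c(1, 1); p <- 0 }
    rel_estimate("icc_c1", coef, ci[1], ci[2], p)
  } else {
    coef <- (ms$MS_R - ms$MS_E) /
      (ms$MS_R + (k - 1) * ms$MS_E + (k / n) * (ms$MS_C - ms$MS_E))
    a <- (k * coef) / (n * (1 - coef))
    b <- 1 + (k * coef * (n - 1)) / (n * (1 - coef))
    v <- (a * ms$MS_C + b * ms$MS_E)^2 /
      ((a * ms$MS_C)^2 / (k - 1) + (b * ms$MS_E)^2 / ((n - 1) * (k - 1)))
    if (is.finite(v) && v > 0 && is.finite(Fv)) {
      FL <- qf(1 - alpha / 2, n - 1, v)
      FU <- qf(1 - alpha / 2, v, n - 1)
      lower <- n * (ms$MS_R - FL * ms$MS_E) /
        (FL * (k * ms$MS_C + (k * n - k - n) * ms$MS_E) + n * ms$MS_R)
      upper <- n * (FU * ms$MS_R - ms$MS_E) /
        (k * ms$MS_C + (k * n - k - n) * ms$MS_E + n * FU * ms$MS_R)
      p <- pf(Fv, n - 1, v, lower.tail = FALSE)
      ci <- c(lower, upper)
    } else { ci <- c(coef, coef); p <- if (is.finite(Fv)) NA else 0 }
    rel_estimate("icc_a1", coef, ci[1], ci[2], p)
  }
}

band_label <- function(x) {
  ifelse(is.na(x), NA_character_,
         ifelse(x >= 0.75, "excellent",
                ifelse(x >= 0.4, "moderate-good", "poor")))
}

#' Reliability table across measures
#'
#' Computes all three reliability statistics (Pearson, ICC(A,1), ICC(C,1))
#' for every measure column shared by the two session tables, with the
#' conventional banding (>= 0.4 moderate-good, >= 0.75 excellent, below 0.4
#' poor).
#'
#' @param measures1,measures2 data frames with a `subject` column plus one
#'   column per measure, for session 1 and session 2.
#' @param conf_level confidence level for all intervals (default 0.95).
#' @return long data frame: `measure`, `method`, `coefficient`, `ci_low`,
#'   `ci_high`, `p_value`, `band`, `flag` (3 rows per measure).
#' @export
reliability_table <- function(measures1, measures2, conf_level = 0.95) {
  stopifnot("subject" %in% names(measures1), "subject" %in% names(measures2))
  off <- c(setdiff(measures1$subject, measures2$subject),
           setdiff(measures2$subject, measures1$subject))
  if (length(off) > 0)
    stop("subjects not matched across sessions: ", paste(off, collapse = ", "))
  measures2 <- measures2[match(measures1$subject, measures2$subject), ]
  cols <- intersect(setdiff(names(measures1), "subject"),
                    setdiff(names(measures2), "subject"))
  out <- do.call(rbind, lapply(cols, function(m) {
    keep <- complete.cases(measures1[[m]], measures2[[m]])
    pm <- paired_measures(measures1$subject[keep], measures1[[m]][keep],
                          measures2[[m]][keep])
    ests <- list(pearson_reliability(pm, conf_level),
                 icc(pm, "agreement", conf_level),
                 icc(pm, "consistency", conf_level))
    do.call(rbind, lapply(ests, function(e)
      data.frame(measure = m, method = e$method, coefficient = e$coefficient,
                 ci_low = e$ci_low, ci_high = e$ci_high, p_value = e$p_value,
                 band = band_label(e$coefficient), flag = e$flag)))
  }))
  rownames(out) <- NULL
  out
}
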