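# Difference-score statistics: outlier handling, paired tests against
# exhaustive rank oracles, Friedman baseline checks and mixed models.

test_that("difference scores subtract the matching baseline", {
  df <- expand.grid(subject = 1:4, measure = "m",
                    condition = c("3.4s real", "3.4s sham", "30s real", "30s sham"),
                    phase = c("baseline", "stim"), stringsAsFactors = FALSE)
  df$value <- 10
  d <- difference_scores(df)
  expect_equal(nrow(d), 16)  # 4 subjects x 4 conditions
  expect_true(all(d$diff == 0))
  # shift invariance
  df2 <- df
  df2$value <- df2$value + 7
  expect_equal(difference_scores(df2)$diff, d$diff)
  # missing baseline flagged
  df3 <- df[!(df$phase == "baseline" & df$subject == 1 & df$condition == "3.4s real"), ]
  d3 <- difference_scores(df3)
  expect_equal(sum(is.na(d3$diff)), 1)
  expect_length(attr(d3, "missing"), 1)
})

test_that("MAD outlier removal flags gross outliers and is idempotent here", {
  r <- remove_outliers_mad(c(1, 1, 1, 1, 100))
  expect_equal(r$removed_idx, 5L)
  expect_equal(r$kept, rep(1, 4))
  r2 <- remove_outliers_mad(r$kept, k = 3)
  expect_length(r2$removed_idx, 0)
  sym <- c(-2, -1, -0.5, 0, 0.5, 1, 2)
  expect_length(remove_outliers_mad(sym)$removed_idx, 0)
  expect_error(remove_outliers_mad(c(1, 2)))
})

test_that("identical vectors give a degenerate paired comparison", {
  r <- paired_compare(1:10, 1:10)
  expect_true(r$degenerate)
  expect_true(is.na(r$p))
  expect_error(paired_compare(1:3, 2:4), "5")
})

test_that("Wilcoxon branch matches exhaustive enumeration of sign assignments", {
  # clearly non-normal pair differences force the rank test
  x <- c(1, 2, 3, 4, 5, 6, 40, 44)
  y <- c(2, 4, 6, 8, 10, 12, 13, 15)
  d <- x - y
  expect_lt(shapiro.test(d)$p.value, 0.05)
  r <- paired_compare(x, y)
  expect_equal(r$test, "wilcoxon")
  expect_equal(r$p, oracle_signed_rank_p(d))
  # W statistic is the positive-rank sum
  expect_equal(r$statistic, sum(rank(abs(d))[d > 0]))
})

test_that("a synthetic condition effect is detected with positive effect size", {
  s <- gen_saliva_table(27, condition_effect = 60, noise = 0.3, seed = 21)
  long <- data.frame(subject = s$subject, measure = "conc",
                     condition = paste(s$protocol, s$arm), phase = s$phase,
                     value = s$concentration)
  d <- difference_scores(long)
  real <- d$diff[d$condition == "30s real"]
  sham <- d$diff[d$condition == "30s sham"]
  r <- paired_compare(real, sham)
  expect_lte(r$p, 0.05)
  expect_gt(r$effect_size_d, 0)
})

test_that("paired_compare holds its nominal type-I rate on null data", {
  set.seed(22)
  n_sim <- 400
  rejections <- vapply(seq_len(n_sim), function(i) {
    s <- gen_saliva_table(20, condition_effect = 0, seed = 3000 + i)
    long <- data.frame(subject = s$subject, measure = "conc",
                       condition = paste(s$protocol, s$arm), phase = s$phase,
                       value = s$concentration)
    d <- difference_scores(long)
    r <- paired_compare(d$diff[d$condition == "30s real"],
                        d$diff[d$condition == "30s sham"])
    r$p <= 0.05
  }, logical(1))
  rate <- mean(rejections)
  mc_se <- sqrt(0.05 * 0.95 / n_sim)
  expect_lte(rate, 0.05 + 3 * mc_se)
  expect_gte(rate, 0.05 - 3 * mc_se)
})

test_that("Friedman baseline check reports k-1 df and triggers pairwise follow-ups", {
  m <- matrix(rnorm(40), 10, 4)
  r <- baseline_check(m)
  expect_equal(r$friedman$df, 3)
  # constructed so column 4 dominates: follow-up triggered
  strong <- matrix(rnorm(24, sd = 0.1), 6, 4)
  strong[, 4] <- strong[, 4] + 5
  r2 <- baseline_check(strong)
  expect_lte(r2$friedman$p, 0.05)
  expect_false(is.null(r2$pairwise))
  expect_equal(nrow(r2$pairwise), 6)
})

test_that("Friedman statistic and p agree with exhaustive within-subject permutation", {
  m <- matrix(c(1.2, 2.5, 3.1,
                0.8, 2.2, 2.9,
                1.5, 1.9, 3.4,
                1.1, 2.8, 2.4,
                0.9, 2.6, 3.0), 5, 3, byrow = TRUE)
  r <- baseline_check(m)
  expect_equal(r$friedman$chisq, oracle_friedman_chisq(m))
  p_exact <- oracle_friedman_exact_p(m)
  # the chi-square approximation should track the exact permutation p
  expect_equal(r$friedman$p, p_exact, tolerance = 0.05)
})

test_that("identical baseline columns give a zero Friedman statistic", {
  m <- matrix(rep(c(1, 3, 2, 5, 4, 6), 4), 6, 4)
  expect_equal(baseline_check(m)$friedman$chisq, 0)
})

test_that("the mixed model collapses to OLS with no between-subject variance", {
  set.seed(23)
  df <- expand.grid(subject = 1:20, arm = c("real", "sham"), rep = 1:3)
  df$value <- 0.4 * (df$arm == "real") + rnorm(nrow(df), sd = 0.3)
  fit <- suppressMessages(fit_random_intercept_lmm(df, "value", "arm"))
  ols <- stats::lm(value ~ C(factor(arm), contr.sum), df)
  expect_equal(fit$estimate, unname(coef(ols)), tolerance = 1e-5)
  vc <- lme4::VarCorr(attr(fit, "model"))
  expect_lt(as.numeric(vc$subject), 1e-4)
})

test_that("the mixed model recovers a known contrast effect", {
  set.seed(24)
  n <- 30
  df <- expand.grid(subject = 1:n, arm = c("real", "sham"), rep = 1:4)
  df$value <- ifelse(df$arm == "real", 0.5, -0.5) +
    rep(rnorm(n, sd = 0.4), 8) + rnorm(nrow(df), sd = 0.3)
  fit <- fit_random_intercept_lmm(df, "value", "arm")
  est <- fit$estimate[fit$term == "arm1"]
  # sum coding: the arm1 coefficient is half the real-sham difference = 0.5
  expect_equal(est, 0.5, tolerance = 0.1)
  expect_true(all(fit$df > 0))
})

test_that("Bonferroni multiplies by the family size and caps at 1", {
  expect_equal(bonferroni(c(0.01, 0.2), m = 12), c(0.12, 1))
  df <- expand.grid(subject = 1:10, arm = c("real", "sham"))
  set.seed(25)
  df$value <- rnorm(nrow(df))
  fit <- suppressMessages(fit_random_intercept_lmm(df, "value", "arm", m = 12))
  expect_equal(fit$p_bonferroni, pmin(1, fit$p * 12))
})
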