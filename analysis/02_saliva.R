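#!/usr/bin/env Rscript
# Step 2 - saliva markers: flow-rate-independent secretion, difference
# scores against session baselines, paired real-vs-sham comparisons per
# protocol, a Friedman check of the four baselines, and the
# time-of-day mixed model on concentration.

suppressMessages(library(tavnspipe))

seed <- 20240
dir.create("results", showWarnings = FALSE)

sal <- gen_saliva_table(n_subjects = 24, condition_effect = 40, seed = seed)
sal$secretion <- compute_secretion(sal$concentration, sal$sample_weight_g,
                                   sal$collection_duration_min)
sal$daytime <- assign_daytime_bin(sal$clock_time)

long <- rbind(
  data.frame(subject = sal$subject, measure = "concentration",
             condition = paste(sal$protocol, sal$arm), phase = sal$phase,
             value = sal$concentration),
  data.frame(subject = sal$subject, measure = "secretion",
             condition = paste(sal$protocol, sal$arm), phase = sal$phase,
             value = sal$secretion))
diffs <- difference_scores(long)

tests <- list()
for (meas in c("concentration", "secretion")) {
  for (proto in c("3.4s", "30s")) {
    d <- diffs[diffs$measure == meas, ]
    res <- paired_compare(d$diff[d$condition == paste(proto, "real")],
                          d$diff[d$condition == paste(proto, "sham")])
    res$measure <- meas; res$protocol <- proto
    tests[[length(tests) + 1]] <- res
    message(sprintf("%s %s: %s statistic=%.1f p=%.4f%s", meas, proto,
                    res$test, res$statistic, res$p,
                    if (!is.na(res$effect_size_d))
                      sprintf(" d=%.2f", res$effect_size_d) else ""))
  }
}
tests <- do.call(rbind, tests)
write.table(tests, "results/saliva_tests.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

base_wide <- with(sal[sal$phase == "baseline", ],
                  tapply(concentration, list(subject, paste(protocol, arm)), mean))
bc <- baseline_check(base_wide)
message(sprintf("baseline Friedman: chi2(%d)=%.2f p=%.3f",
                bc$friedman$df, bc$friedman$chisq, bc$friedman$p))

lmm <- fit_random_intercept_lmm(sal[sal$phase == "stim", ], "concentration",
                                fixed = "arm * daytime", subject = "subject")
write.table(lmm, "results/saliva_lmm.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
message("time-of-day mixed model written to results/saliva_lmm.tsv")
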