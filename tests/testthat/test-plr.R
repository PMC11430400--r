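# Light-reflex preprocessing, QC and parameter extraction, checked against
# the generator's closed-form ground truth.

noiseless_epoch <- function(model, rate = 120) {
  t <- seq(-1, 9 - 1 / rate, by = 1 / rate)
  structure(list(eye = "left", flash_time = 0, intensity = 1, time = t,
                 samples = tavnspipe:::plr_model_eval(model, t), rate = rate,
                 qc_status = NULL), class = "plr_epoch")
}

test_that("a 12-flash session yields 12 epochs per eye", {
  g <- gen_plr_recording(plr_gen_model(noise_sd = 0.02),
                         seq(5, by = 11, length.out = 12), seed = 1)
  eps <- preprocess_plr(g$recording, g$flash_times)
  expect_length(eps, 24)
  expect_equal(sum(vapply(eps, function(e) e$eye == "left", logical(1))), 12)
  expect_equal(vapply(eps[1:12], `[[`, numeric(1), "intensity"),
               rep(1:4, 3))
})

test_that("the smoothing filter has unit DC gain and tracks the noiseless model", {
  rec <- pupil_recording(seq(0, 20, by = 1 / 120), rep(5, 2401), rep(5, 2401),
                         rate = 120)
  eps <- preprocess_plr(rec, 5)
  expect_equal(eps[[1]]$samples, rep(5, length(eps[[1]]$samples)),
               tolerance = 1e-9)
  m <- plr_gen_model(d1 = 7, d2 = 4, t_latency = 0.25, t_min = 1.1,
                     redil_tau = 2, noise_sd = 0)
  g <- gen_plr_recording(m, 15, seed = 2)
  ep <- preprocess_plr(g$recording, 15)[[1]]
  model_vals <- tavnspipe:::plr_model_eval(m, ep$time)
  # away from the sharp constriction edges the filtered trace stays close
  edge <- ep$time > 0.05 & ep$time < 1.6
  expect_lt(max(abs(ep$samples - model_vals)[!edge]), 0.05)
})

test_that("epochs past the recording edge are dropped with a log entry", {
  rec <- pupil_recording(seq(0, 12, by = 1 / 120), rep(5, 1441), rep(5, 1441),
                         rate = 120)
  eps <- preprocess_plr(rec, 8)  # needs data to 17 s
  expect_length(eps, 0)
  expect_equal(nrow(attr(eps, "dropped")), 2)
})

test_that("QC passes clean reflexes and names the violated criterion", {
  m <- plr_gen_model()
  expect_equal(qc_plr(noiseless_epoch(m)), "pass")
  flat <- noiseless_epoch(m)
  flat$samples <- rep(m$d1, length(flat$samples))
  expect_equal(qc_plr(flat), "fail:rapid_constriction")
  stepped <- noiseless_epoch(m)
  stepped$samples[600] <- stepped$samples[600] + 2
  expect_equal(qc_plr(stepped), "fail:fluctuation")
  wobbly <- noiseless_epoch(m)
  wobbly$samples[wobbly$time < 0] <- m$d1 + rep(c(-0.5, 0.5), length.out = sum(wobbly$time < 0))
  expect_equal(qc_plr(wobbly), "fail:stable_baseline")
})

test_that("noiseless extraction recovers every parameter within tolerance", {
  models <- list(
    plr_gen_model(d1 = 7, d2 = 4, t_latency = 0.25, t_min = 1.1, redil_tau = 2, noise_sd = 0),
    plr_gen_model(d1 = 6, d2 = 4.5, t_latency = 0.2, t_min = 0.9, redil_tau = 1.5, noise_sd = 0),
    plr_gen_model(d1 = 8, d2 = 5, t_latency = 0.3, t_min = 1.4, redil_tau = 3, noise_sd = 0))
  two_samples <- 2 / 120
  for (m in models) {
    p <- extract_plr_parameters(noiseless_epoch(m))
    truth <- tavnspipe:::plr_model_truth(m)
    expect_equal(p$D1, truth$D1, tolerance = 0.05)
    expect_equal(p$D2, truth$D2, tolerance = 0.05)
    expect_equal(p$AMP, truth$AMP, tolerance = 0.05)
    expect_equal(p$Rel_AMP, truth$Rel_AMP, tolerance = 0.01)
    expect_lt(abs(p$T1 - truth$T1), two_samples)
    expect_lt(abs(p$T2 - truth$T2), two_samples)
    expect_lt(abs(p$T3 - truth$T3), 2 * two_samples)
    expect_lt(abs(p$Redil_25 - truth$Redil_25), two_samples)
    expect_lt(abs(p$Redil_50 - truth$Redil_50), two_samples)
    expect_lt(abs(p$Redil_75 - truth$Redil_75), two_samples)
    expect_equal(p$VCmax, truth$VCmax, tolerance = 0.01)
    expect_equal(p$ACmax, truth$ACmax, tolerance = 0.02)
    # exact identities of the computed values
    expect_equal(p$AMP, p$D1 - p$D2)
    expect_equal(p$Rel_AMP, p$AMP / p$D1)
    expect_equal(p$T3, p$T2 - p$T1)
  }
})

test_that("redilation with tau = 2 s recovers Redil_50 near 2 ln 2", {
  m <- plr_gen_model(redil_tau = 2, noise_sd = 0)
  p <- extract_plr_parameters(noiseless_epoch(m))
  expect_equal(p$Redil_50, 2 * log(2), tolerance = 0.02)
})

test_that("redilation times are ordered on monotone recoveries", {
  for (seed in 1:5) {
    g <- gen_plr_recording(plr_gen_model(noise_sd = 0.03), c(5, 16), seed = seed)
    eps <- preprocess_plr(g$recording, g$flash_times)
    for (ep in eps) {
      p <- extract_plr_parameters(ep)
      if (!anyNA(c(p$Redil_25, p$Redil_50, p$Redil_75))) {
        expect_true(p$Redil_25 <= p$Redil_50)
        expect_true(p$Redil_50 <= p$Redil_75)
      }
    }
  }
})

test_that("extraction is a pure function of the epoch", {
  ep <- noiseless_epoch(plr_gen_model())
  expect_identical(extract_plr_parameters(ep), extract_plr_parameters(ep))
})

test_that("cell aggregation removes 3 SD outliers in one pass", {
  vals <- data.frame(eye = "left", intensity = 1, parameter = "AMP",
                     value = c(rep(3, 11), 30))
  agg <- aggregate_plr(vals)
  expect_equal(agg$value, 3)
  expect_equal(agg$n, 11)
  expect_equal(attr(agg, "removed"), 1L)
  same <- data.frame(eye = "left", intensity = 1, parameter = "AMP",
                     value = rep(2.5, 6))
  agg2 <- aggregate_plr(same)
  expect_equal(agg2$value, 2.5)
  expect_equal(attr(agg2, "removed"), 0L)
})

test_that("per-subject aggregation yields 12 parameters per condition cell", {
  g <- gen_plr_recording(plr_gen_model(noise_sd = 0.02),
                         seq(5, by = 11, length.out = 12), seed = 6)
  eps <- preprocess_plr(g$recording, g$flash_times)
  ok <- vapply(eps, function(e) qc_plr(e) == "pass", logical(1))
  params <- do.call(rbind, lapply(eps[ok], extract_plr_parameters))
  par_cols <- setdiff(names(params), c("eye", "intensity", "flash_time"))
  expect_length(par_cols, 12)
  long <- do.call(rbind, lapply(par_cols, function(pc) {
    data.frame(eye = params$eye, intensity = params$intensity,
               parameter = pc, value = params[[pc]])
  }))
  agg <- aggregate_plr(long)
  expect_equal(sort(unique(agg$parameter)), sort(par_cols))
})
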