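# Synthetic generators: degenerate cases, ground-truth consistency,
# determinism.

test_that("degenerate resting-pupil config yields a constant trace of the right length", {
  cfg <- pupil_gen_config(noise_sd = 0, blink_rate = 0,
                          stim_response_amplitude = 0, duration = 60, seed = 1)
  g <- gen_pupil_rest_recording(cfg)
  expect_length(g$recording$eyes$left$diameter, 7200)
  expect_length(g$recording$eyes$right$diameter, 7200)
  expect_true(all(abs(g$recording$eyes$left$diameter - 4.5) < 1e-12))
  expect_equal(nrow(g$blinks), 0)
})

test_that("non-positive duration is rejected", {
  expect_error(pupil_gen_config(duration = 0), "duration")
  expect_error(pupil_gen_config(duration = -5), "duration")
})

test_that("scheduled blinks zero confidence over their ground-truth interval", {
  cfg <- pupil_gen_config(noise_sd = 0, blink_rate = 0, blink_times = 10,
                          blink_duration = 200, duration = 30, seed = 2)
  g <- gen_pupil_rest_recording(cfg)
  expect_equal(g$blinks$onset, 10)
  expect_equal(g$blinks$offset, 10.2)
  t <- g$recording$time
  inside <- t >= 10 & t <= 10.2
  expect_gte(mean(g$recording$eyes$left$confidence[inside] == 0), 0.95)
  # the collapse dips below the physiological floor
  expect_lt(min(g$recording$eyes$left$diameter[inside]), 1.5)
})

test_that("stimulation transient is smooth, unimodal and of stated amplitude", {
  cfg <- pupil_gen_config(noise_sd = 0, blink_rate = 0, duration = 40,
                          stim_onsets = 10, stim_response_amplitude = 0.3,
                          stim_response_latency = 0.5, seed = 3)
  g <- gen_pupil_rest_recording(cfg)
  d <- g$recording$eyes$left$diameter - 4.5
  expect_equal(max(d), 0.3, tolerance = 1e-6)
  expect_true(all(d[g$recording$time <= 10.5] < 1e-9))
})

test_that("light-reflex generator returns analytic truth per flash", {
  m <- plr_gen_model(d1 = 7, d2 = 4, noise_sd = 0)
  fl <- seq(5, by = 11, length.out = 12)
  g <- gen_plr_recording(m, fl, seed = 4)
  expect_equal(nrow(g$truth), 12)
  expect_equal(g$truth$AMP[1], 3)
  expect_equal(g$truth$Rel_AMP[1], 3 / 7)
  expect_error(gen_plr_recording(m, c(5, 10)), "spaced")
})

test_that("redilation crossing times match the closed-form exponential solution", {
  # oracle: sample the continuous model densely and read off crossings
  m <- plr_gen_model(d1 = 7, d2 = 4, t_latency = 0.25, t_min = 1.1,
                     redil_tau = 2, noise_sd = 0)
  s <- seq(0, 9, by = 1e-4)
  x <- tavnspipe:::plr_model_eval(m, s)
  for (q in c(0.25, 0.50, 0.75)) {
    target <- 4 + q * 3
    cross <- s[which(s > 1.1 & x >= target)[1]] - 1.1
    expect_equal(cross, 2 * log(1 / (1 - q)), tolerance = 1e-3)
  }
  expect_equal(m$redil_tau * log(4), 2 * log(4))
})

test_that("band-power generator injects the stated standardized shift", {
  g <- gen_eeg_epochs(20, 8, 30, effect_window = list(channels = 1:5, times = 5:24),
                      effect_size = 2.0, seed = 5)
  inside <- apply(g$data[, 1:5, 5:24], c(2, 3), mean)
  expect_equal(mean(inside), 2.0, tolerance = 0.5)
  expect_true(all(g$truth[1:5, 5:24]))
  expect_equal(sum(g$truth), 5 * 20)
  g0 <- gen_eeg_epochs(5, 4, 10, effect_size = 0, seed = 6)
  expect_true(all(is.finite(g0$data)))
  expect_error(gen_eeg_epochs(5, 4, 10, effect_size = 1), "effect_window")
})

test_that("GNG generator produces the session structure with exact Go counts", {
  g <- gen_gng_trials(seed = 7)
  expect_equal(nrow(g), 276)
  expect_equal(sum(g$is_go), 184)
  expect_true(all(table(g$block) == 92))
  # error-free agent scores perfectly
  g0 <- gen_gng_trials(go_omission_rate = 0, go_error_rate = 0,
                       nogo_commission_rate = 0, seed = 8)
  sc <- score_gng(g0)
  expect_equal(sc$accuracy, 1)
  expect_equal(sc$error_rate, 0)
})

test_that("No-Go commission rate is honoured (binomial check)", {
  counts <- vapply(1:8, function(i) {
    g <- gen_gng_trials(nogo_commission_rate = 0.2, seed = 100 + i)
    score_gng(g)$counts[["commission"]]
  }, numeric(1))
  n_nogo <- 92  # per session
  p_hat <- mean(counts) / n_nogo
  expect_equal(p_hat, 0.2, tolerance = 0.05)
})

test_that("saliva table mirrors the 4-baseline + 4-stimulation layout", {
  s <- gen_saliva_table(6, seed = 9)
  expect_equal(nrow(s), 6 * 8)
  per_subj <- table(s$subject, paste(s$protocol, s$arm, s$phase))
  expect_true(all(per_subj == 1))
  expect_true(all(s$concentration > 0))
  expect_error(gen_saliva_table(1), "n_subjects")
})

test_that("fixed seed reproduces every generator bitwise", {
  expect_identical(gen_pupil_rest_recording(pupil_gen_config(seed = 11, duration = 10)),
                   gen_pupil_rest_recording(pupil_gen_config(seed = 11, duration = 10)))
  m <- plr_gen_model()
  expect_identical(gen_plr_recording(m, c(5, 16), seed = 12),
                   gen_plr_recording(m, c(5, 16), seed = 12))
  expect_identical(gen_eeg_epochs(4, 3, 10, seed = 13),
                   gen_eeg_epochs(4, 3, 10, seed = 13))
  expect_identical(gen_gng_trials(seed = 14), gen_gng_trials(seed = 14))
  expect_identical(gen_saliva_table(4, seed = 15), gen_saliva_table(4, seed = 15))
  expect_identical(gen_erp_epochs(seed = 16), gen_erp_epochs(seed = 16))
  # and a different seed differs
  expect_false(identical(gen_gng_trials(seed = 14), gen_gng_trials(seed = 15)))
})

test_that("generators leave the global RNG state untouched", {
  set.seed(99)
  expected <- runif(1)
  set.seed(99)
  invisible(gen_saliva_table(3, seed = 42))
  expect_identical(runif(1), expected)
})
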