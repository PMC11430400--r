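# Resting-pupil pipeline: segmentation windows, screening rules with
# brute-force threshold oracles, blink detection, normalization and
# subject-level finalization.

make_replicate <- function(samples, rate = 120, baseline_s = 2,
                           confidence = rep(1, length(samples))) {
  n <- length(samples)
  time <- (seq_len(n) - 1) / rate - baseline_s
  tavnspipe:::new_replicate("left", 0, time, samples, confidence, rate)
}

test_that("stimulation protocols encode the printed windows and duty cycle", {
  p30 <- protocol_spec("30s")
  expect_equal(p30$replicate_length, 60)
  expect_equal(p30$duty_cycle_pct, 0.625)
  p34 <- protocol_spec("3.4s")
  expect_equal(p34$replicate_length, 32)
  expect_equal(p34$baseline_window, 2)
})

test_that("segmentation spans [-2, stim+post) around each onset", {
  cfg <- pupil_gen_config(duration = 200, noise_sd = 0, blink_rate = 0, seed = 1)
  rec <- gen_pupil_rest_recording(cfg)$recording
  reps <- segment_replicates(rec, 100, protocol_spec("30s"))
  expect_length(reps, 2)  # one per eye
  r <- reps[[1]]
  expect_equal(min(r$time), -2, tolerance = 1 / 120)
  expect_lt(max(r$time), 58)
  expect_equal(length(r$samples), 60 * 120)
  # absolute coverage [98, 158) s
  expect_equal(r$onset + range(r$time)[1], 98, tolerance = 1 / 120)
})

test_that("empty onset lists and truncated windows are handled", {
  cfg <- pupil_gen_config(duration = 100, seed = 2)
  rec <- gen_pupil_rest_recording(cfg)$recording
  expect_length(segment_replicates(rec, numeric(0), protocol_spec("30s")), 0)
  reps <- segment_replicates(rec, c(20, 90), protocol_spec("30s"))
  expect_length(reps, 2)  # the onset at 90 is truncated for both eyes
  expect_equal(nrow(attr(reps, "dropped")), 2)
  expect_equal(attr(reps, "dropped")$reason, rep("window_truncated", 2))
})

test_that("a 20-minute recording with 60 s spaced onsets yields 19 replicates per eye", {
  cfg <- pupil_gen_config(duration = 1200, noise_sd = 0, blink_rate = 0, seed = 3)
  rec <- gen_pupil_rest_recording(cfg)$recording
  reps <- segment_replicates(rec, seq(60, 1140, by = 60), protocol_spec("30s"))
  expect_equal(sum(vapply(reps, function(r) r$eye == "left", logical(1))), 19)
  expect_equal(sum(vapply(reps, function(r) r$eye == "right", logical(1))), 19)
})

test_that("constant traces pass screening unflagged", {
  r <- screen_replicate(make_replicate(rep(4, 3840)))
  expect_equal(r$status, "kept")
  expect_true(all(r$mask == "valid"))
})

test_that("a single jump is MAD-flagged exactly as brute force predicts", {
  set.seed(10)
  x <- 4 + cumsum(rnorm(3840, sd = 1e-4))  # smooth wander
  x[2000] <- x[2000] + 3                   # one 3 mm jump up and back
  r <- screen_replicate(make_replicate(x))
  # oracle: recompute the threshold from scratch
  d <- abs(diff(x))
  thr <- median(d) + 6 * mad(d, constant = 1)
  expected_flags <- which(d > thr) + 1L
  expect_identical(which(r$mask == "mad_excluded"), expected_flags)
  expect_equal(r$status, "kept")
  expect_equal(r$screen_log$mad_flagged, length(expected_flags))
})

test_that("more than 2% MAD-flagged samples excludes the replicate", {
  set.seed(11)
  x <- 4 + cumsum(rnorm(3840, sd = 1e-4))
  jumps <- seq(100, by = 40, length.out = 50)  # 50 isolated jumps -> 100 flags
  x[jumps] <- x[jumps] + 2
  r <- screen_replicate(make_replicate(x))
  expect_match(r$status, "excluded:mad_nan")
})

test_that("out-of-range samples beyond 5% exclude the replicate", {
  x <- rep(4, 4000)
  x[1:400] <- 1.0  # 10% below the 1.5 mm floor
  r <- screen_replicate(make_replicate(x))
  expect_equal(r$status, "excluded:blink_range")
  expect_gte(r$screen_log$range_flagged + r$screen_log$blink_flagged, 400)
})

test_that("mostly-invalid replicates are excluded before blink screening", {
  x <- rep(NaN, 4000)
  x[1:1000] <- 4
  r <- screen_replicate(make_replicate(x))
  expect_equal(r$status, "excluded:invalid_before_blink")
})

test_that("blink detector finds scheduled blinks and merges close ones", {
  expect_equal(nrow(detect_blinks(rep(4, 1200), rep(1, 1200), 120)), 0)
  cfg <- pupil_gen_config(noise_sd = 0, blink_rate = 0, blink_times = 10,
                          blink_duration = 200, duration = 30, seed = 4)
  g <- gen_pupil_rest_recording(cfg)
  bl <- detect_blinks(g$recording$eyes$left$diameter,
                      g$recording$eyes$left$confidence, 120)
  expect_equal(nrow(bl), 1)
  covered <- max(0, min(bl$offset[1], 10.2) - max(bl$onset[1], 10.0))
  expect_gte(covered / 0.2, 0.9)
  # two blinks 50 ms apart merge after 100 ms padding
  conf <- rep(1, 1200)
  conf[241:252] <- 0                 # blink 1: 2.00-2.09 s
  conf[259:270] <- 0                 # blink 2: 50 ms later
  bl2 <- detect_blinks(rep(4, 1200), conf, 120)
  expect_equal(nrow(bl2), 1)
})

test_that("normalization interpolates linearly and zeroes the baseline exactly", {
  x <- rep(5, 3840)
  x[1000:1004] <- NaN
  x[999] <- 4; x[1005] <- 4.5
  r <- make_replicate(x)
  r$mask[1000:1004] <- "blink"
  out <- normalize_replicate(r, screen_config(smooth_window = 1))
  expect_equal(out$samples[999:1005] + out$baseline_mean,
               seq(4, 4.5, length.out = 7))
  expect_identical(out$mask[1000:1004], rep("interpolated", 5))
  expect_equal(mean(out$samples[out$time >= -2 & out$time < 0]), 0)
  # smooth trace: baseline mean 5 -> stim window shifted by -5
  r2 <- normalize_replicate(make_replicate(rep(5, 3840)), screen_config())
  expect_equal(mean(r2$samples[r2$time >= -2 & r2$time < 0]), 0)
  expect_equal(unique(round(r2$samples, 12)), 0)
  expect_equal(r2$baseline_mean, 5)
})

test_that("an all-invalid baseline window excludes the replicate", {
  x <- rep(4, 3840)
  x[1:240] <- NaN  # the whole 2 s baseline
  r <- make_replicate(x)
  out <- normalize_replicate(r, screen_config())
  expect_equal(out$status, "excluded:baseline_all_invalid")
})

test_that("baseline z-screening excludes exactly the shifted replicate", {
  set.seed(12)
  reps <- lapply(1:20, function(i) {
    base <- 4 + rnorm(1, sd = 0.05)
    if (i == 7) base <- base + 1  # far beyond 2.5 SD of the others
    r <- make_replicate(base + tavnspipe:::rollmean_shrink(rnorm(3840, sd = 0.01), 12))
    screen_replicate(r)
  })
  out <- normalize_replicates(reps, screen_config())
  status <- vapply(out, `[[`, character(1), "status")
  expect_equal(which(status == "excluded:baseline_z"), 7L)
  expect_equal(sum(status == "kept"), 19)
})

test_that("finalization averages and downsamples 120 Hz to 10 Hz", {
  reps <- lapply(1:3, function(i) {
    r <- make_replicate(rep(5, 7200), baseline_s = 2)  # 60 s at 120 Hz
    normalize_replicate(r, screen_config())
  })
  tr <- finalize_subject(reps, screen_config())
  expect_s3_class(tr, "subject_trace")
  expect_length(tr$trace, 600)
  # identical replicates: the mean equals any single downsampled replicate
  single <- colMeans(matrix(reps[[1]]$samples, nrow = 12))
  expect_equal(tr$trace, single)
})

test_that("subjects below 10% retention are dropped for the condition", {
  reps <- lapply(1:20, function(i) {
    r <- make_replicate(rep(4, 1200))
    if (i > 1) r$status <- "excluded:mad_nan"
    r
  })
  reps[[1]] <- normalize_replicate(reps[[1]], screen_config())
  out <- finalize_subject(reps, screen_config())
  expect_s3_class(out, "subject_excluded")
  expect_equal(out$n_kept, 1)
  expect_s3_class(finalize_subject(list(), screen_config()), "subject_excluded")
})

test_that("exclusion bookkeeping reconciles against input totals", {
  cfg <- pupil_gen_config(duration = 320, stim_onsets = seq(30, by = 30, length.out = 5),
                          blink_rate = 6, seed = 13)
  rec <- gen_pupil_rest_recording(cfg)$recording
  res <- process_pupil_rest(rec, seq(30, by = 30, length.out = 5),
                            protocol_spec("3.4s"))
  qc <- res$qc
  expect_equal(nrow(qc), 10)  # 5 onsets x 2 eyes
  expect_true(all(qc$status == "kept" | grepl("^excluded:", qc$status)))
  # every excluded replicate carries a machine-readable reason, and the
  # kept + excluded counts add up
  expect_equal(sum(qc$status == "kept") + sum(grepl("^excluded:", qc$status)), 10)
  # interpolated samples only ever replace flagged ones
  kept <- Filter(function(r) r$status == "kept", res$replicates)
  for (r in kept) {
    expect_lte(sum(r$mask == "interpolated"),
               r$screen_log$mad_flagged + r$screen_log$blink_flagged +
                 r$screen_log$range_flagged + 1)
  }
})

test_that("the pipeline is idempotent on clean data up to smoothing edge effects", {
  x <- 4 + 0.2 * sin(2 * pi * (1:3840) / 3840)
  r <- screen_replicate(make_replicate(x))
  expect_equal(r$status, "kept")
  expect_true(all(r$mask == "valid"))
  out <- normalize_replicate(r, screen_config())
  core <- 200:3640
  expect_equal(out$samples[core] + out$baseline_mean, x[core], tolerance = 0.01)
})
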