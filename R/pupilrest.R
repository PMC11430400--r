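# Resting-pupil preprocessing: stimulation-locked replicates, speed-based
# MAD screening, blink detection, range filtering, interpolation, smoothing,
# baseline correction, subject-level retention control and 10 Hz
# downsampling — with a machine-readable reason for every exclusion.

#' Stimulation protocol specification
#'
#' Encodes the two stimulation protocols: short (3.4 s ON, 26.6 s
#' post-stimulation window) and long (30 s ON, 28 s post). Both use a 2 s
#' pre-stimulation baseline, 25 Hz pulse frequency and 250 us pulse width,
#' giving a duty cycle of 0.625% ON period.
#'
#' @param label `"3.4s"` or `"30s"`.
#' @return A list of class `protocol_spec` with fields `baseline_window`,
#'   `stim_duration`, `post_duration`, `pulse_frequency` (Hz), `pulse_width`
#'   (us), `duty_cycle_pct` (derived) and `replicate_length` (s).
#' @export
protocol_spec <- function(label = c("30s", "3.4s")) {
  label <- match.arg(label)
  stim <- if (label == "30s") 30 else 3.4
  post <- if (label == "30s") 28 else 26.6
  freq <- 25       # Hz
  width_us <- 250  # microseconds
  structure(list(
    label = label,
    baseline_window = 2,
    stim_duration = stim,
    post_duration = post,
    pulse_frequency = freq,
    pulse_width = width_us,
    duty_cycle_pct = freq * width_us * 1e-6 * 100,
    replicate_length = 2 + stim + post), class = "protocol_spec")
}

#' Screening configuration for the resting-pupil pipeline
#'
#' Houses every threshold of the replicate-screening stages: the MAD speed
#' criterion (scale 6, 2% NaN limit), the physiological diameter range
#' (1.5-9 mm), the 5% blink/range and 60% pre-stage invalidity limits, the
#' 100-sample smoothing window, the 2.5 SD baseline-z exclusion, the 10%
#' subject retention limit and the 10 Hz target rate, plus the blink
#' detector's confidence/velocity/padding settings.
#'
#' @param mad_scale Scale factor on the MAD of successive differences.
#' @param mad_nan_limit Maximum tolerated fraction of MAD-flagged samples.
#' @param range Physiological pupil range (mm).
#' @param post_blink_invalid_limit Maximum fraction removed by blink +
#'   range screening combined.
#' @param pre_blink_invalid_limit Invalid fraction before blink/range
#'   screening above which the replicate is excluded outright.
#' @param smooth_window Rolling-average window (samples).
#' @param baseline_z_limit Baseline z-score exclusion limit (SD).
#' @param retention_limit Minimum kept/initial replicate fraction per
#'   subject and condition.
#' @param target_rate Output rate (Hz).
#' @param conf_threshold Blink detector: confidence below this is a blink.
#' @param velocity_threshold Blink detector: absolute velocity bound (mm/s).
#' @param blink_pad Padding (s) added around detected blink runs.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(mad_scale = 6, mad_nan_limit = 0.02,
                          range = c(1.5, 9), post_blink_invalid_limit = 0.05,
                          pre_blink_invalid_limit = 0.60, smooth_window = 100,
                          baseline_z_limit = 2.5, retention_limit = 0.10,
                          target_rate = 10, conf_threshold = 0.6,
                          velocity_threshold = 8, blink_pad = 0.1) {
  stopifnot(smooth_window >= 1, mad_nan_limit > 0, mad_nan_limit < 1,
            length(range) == 2, range[1] < range[2],
            post_blink_invalid_limit > 0, pre_blink_invalid_limit > 0,
            baseline_z_limit > 0, retention_limit > 0, target_rate > 0)
  structure(as.list(environment()), class = "screen_config")
}

new_replicate <- function(eye, onset, time, samples, confidence, rate) {
  structure(list(
    eye = eye, onset = onset, time = time, samples = samples,
    confidence = confidence, rate = rate,
    mask = rep("valid", length(samples)),
    status = "kept", screen_log = list(),
    baseline_mean = NA_real_), class = "pupil_replicate")
}

#' @export
print.pupil_replicate <- function(x, ...) {
  cat(sprintf("<pupil_replicate> eye=%s onset=%.1fs n=%d status=%s\n",
              x$eye, x$onset, length(x$samples), x$status))
  invisible(x)
}

exclude_replicate <- function(r, rule) {
  # once excluded a replicate is never re-included
  if (r$status == "kept") r$status <- paste0("excluded:", rule)
  r
}

#' Cut a recording into stimulation-locked replicates
#'
#' One replicate per eye per stimulation onset, spanning 2 s of baseline,
#' the stimulation ON window and the post-stimulation window (60 s total
#' for the 30 s protocol, 32 s for the 3.4 s protocol). Onsets whose window
#' is truncated at the recording edges are dropped with a logged reason.
#'
#' @param recording A [pupil_recording()].
#' @param stim_onsets Stimulation onset times (s), sorted.
#' @param protocol A [protocol_spec()].
#' @return A list of `pupil_replicate` objects; dropped onsets are recorded
#'   in the `"dropped"` attribute (data.frame of onset, eye, reason).
#' @export
segment_replicates <- function(recording, stim_onsets, protocol) {
  stopifnot(inherits(recording, "pupil_recording"),
            inherits(protocol, "protocol_spec"))
  if (is.unsorted(stim_onsets)) stop("stim_onsets must be sorted")
  span <- protocol$replicate_length
  n_expect <- round(span * recording$rate)
  out <- list()
  dropped <- data.frame(onset = numeric(0), eye = character(0),
                        reason = character(0))
  for (eye in c("left", "right")) {
    d <- recording$eyes[[eye]]
    for (on in stim_onsets) {
      idx <- which(recording$time >= on - protocol$baseline_window &
                     recording$time < on + protocol$stim_duration +
                       protocol$post_duration)
      if (length(idx) < n_expect) {
        dropped <- rbind(dropped, data.frame(
          onset = on, eye = eye, reason = "window_truncated"))
        next
      }
      out[[length(out) + 1]] <- new_replicate(
        eye, on, recording$time[idx] - on,
        d$diameter[idx], d$confidence[idx], recording$rate)
    }
  }
  attr(out, "dropped") <- dropped
  out
}

#' Detect blinks from confidence and velocity
#'
#' Flags the union of (i) runs of tracker confidence below the threshold
#' and (ii) runs bounded by absolute sample-to-sample velocity above the
#' bound, pads every run on both sides, and merges overlapping intervals.
#'
#' @param samples Pupil diameter (mm).
#' @param confidence Per-sample confidence.
#' @param rate Sampling rate (Hz).
#' @param conf_threshold Confidence threshold (default 0.6).
#' @param velocity_threshold Absolute velocity bound in mm/s (default 8).
#' @param pad Padding in s added to each side (default 0.1).
#' @return A data.frame of intervals (`onset`, `offset`, in s with the
#'   first sample at 0).
#' @export
detect_blinks <- function(samples, confidence, rate, conf_threshold = 0.6,
                          velocity_threshold = 8, pad = 0.1) {
  stopifnot(rate > 0)
  n <- length(samples)
  if (n == 0) {
    return(data.frame(onset = numeric(0), offset = numeric(0)))
  }
  flag <- !is.na(confidence) & confidence < conf_threshold
  if (n > 1) {
    v <- c(0, diff(samples)) * rate
    vflag <- !is.na(v) & abs(v) > velocity_threshold
    flag <- flag | vflag
  }
  runs <- true_runs(flag)
  if (nrow(runs) == 0) {
    return(data.frame(onset = numeric(0), offset = numeric(0)))
  }
  iv <- cbind(pmax(0, (runs[, "start"] - 1) / rate - pad),
              pmin((n - 1) / rate, (runs[, "end"] - 1) / rate + pad))
  iv <- merge_intervals(iv)
  data.frame(onset = iv[, 1], offset = iv[, 2])
}

#' Screen a replicate: MAD speed criterion, blinks, range
#'
#' Applies, in order: (a) the MAD stage — absolute successive differences
#' are thresholded at their median plus `mad_scale` times their (unscaled)
#' MAD; flagged samples become NaN and the replicate is excluded if more
#' than `mad_nan_limit` of it is flagged; (b) outright exclusion if the
#' replicate is already at least `pre_blink_invalid_limit` invalid; (c)
#' blink detection; (d) the physiological range filter; (e) exclusion if
#' blink + range screening together removed more than
#' `post_blink_invalid_limit` of the replicate.
#'
#' @param r A `pupil_replicate` (not yet screened).
#' @param cfg A [screen_config()].
#' @param blink_detector Function with the signature of [detect_blinks()].
#' @return The replicate with updated `mask`, `samples` (invalid samples
#'   NaN), `status` and `screen_log` (flag counts per rule).
#' @export
screen_replicate <- function(r, cfg = screen_config(), blink_detector = detect_blinks) {
  stopifnot(inherits(r, "pupil_replicate"), inherits(cfg, "screen_config"))
  n <- length(r$samples)
  if (n < 3) {
    r <- exclude_replicate(r, "too_short")
    return(r)
  }
  x <- r$samples

  # (a) speed criterion on absolute successive differences
  d <- abs(diff(x))
  thr <- stats::median(d, na.rm = TRUE) +
    cfg$mad_scale * stats::mad(d, constant = 1, na.rm = TRUE)
  mad_idx <- which(d > thr) + 1L  # flag the arriving sample
  x[mad_idx] <- NaN
  r$mask[mad_idx] <- "mad_excluded"
  r$screen_log$mad_flagged <- length(mad_idx)
  r$screen_log$mad_threshold <- thr
  if (length(mad_idx) / n > cfg$mad_nan_limit) {
    r$samples <- x
    return(exclude_replicate(r, "mad_nan"))
  }

  # (b) already extensively invalid before blink/range screening
  invalid_before <- !is.finite(x)
  if (mean(invalid_before) >= cfg$pre_blink_invalid_limit) {
    r$samples <- x
    return(exclude_replicate(r, "invalid_before_blink"))
  }

  # (c) blink detection
  bl <- blink_detector(x, r$confidence, r$rate,
                       conf_threshold = cfg$conf_threshold,
                       velocity_threshold = cfg$velocity_threshold,
                       pad = cfg$blink_pad)
  t0 <- (seq_len(n) - 1) / r$rate
  blink_flag <- rep(FALSE, n)
  if (nrow(bl) > 0) {
    for (i in seq_len(nrow(bl))) {
      blink_flag <- blink_flag | (t0 >= bl$onset[i] & t0 <= bl$offset[i])
    }
  }
  new_blink <- blink_flag & !invalid_before
  r$mask[new_blink] <- "blink"
  x[new_blink] <- NaN

  # (d) physiological range filter
  range_flag <- is.finite(x) & (x < cfg$range[1] | x > cfg$range[2])
  r$mask[range_flag] <- "out_of_range"
  x[range_flag] <- NaN

  r$screen_log$blink_flagged <- sum(new_blink)
  r$screen_log$range_flagged <- sum(range_flag)
  removed_frac <- mean(new_blink | range_flag)
  r$screen_log$blink_range_fraction <- removed_frac
  r$samples <- x
  if (removed_frac > cfg$post_blink_invalid_limit) {
    return(exclude_replicate(r, "blink_range"))
  }
  r
}

#' Interpolate, smooth and baseline-correct a screened replicate
#'
#' Invalid samples are linearly interpolated (edge gaps held at the nearest
#' valid value) and marked `interpolated`; a centred rolling mean of
#' `smooth_window` samples (shrinking at the edges) is applied; the mean
#' over the \eqn{[-2, 0)} s baseline window is subtracted from every sample
#' so the corrected baseline mean is exactly zero. If subject-level
#' baseline statistics are supplied, the replicate's (pre-subtraction)
#' baseline mean is z-scored against them and the replicate is excluded
#' when |z| exceeds the configured limit.
#'
#' @param r A kept `pupil_replicate` after [screen_replicate()].
#' @param cfg A [screen_config()].
#' @param baseline_stats Optional list with `mean` and `sd` of the
#'   subject's distribution of replicate baseline means.
#' @return The normalized replicate; `baseline_mean` holds the
#'   pre-subtraction baseline mean used for the z-score stage.
#' @export
normalize_replicate <- function(r, cfg = screen_config(), baseline_stats = NULL) {
  stopifnot(inherits(r, "pupil_replicate"))
  if (r$status != "kept") return(r)
  x <- r$samples
  invalid <- !is.finite(x)
  base_idx <- r$time >= -2 & r$time < 0
  if (all(invalid[base_idx])) {
    return(exclude_replicate(r, "baseline_all_invalid"))
  }
  if (all(invalid)) return(exclude_replicate(r, "all_invalid"))
  if (any(invalid)) {
    x[invalid] <- NA
    x <- zoo::na.approx(x, na.rm = FALSE, rule = 2)
    r$mask[invalid] <- "interpolated"
  }
  x <- rollmean_shrink(x, cfg$smooth_window)
  bmean <- mean(x[base_idx])
  r$baseline_mean <- bmean
  x <- x - bmean
  r$samples <- x
  if (!is.null(baseline_stats)) {
    z <- if (baseline_stats$sd > 0) (bmean - baseline_stats$mean) / baseline_stats$sd else 0
    r$screen_log$baseline_z <- z
    if (abs(z) > cfg$baseline_z_limit) {
      return(exclude_replicate(r, "baseline_z"))
    }
  }
  r
}

#' Normalize a subject's replicates with baseline z-screening
#'
#' Runs [normalize_replicate()] over all kept replicates of one subject and
#' condition round, then z-scores every replicate's baseline mean against
#' the subject's own distribution of baseline means and excludes replicates
#' beyond the configured limit.
#'
#' @param replicates List of screened `pupil_replicate`s.
#' @param cfg A [screen_config()].
#' @return The list with normalized samples and updated statuses.
#' @export
normalize_replicates <- function(replicates, cfg = screen_config()) {
  replicates <- lapply(replicates, function(r) {
    if (r$status == "kept") normalize_replicate(r, cfg, baseline_stats = NULL) else r
  })
  bmeans <- vapply(replicates, function(r) {
    if (r$status == "kept") r$baseline_mean else NA_real_
  }, numeric(1))
  if (sum(!is.na(bmeans)) >= 2) {
    stats_b <- list(mean = mean(bmeans, na.rm = TRUE),
                    sd = stats::sd(bmeans, na.rm = TRUE))
    replicates <- lapply(replicates, function(r) {
      if (r$status != "kept") return(r)
      z <- if (stats_b$sd > 0) (r$baseline_mean - stats_b$mean) / stats_b$sd else 0
      r$screen_log$baseline_z <- z
      if (abs(z) > cfg$baseline_z_limit) exclude_replicate(r, "baseline_z") else r
    })
  }
  replicates
}

#' Average a subject's kept replicates and downsample to the target rate
#'
#' If fewer than `retention_limit` of the initial replicates survived, the
#' subject is excluded for that condition. Otherwise the kept replicates
#' are averaged pointwise and block-averaged down to the target rate
#' (12:1 for a 120 Hz source and 10 Hz target).
#'
#' @param replicates List of normalized `pupil_replicate`s (kept and
#'   excluded; statuses are used for the retention check).
#' @param cfg A [screen_config()].
#' @param n_initial Number of replicates before any exclusion; defaults to
#'   `length(replicates)`.
#' @return A list of class `subject_trace` with `time` (s, relative to
#'   stimulation onset), `trace` (mm, baseline-corrected, at
#'   `cfg$target_rate`), `n_kept`, `n_initial`; or class
#'   `subject_excluded` with the reason.
#' @export
finalize_subject <- function(replicates, cfg = screen_config(),
                             n_initial = length(replicates)) {
  kept <- Filter(function(r) r$status == "kept", replicates)
  if (n_initial == 0 || length(kept) == 0 ||
      length(kept) / n_initial < cfg$retention_limit) {
    return(structure(list(n_kept = length(kept), n_initial = n_initial,
                          reason = "retention_below_limit"),
                     class = "subject_excluded"))
  }
  mat <- do.call(rbind, lapply(kept, `[[`, "samples"))
  avg <- colMeans(mat)
  rate <- kept[[1]]$rate
  factor <- round(rate / cfg$target_rate)
  n_blocks <- floor(length(avg) / factor)
  avg <- avg[seq_len(n_blocks * factor)]
  trace <- colMeans(matrix(avg, nrow = factor))
  t0 <- kept[[1]]$time[1]
  time <- t0 + (seq_len(n_blocks) - 0.5) * factor / rate
  structure(list(time = time, trace = trace,
                 n_kept = length(kept), n_initial = n_initial),
            class = "subject_trace")
}

#' Per-replicate QC table
#'
#' One row per replicate with its eye, onset, final status and per-rule
#' flag counts, so exclusion counts reconcile against input totals.
#'
#' @param replicates List of `pupil_replicate`s.
#' @return A data.frame.
#' @export
replicate_qc_table <- function(replicates) {
  cnt <- function(r, f) if (is.null(r$screen_log[[f]])) 0L else r$screen_log[[f]]
  do.call(rbind, lapply(replicates, function(r) {
    data.frame(
      eye = r$eye, onset = r$onset, status = r$status,
      n_samples = length(r$samples),
      n_mad = cnt(r, "mad_flagged"),
      n_blink = cnt(r, "blink_flagged"),
      n_range = cnt(r, "range_flagged"),
      n_interpolated = sum(r$mask == "interpolated"),
      baseline_mean = r$baseline_mean)
  }))
}

#' Run the full resting-pupil pipeline for one subject and condition
#'
#' Segments, screens, normalizes and finalizes; returns per-eye traces at
#' the target rate together with the QC table.
#'
#' @param recording A [pupil_recording()].
#' @param stim_onsets Stimulation onsets (s).
#' @param protocol A [protocol_spec()].
#' @param cfg A [screen_config()].
#' @return List with `traces` (per eye: `subject_trace` or
#'   `subject_excluded`), `qc` (data.frame), `replicates`.
#' @export
process_pupil_rest <- function(recording, stim_onsets, protocol,
                               cfg = screen_config()) {
  reps <- segment_replicates(recording, stim_onsets, protocol)
  reps <- lapply(reps, screen_replicate, cfg = cfg)
  traces <- list()
  out_reps <- list()
  for (eye in c("left", "right")) {
    eye_reps <- Filter(function(r) r$eye == eye, reps)
    eye_reps <- normalize_replicates(eye_reps, cfg)
    traces[[eye]] <- finalize_subject(eye_reps, cfg,
                                      n_initial = length(eye_reps))
    out_reps <- c(out_reps, eye_reps)
  }
  list(traces = traces, qc = replicate_qc_table(out_reps), replicates = out_reps)
}
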