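# Pupillary light reflex: blink removal, zero-phase low-pass filtering,
# epoching around flashes, automated quality control, and extraction of the
# 12 light-reflex parameters (D1, D2, AMP, Rel_AMP, T1, T2, T3, VCmax,
# ACmax, Redil_25/50/75).

#' Preprocess a recording for light-reflex analysis
#'
#' Blinks are detected (confidence + velocity criteria), removed and
#' linearly interpolated; a zero-phase third-order low-pass Butterworth
#' filter with a 4 Hz cut-off smooths the trace; the result is cut into
#' epochs spanning 1 s before to 9 s after each flash.
#'
#' @param recording A [pupil_recording()].
#' @param flash_times Flash onsets (s), spaced at least 10 s apart.
#' @param intensity Flash intensity index per flash (default cycles 1..4,
#'   four increasing flash sizes repeated across the session).
#' @param lowpass Filter cut-off (Hz); `NULL` skips the smoothing filter.
#' @param order Butterworth filter order.
#' @param cfg A [screen_config()] supplying the blink-detector settings.
#' @return List of `plr_epoch` objects (fields `eye`, `flash_time`,
#'   `intensity`, `time` in s relative to onset, `samples`, `rate`,
#'   `qc_status`); epochs extending past the recording are dropped and
#'   listed in the `"dropped"` attribute.
#' @export
preprocess_plr <- function(recording, flash_times,
                           intensity = rep(1:4, length.out = length(flash_times)),
                           lowpass = 4, order = 3, cfg = screen_config()) {
  stopifnot(inherits(recording, "pupil_recording"))
  if (length(flash_times) > 1 && any(diff(flash_times) < 10)) {
    stop("flash_times must be spaced at least 10 s apart")
  }
  rate <- recording$rate
  bf <- if (!is.null(lowpass)) {
    signal::butter(order, lowpass / (rate / 2), type = "low")
  } else NULL
  n_expect <- round(10 * rate)
  epochs <- list()
  dropped <- data.frame(flash_time = numeric(0), eye = character(0))
  for (eye in c("left", "right")) {
    d <- recording$eyes[[eye]]
    x <- d$diameter
    bl <- detect_blinks(x, d$confidence, rate,
                        conf_threshold = cfg$conf_threshold,
                        velocity_threshold = cfg$velocity_threshold,
                        pad = cfg$blink_pad)
    t_rel <- recording$time - recording$time[1]
    if (nrow(bl) > 0) {
      for (i in seq_len(nrow(bl))) {
        x[t_rel >= bl$onset[i] & t_rel <= bl$offset[i]] <- NA
      }
    }
    x[!is.finite(x)] <- NA
    if (anyNA(x)) x <- zoo::na.approx(x, na.rm = FALSE, rule = 2)
    if (!is.null(bf)) x <- as.numeric(signal::filtfilt(bf, x))
    for (i in seq_along(flash_times)) {
      idx <- which(recording$time >= flash_times[i] - 1 &
                     recording$time < flash_times[i] + 9)
      if (length(idx) < n_expect) {
        dropped <- rbind(dropped,
                         data.frame(flash_time = flash_times[i], eye = eye))
        next
      }
      epochs[[length(epochs) + 1]] <- structure(
        list(eye = eye, flash_time = flash_times[i],
             intensity = intensity[i],
             time = recording$time[idx] - flash_times[i],
             samples = x[idx], rate = rate, qc_status = NULL),
        class = "plr_epoch")
    }
  }
  attr(epochs, "dropped") <- dropped
  epochs
}

#' Automated quality control of a light-reflex epoch
#'
#' Automated surrogates for the visual inspection criteria: a stable
#' baseline (baseline SD below `baseline_sd_limit`), a rapid constriction
#' (minimum within `min_within` s of the flash and amplitude above
#' `min_amp`), re-dilation (positive mean post-minimum slope), and no
#' non-physiological fluctuations (no absolute sample-to-sample step above
#' `max_step` after filtering). The first violated criterion is reported.
#'
#' @param epoch A `plr_epoch`.
#' @param baseline_sd_limit mm (default 0.25).
#' @param min_within s (default 3).
#' @param min_amp mm (default 0.3).
#' @param max_step mm (default 1).
#' @return `"pass"` or `"fail:<criterion>"`.
#' @export
qc_plr <- function(epoch, baseline_sd_limit = 0.25, min_within = 3,
                   min_amp = 0.3, max_step = 1) {
  stopifnot(inherits(epoch, "plr_epoch"))
  x <- epoch$samples
  t <- epoch$time
  base <- x[t < 0]
  if (stats::sd(base) >= baseline_sd_limit) return("fail:stable_baseline")
  post <- t > 0
  d1 <- mean(base)
  i_min <- which.min(ifelse(post, x, Inf))
  amp <- d1 - x[i_min]
  if (t[i_min] > min_within || amp <= min_amp) return("fail:rapid_constriction")
  after <- t > t[i_min]
  if (sum(after) >= 2) {
    slope <- stats::coef(stats::lm.fit(cbind(1, t[after]), x[after]))[2]
    if (slope <= 0) return("fail:redilation")
  }
  if (max(abs(diff(x))) > max_step) return("fail:fluctuation")
  "pass"
}

#' Extract the 12 light-reflex parameters from an epoch
#'
#' Definitions: `D1` is the mean diameter over the 1 s baseline; `D2` the
#' post-flash minimum; `AMP = D1 - D2`; `Rel_AMP = AMP / D1`; `T1` the
#' constriction-onset latency (first post-flash time where velocity drops
#' below minus three baseline velocity SDs, sustained for 50 ms); `T2` the
#' time of the minimum; `T3 = T2 - T1` the constriction duration; `VCmax`
#' and `ACmax` the peak absolute velocity and acceleration within
#' `(T1, T2)` from central finite differences; `Redil_q` the time from the
#' minimum until recovery of q% of the amplitude (missing if not reached
#' within the epoch).
#'
#' @param epoch A `plr_epoch` that passed QC.
#' @return A one-row data.frame with the 12 parameters plus `eye`,
#'   `intensity` and `flash_time`.
#' @export
extract_plr_parameters <- function(epoch) {
  stopifnot(inherits(epoch, "plr_epoch"))
  x <- epoch$samples
  t <- epoch$time
  dt <- 1 / epoch$rate
  n <- length(x)
  base_idx <- t < 0
  d1 <- mean(x[base_idx])
  post <- t > 0
  i_min <- which.min(ifelse(post, x, Inf))
  d2 <- x[i_min]
  t2 <- t[i_min]
  amp <- d1 - d2

  # central finite differences (endpoints one-sided)
  v <- c(NA, (x[3:n] - x[1:(n - 2)]) / (2 * dt), NA)
  a <- c(NA, (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) / dt^2, NA)

  # onset threshold: minus three baseline velocity SDs, floored at 2% of
  # the peak constriction speed so near-noiseless baselines (where the SD
  # collapses toward zero) cannot trigger on numerical ripple
  v_base_sd <- stats::sd(v[base_idx], na.rm = TRUE)
  v_peak <- max(abs(v[post & t < t2]), 0, na.rm = TRUE)
  vthr <- -max(3 * v_base_sd, 0.02 * v_peak, 1e-9)
  sustain <- max(1L, ceiling(0.05 * epoch$rate))
  below <- !is.na(v) & v < vthr & post & t < t2
  t1 <- NA_real_
  runs <- true_runs(below)
  if (nrow(runs) > 0) {
    long_enough <- runs[, "end"] - runs[, "start"] + 1L >= sustain
    if (any(long_enough)) t1 <- t[runs[which(long_enough)[1], "start"]]
  }
  t3 <- if (!is.na(t1)) t2 - t1 else NA_real_

  win <- !is.na(t1) & t > t1 & t < t2
  vcmax <- if (any(win, na.rm = TRUE)) max(abs(v[win]), na.rm = TRUE) else NA_real_
  acmax <- if (any(win, na.rm = TRUE)) max(abs(a[win]), na.rm = TRUE) else NA_real_

  redil_time <- function(q) {
    target <- d2 + q * amp
    after <- which(t > t2 & x >= target)
    if (length(after) == 0) return(NA_real_)
    t[after[1]] - t2
  }

  data.frame(eye = epoch$eye, intensity = epoch$intensity,
             flash_time = epoch$flash_time,
             D1 = d1, D2 = d2, AMP = amp, Rel_AMP = amp / d1,
             T1 = t1, T2 = t2, T3 = t3, VCmax = vcmax, ACmax = acmax,
             Redil_25 = redil_time(0.25), Redil_50 = redil_time(0.50),
             Redil_75 = redil_time(0.75))
}

#' Aggregate light-reflex parameters with 3 SD outlier screening
#'
#' Within each aggregation cell and parameter, values more than 3 standard
#' deviations from the cell mean are removed (one pass), then cell means
#' are computed. Removal counts are logged in the `"removed"` attribute.
#'
#' @param params Long data.frame with columns `parameter`, `value` and the
#'   grouping columns in `by`.
#' @param by Character vector of grouping columns (e.g. subject, condition,
#'   eye, intensity).
#' @param sd_limit Outlier limit in within-cell SDs (default 3).
#' @return A data.frame of cell means with an `n` column; cells empty after
#'   removal yield `NA` values.
#' @export
aggregate_plr <- function(params, by = c("eye", "intensity"), sd_limit = 3) {
  stopifnot(all(c(by, "parameter", "value") %in% names(params)))
  key <- interaction(params[c(by, "parameter")], drop = TRUE)
  removed <- 0L
  out <- lapply(split(params, key), function(cell) {
    v <- cell$value
    keep <- rep(TRUE, length(v))
    ok <- !is.na(v)
    if (sum(ok) >= 2) {
      m <- mean(v[ok]); s <- stats::sd(v[ok])
      if (s > 0) keep <- is.na(v) | abs(v - m) <= sd_limit * s
    }
    removed <<- removed + sum(!keep)
    res <- cell[1, c(by, "parameter"), drop = FALSE]
    vv <- v[keep & !is.na(v)]
    res$value <- if (length(vv)) mean(vv) else NA_real_
    res$n <- length(vv)
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}
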