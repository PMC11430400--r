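# Synthetic-data generators. Every downstream stage of the pipeline is
# exercisable against these with known ground truth, since raw study
# recordings of this kind are typically not publicly archived.

#' Configuration for the resting-pupil generator
#'
#' @param sampling_rate Samples per second (Hz).
#' @param duration Recording length (s).
#' @param baseline_diameter Baseline pupil diameter (mm); length 1 (both
#'   eyes) or 2 (left, right).
#' @param noise_sd Gaussian measurement noise SD (mm).
#' @param blink_rate Blink events per minute (Poisson-scheduled unless
#'   `blink_times` is given).
#' @param blink_duration Blink length (ms).
#' @param blink_times Optional explicit blink onset times (s); overrides
#'   `blink_rate` scheduling.
#' @param stim_onsets Stimulation ON times (s).
#' @param stim_response_amplitude Peak amplitude (mm) of the
#'   stimulation-locked dilation transient.
#' @param stim_response_latency Delay (s) from stimulation onset to the
#'   start of the transient.
#' @param stim_response_scale Time-to-peak (s) of the gamma-shaped transient.
#' @param drift_amplitude Amplitude (mm) of a slow sinusoidal drift.
#' @param seed Integer seed.
#' @return A list of class `pupil_gen_config`.
#' @export
pupil_gen_config <- function(sampling_rate = 120, duration = 60,
                             baseline_diameter = 4.5, noise_sd = 0.02,
                             blink_rate = 10, blink_duration = 150,
                             blink_times = NULL,
                             stim_onsets = numeric(0),
                             stim_response_amplitude = 0.1,
                             stim_response_latency = 0.5,
                             stim_response_scale = 1.5,
                             drift_amplitude = 0, seed = 1L) {
  stopifnot(sampling_rate > 0, blink_duration > 0,
            stim_response_amplitude >= 0, drift_amplitude >= 0,
            noise_sd >= 0, blink_rate >= 0)
  if (duration <= 0) stop("duration must be positive")
  if (length(baseline_diameter) == 1) baseline_diameter <- rep(baseline_diameter, 2)
  structure(as.list(environment()), class = "pupil_gen_config")
}

# Gamma-shaped (shape 2) unimodal transient, unit peak at t = scale.
gamma_bump <- function(t, scale) {
  ifelse(t <= 0, 0, (t / scale) * exp(1 - t / scale))
}

#' Generate a resting-pupil recording with ground truth
#'
#' Produces a two-eye trace at the configured rate with optional blinks
#' (linear collapse below 1.5 mm with confidence 0), a smooth gamma-shaped
#' stimulation-locked dilation transient at each stimulation onset, slow
#' drift and Gaussian noise. The blink schedule is returned alongside as
#' ground truth.
#'
#' @param cfg A [pupil_gen_config()].
#' @return A list with elements `recording` (a [pupil_recording()]) and
#'   `blinks` (data.frame of ground-truth blink `onset`/`offset` in s).
#' @export
gen_pupil_rest_recording <- function(cfg) {
  stopifnot(inherits(cfg, "pupil_gen_config"))
  with_seed(cfg$seed, {
    n <- floor(cfg$duration * cfg$sampling_rate)
    t <- (seq_len(n) - 1) / cfg$sampling_rate
    blink_dur_s <- cfg$blink_duration / 1000

    if (!is.null(cfg$blink_times)) {
      onsets <- cfg$blink_times
    } else if (cfg$blink_rate > 0) {
      n_blinks <- stats::rpois(1, cfg$blink_rate * cfg$duration / 60)
      onsets <- sort(stats::runif(n_blinks, 0, max(0, cfg$duration - blink_dur_s)))
    } else {
      onsets <- numeric(0)
    }
    blinks <- data.frame(onset = onsets, offset = onsets + blink_dur_s)

    stim_signal <- numeric(n)
    for (on in cfg$stim_onsets) {
      stim_signal <- stim_signal + cfg$stim_response_amplitude *
        gamma_bump(t - on - cfg$stim_response_latency, cfg$stim_response_scale)
    }
    drift <- if (cfg$drift_amplitude > 0) {
      cfg$drift_amplitude * sin(2 * pi * t / max(cfg$duration / 3, 30))
    } else 0

    # measurement noise is temporally smoothed (~100 ms moving average,
    # rescaled to noise_sd): pupil traces are slow signals and tracker
    # noise is correlated across neighboring samples, so white noise would
    # produce non-physiological sample-to-sample velocities
    smooth_noise <- function() {
      if (cfg$noise_sd == 0) return(numeric(n))
      w <- max(1, round(cfg$sampling_rate / 10))
      z <- rollmean_shrink(stats::rnorm(n), w)
      z * cfg$noise_sd / stats::sd(z)
    }
    make_eye <- function(base) {
      d <- base + stim_signal + drift + smooth_noise()
      conf <- rep(1, n)
      if (nrow(blinks) > 0) {
        for (i in seq_len(nrow(blinks))) {
          idx <- which(t >= blinks$onset[i] & t <= blinks$offset[i])
          if (length(idx) == 0) next
          # V-shaped linear collapse to well below the 1.5 mm physiological
          # floor so both the range filter and the blink detector trigger
          mid <- (blinks$onset[i] + blinks$offset[i]) / 2
          half <- blink_dur_s / 2
          depth <- 1 - pmin(1, abs(t[idx] - mid) / half)
          d[idx] <- d[idx] - (base - 0.3) * depth
          conf[idx] <- 0
        }
      }
      list(diameter = d, confidence = conf)
    }
    le <- make_eye(cfg$baseline_diameter[1])
    re <- make_eye(cfg$baseline_diameter[2])
    rec <- pupil_recording(t, le$diameter, re$diameter,
                           le$confidence, re$confidence,
                           rate = cfg$sampling_rate)
    list(recording = rec, blinks = blinks)
  })
}

#' Parametric light-reflex generator model
#'
#' Piecewise model of one pupillary light reflex: flat baseline at `d1`
#' until `t_latency` after the flash, smooth (raised-cosine) constriction to
#' the minimum `d2` at `t_min`, then exponential redilation back toward `d1`
#' with time constant `redil_tau`.
#'
#' @param d1 Baseline diameter (mm).
#' @param d2 Minimum diameter (mm), `d2 < d1`.
#' @param t_latency Constriction-onset latency after the flash (s).
#' @param t_min Time of the minimum after the flash (s), `> t_latency`.
#' @param redil_tau Exponential recovery time constant (s).
#' @param noise_sd Gaussian noise SD (mm).
#' @return A list of class `plr_gen_model`.
#' @export
plr_gen_model <- function(d1 = 6.5, d2 = 4.0, t_latency = 0.25,
                          t_min = 1.1, redil_tau = 2.0, noise_sd = 0.01) {
  stopifnot(d2 < d1, t_latency > 0, t_latency < t_min, redil_tau > 0, noise_sd >= 0)
  structure(list(d1 = d1, d2 = d2, t_latency = t_latency, t_min = t_min,
                 redil_tau = redil_tau, noise_sd = noise_sd),
            class = "plr_gen_model")
}

# Continuous noiseless trajectory of one reflex at time s after its flash.
plr_model_eval <- function(model, s) {
  amp <- model$d1 - model$d2
  t3 <- model$t_min - model$t_latency
  out <- rep(model$d1, length(s))
  con <- s >= model$t_latency & s < model$t_min
  out[con] <- model$d1 - amp / 2 * (1 - cos(pi * (s[con] - model$t_latency) / t3))
  red <- s >= model$t_min
  out[red] <- model$d1 - amp * exp(-(s[red] - model$t_min) / model$redil_tau)
  out
}

# Closed-form light-reflex parameters of the continuous noiseless model,
# using the same definitions the extraction stage applies to sampled traces.
plr_model_truth <- function(model) {
  amp <- model$d1 - model$d2
  t3 <- model$t_min - model$t_latency
  data.frame(
    D1 = model$d1, D2 = model$d2, AMP = amp, Rel_AMP = amp / model$d1,
    T1 = model$t_latency, T2 = model$t_min, T3 = t3,
    VCmax = amp * pi / (2 * t3),
    ACmax = amp * pi^2 / (2 * t3^2),
    Redil_25 = model$redil_tau * log(4 / 3),
    Redil_50 = model$redil_tau * log(2),
    Redil_75 = model$redil_tau * log(4))
}

#' Generate a pupillary-light-reflex recording with ground truth
#'
#' Each flash produces one reflex drawn from the corresponding generator
#' model (models are recycled across flashes). Analytic parameter values of
#' the noiseless continuous model are returned per flash as ground truth.
#'
#' @param models A `plr_gen_model` or list of them, recycled over flashes.
#' @param flash_times Flash onset times (s), strictly increasing and spaced
#'   more than 10 s apart (one epoch length).
#' @param rate Sampling rate (Hz).
#' @param pre Seconds of flat baseline recorded before the first flash.
#' @param seed Integer seed.
#' @return List with `recording` (a [pupil_recording()]), `truth`
#'   (data.frame of per-flash analytic parameters) and `flash_times`.
#' @export
gen_plr_recording <- function(models, flash_times, rate = 120, pre = 2, seed = 1L) {
  if (inherits(models, "plr_gen_model")) models <- list(models)
  stopifnot(length(flash_times) >= 1, all(diff(flash_times) > 0))
  if (length(flash_times) > 1 && any(diff(flash_times) <= 10)) {
    stop("flash_times must be spaced more than 10 s apart (epoch length)")
  }
  models <- rep(models, length.out = length(flash_times))
  with_seed(seed, {
    t_end <- max(flash_times) + 10
    n <- floor((t_end + pre) * rate)
    t <- (seq_len(n) - 1) / rate - pre
    d <- rep(models[[1]]$d1, n)
    for (i in seq_along(flash_times)) {
      upper <- if (i < length(flash_times)) flash_times[i + 1] else Inf
      idx <- which(t >= flash_times[i] & t < upper)
      d[idx] <- plr_model_eval(models[[i]], t[idx] - flash_times[i])
    }
    truth <- do.call(rbind, lapply(models, plr_model_truth))
    truth$flash_time <- flash_times
    # smoothed measurement noise (see gen_pupil_rest_recording)
    noise_sd <- vapply(models, `[[`, numeric(1), "noise_sd")[1]
    smooth_noise <- function() {
      if (noise_sd == 0) return(numeric(n))
      w <- max(1, round(rate / 10))
      z <- rollmean_shrink(stats::rnorm(n), w)
      z * noise_sd / stats::sd(z)
    }
    le <- d + smooth_noise()
    re <- d + smooth_noise()
    rec <- pupil_recording(t, le, re, rate = rate)
    list(recording = rec, truth = truth, flash_times = flash_times)
  })
}

#' Generate band-power epoch arrays with an optional injected effect
#'
#' Independent unit-variance Gaussian noise per subject/channel/time cell;
#' a standardized mean shift of `effect_size` is added inside the effect
#' window. Used as null or effect input for cluster-based permutation
#' inference.
#'
#' @param n_subjects,n_channels,n_times Array dimensions (`n_subjects >= 3`).
#' @param effect_window `NULL`, or a list with integer vectors `channels`
#'   and `times` defining the shifted cells.
#' @param effect_size Standardized mean shift added inside the window.
#' @param seed Integer seed.
#' @return List with `data` (subjects x channels x times array) and `truth`
#'   (logical channels x times mask of shifted cells).
#' @export
gen_eeg_epochs <- function(n_subjects, n_channels, n_times,
                           effect_window = NULL, effect_size = 0, seed = 1L) {
  stopifnot(n_subjects >= 3, n_channels >= 1, n_times >= 1)
  mask <- matrix(FALSE, n_channels, n_times)
  if (!is.null(effect_window)) {
    mask[effect_window$channels, effect_window$times] <- TRUE
  }
  if (effect_size != 0 && !any(mask)) {
    stop("nonzero effect_size requires a non-empty effect_window")
  }
  with_seed(seed, {
    x <- array(stats::rnorm(n_subjects * n_channels * n_times),
               dim = c(n_subjects, n_channels, n_times))
    if (any(mask)) {
      shift <- array(rep(effect_size * mask, each = n_subjects),
                     dim = dim(x))
      x <- x + shift
    }
    list(data = x, truth = mask)
  })
}

#' Generate Go/No-Go trials with 1-back identity structure
#'
#' Builds blocks with the stated Go fraction (Go identities drawn from 4
#' types, No-Go from 2), determines the 1-back correct response (left if the
#' stimulus repeats the previous one, right otherwise; the first trial of a
#' block has no 1-back and any response is correct), and simulates an
#' agent's responses with the stated error and ex-Gaussian RT parameters.
#'
#' @param n_blocks,trials_per_block,go_fraction Session structure.
#' @param go_omission_rate P(no response) on a Go trial.
#' @param go_error_rate P(wrong hand) on an answered Go trial.
#' @param nogo_commission_rate P(response) on a No-Go trial.
#' @param rt_mu,rt_sigma,rt_tau Ex-Gaussian RT parameters (ms).
#' @param deadline Response deadline (ms); slower finishing times become
#'   omissions.
#' @param seed Integer seed.
#' @return A data.frame trial table (`task = "GNG"`).
#' @export
gen_gng_trials <- function(n_blocks = 3, trials_per_block = 92, go_fraction = 2 / 3,
                           go_omission_rate = 0.02, go_error_rate = 0.05,
                           nogo_commission_rate = 0.15,
                           rt_mu = 420, rt_sigma = 60, rt_tau = 80,
                           deadline = 1250, seed = 1L) {
  stopifnot(go_fraction > 0, go_fraction < 1, n_blocks >= 1, trials_per_block >= 2)
  # distribute Go counts so the session total matches the fraction exactly
  go_per_block <- diff(c(0, round(seq_len(n_blocks) * trials_per_block * go_fraction)))
  with_seed(seed, {
    rows <- lapply(seq_len(n_blocks), function(b) {
      n_go <- go_per_block[b]
      is_go <- sample(rep(c(TRUE, FALSE), c(n_go, trials_per_block - n_go)))
      stim <- ifelse(is_go,
                     paste0("go", sample(1:4, trials_per_block, replace = TRUE)),
                     paste0("nogo", sample(1:2, trials_per_block, replace = TRUE)))
      prev <- c(NA, stim[-trials_per_block])
      correct_response <- ifelse(is_go,
                                 ifelse(is.na(prev), "either",
                                        ifelse(stim == prev, "left", "right")),
                                 "none")
      ft <- rexgauss(trials_per_block, rt_mu, rt_sigma, rt_tau)
      response <- character(trials_per_block)
      rt <- rep(NA_real_, trials_per_block)
      for (i in seq_len(trials_per_block)) {
        if (is_go[i]) {
          if (stats::runif(1) < go_omission_rate || ft[i] > deadline) {
            response[i] <- "none"
          } else {
            intended <- if (correct_response[i] == "either") {
              sample(c("left", "right"), 1)
            } else correct_response[i]
            wrong <- stats::runif(1) < go_error_rate
            response[i] <- if (!wrong) intended else setdiff(c("left", "right"), intended)
            rt[i] <- ft[i]
          }
        } else {
          if (stats::runif(1) < nogo_commission_rate && ft[i] <= deadline) {
            response[i] <- sample(c("left", "right"), 1)
            rt[i] <- ft[i]
          } else {
            response[i] <- "none"
          }
        }
      }
      data.frame(block = b, trial = seq_len(trials_per_block), task = "GNG",
                 stimulus = stim, is_go = is_go,
                 correct_response = correct_response,
                 response = response, rt_ms = rt)
    })
    out <- do.call(rbind, rows)
    out$trial_index <- seq_len(nrow(out))
    out
  })
}

#' Generate a synthetic saliva sample table
#'
#' One row per subject x protocol (3.4 s / 30 s) x arm (real / sham) x phase
#' (baseline / stimulation): log-normal concentration around a condition
#' mean with optional circadian drift over the day, `condition_effect`
#' added to real-stimulation cells, Salivette sample weight over a 2-minute
#' collection, and a clock time. Mirrors the usual
#' 4-baselines-plus-4-stimulations layout of a two-protocol sham-controlled
#' crossover.
#'
#' @param n_subjects Number of subjects (`>= 2`).
#' @param condition_effect Concentration shift (U/mL) added to real
#'   stimulation cells.
#' @param base_mean Baseline geometric-mean concentration (U/mL).
#' @param circadian_slope Fractional concentration increase per hour of the
#'   day (applied relative to 07:30).
#' @param noise Log-scale SD of the concentration.
#' @param seed Integer seed.
#' @return A data.frame with columns `subject`, `protocol`, `arm`, `phase`,
#'   `concentration`, `sample_weight_g`, `collection_duration_min`,
#'   `clock_time` (decimal hours).
#' @export
gen_saliva_table <- function(n_subjects, condition_effect = 0, base_mean = 75,
                             circadian_slope = 0.03, noise = 0.4, seed = 1L) {
  stopifnot(n_subjects >= 2, base_mean > 0, circadian_slope >= 0, noise >= 0)
  with_seed(seed, {
    grid <- expand.grid(subject = seq_len(n_subjects),
                        protocol = c("3.4s", "30s"),
                        arm = c("real", "sham"),
                        phase = c("baseline", "stim"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[order(grid$subject, grid$protocol, grid$arm, grid$phase), ]
    # each protocol x arm session happens at one time of day; baseline and
    # stimulation samples of a session are ~20 min apart
    key <- paste(grid$subject, grid$protocol, grid$arm)
    session_start <- stats::runif(length(unique(key)), 7.5, 16.0)
    names(session_start) <- unique(key)
    grid$clock_time <- session_start[key] + ifelse(grid$phase == "stim", 1 / 3, 0)
    subj_level <- stats::rnorm(n_subjects, sd = noise / 2)
    conc <- base_mean * exp(stats::rnorm(nrow(grid), sd = noise) +
                            subj_level[grid$subject]) *
      (1 + circadian_slope * (grid$clock_time - 7.5))
    conc <- conc + ifelse(grid$arm == "real" & grid$phase == "stim",
                          condition_effect, 0)
    grid$concentration <- conc
    grid$sample_weight_g <- pmax(0.2, stats::rnorm(nrow(grid), 1.0, 0.15))
    grid$collection_duration_min <- 2
    rownames(grid) <- NULL
    grid
  })
}

#' Generate synthetic event-related-potential epochs
#'
#' Each epoch is zero-mean Gaussian noise per channel with a Gaussian
#' positive component of amplitude `peak_amp` centred at `peak_time` added
#' to the listed component channels — a minimal stand-in for No-Go-locked
#' epochs carrying a P300.
#'
#' @param n_epochs Number of epochs.
#' @param labels Channel labels (must include the measurement channel of
#'   interest, e.g. "Pz").
#' @param rate Sampling rate (Hz).
#' @param tmin,tmax Epoch window (s) relative to stimulus onset.
#' @param peak_amp Component amplitude (uV).
#' @param peak_time Component latency (s).
#' @param peak_width Component Gaussian SD (s).
#' @param component_channels Channels carrying the component.
#' @param noise_sd Per-sample noise SD (uV).
#' @param seed Integer seed.
#' @return List with `epochs` (n_epochs x channels x times array), `times`
#'   (s) and `labels`.
#' @export
gen_erp_epochs <- function(n_epochs = 40, labels = c("Cz", "Pz", "Oz"),
                           rate = 250, tmin = -0.2, tmax = 1.5,
                           peak_amp = 10, peak_time = 0.5, peak_width = 0.08,
                           component_channels = "Pz", noise_sd = 5, seed = 1L) {
  stopifnot(n_epochs >= 1, rate > 0, tmax > tmin)
  with_seed(seed, {
    times <- seq(tmin, tmax, by = 1 / rate)
    n_t <- length(times)
    n_ch <- length(labels)
    comp <- peak_amp * exp(-(times - peak_time)^2 / (2 * peak_width^2))
    x <- array(stats::rnorm(n_epochs * n_ch * n_t, sd = noise_sd),
               dim = c(n_epochs, n_ch, n_t))
    for (ch in match(component_channels, labels)) {
      x[, ch, ] <- x[, ch, , drop = FALSE] + rep(comp, each = n_epochs)
    }
    list(epochs = x, times = times, labels = labels)
  })
}
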