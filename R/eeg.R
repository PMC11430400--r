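# EEG: preprocessing (average reference, 0.1-50 Hz band-pass, resampling
# to 1 kHz, 25 Hz notch, spherical-spline bad-channel interpolation),
# Morlet-wavelet band power for alpha/theta with pre-stimulus baseline
# correction, and P300 peak extraction at Pz.

#' Multichannel EEG recording container
#'
#' @param data Numeric matrix `channels x time` (uV).
#' @param rate Sampling rate (Hz).
#' @param labels Channel labels (standard 10-20 names).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, rate, labels = rownames(data)) {
  stopifnot(is.matrix(data), rate > 0)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  stopifnot(length(labels) == nrow(data))
  structure(list(data = data, rate = rate, labels = labels),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz\n",
              nrow(x$data), ncol(x$data), x$rate))
  invisible(x)
}

#' Read an EEG matrix from CSV
#'
#' Expects a `channels x time` matrix with channel labels in the first
#' column and a header row of sample times (seconds).
#'
#' @param path CSV path.
#' @param rate Sampling rate (Hz); if `NULL`, inferred from the time header.
#' @return An [eeg_recording()].
#' @export
read_eeg_csv <- function(path, rate = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  labels <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  times <- suppressWarnings(as.numeric(colnames(mat)))
  if (is.null(rate)) {
    if (anyNA(times)) stop("cannot infer rate: header is not a time row")
    rate <- 1 / stats::median(diff(times))
  }
  rownames(mat) <- labels
  eeg_recording(mat, rate, labels)
}

# Legendre polynomial values P_1..P_n at x (vector), by recurrence.
legendre_table <- function(x, n_terms) {
  out <- matrix(0, length(x), n_terms)
  p_prev <- rep(1, length(x))  # P_0
  p_cur <- x                   # P_1
  out[, 1] <- p_cur
  if (n_terms > 1) {
    for (k in 2:n_terms) {
      p_next <- ((2 * k - 1) * x * p_cur - (k - 1) * p_prev) / k
      out[, k] <- p_next
      p_prev <- p_cur
      p_cur <- p_next
    }
  }
  out
}

# Spherical-spline g function (stiffness m = 4) of cos(angle) values.
spline_g <- function(cosang, m = 4, n_terms = 20) {
  k <- seq_len(n_terms)
  coef <- (2 * k + 1) / (k^m * (k + 1)^m)
  P <- legendre_table(pmin(1, pmax(-1, cosang)), n_terms)
  as.numeric(P %*% coef) / (4 * pi)
}

# Spherical-spline interpolation matrix mapping good-channel data to the
# bad channels (Perrin-style surface spline on the unit sphere).
spline_interp_matrix <- function(good_pos, bad_pos, m = 4, n_terms = 20) {
  gu <- good_pos / sqrt(rowSums(good_pos^2))
  bu <- bad_pos / sqrt(rowSums(bad_pos^2))
  k <- nrow(gu)
  G <- matrix(spline_g(tcrossprod(gu), m, n_terms), k, k)
  Gt <- matrix(spline_g(tcrossprod(bu, gu), m, n_terms), nrow(bu), k)
  A <- rbind(cbind(G + diag(1e-8, k), rep(1, k)), c(rep(1, k), 0))
  Ainv <- solve(A)
  (cbind(Gt, 1) %*% Ainv)[, seq_len(k), drop = FALSE]
}

#' Preprocess a raw EEG recording
#'
#' Applies, in order: average reference; 50 Hz low-pass; resampling to the
#' target rate (decimation after the anti-aliasing low-pass); 0.1 Hz
#' high-pass; an additional notch at the stimulation pulse frequency
#' (25 Hz); and spherical-spline interpolation of caller-listed bad
#' channels from their neighbors. All filters are zero-phase Butterworth.
#'
#' @param rec An [eeg_recording()] (raw rate typically 10 kHz).
#' @param bad_channels Channel labels to interpolate (at most 25% of all
#'   channels).
#' @param montage Electrode positions (data.frame as from
#'   [standard_montage_64()]) for the interpolation; required only when
#'   `bad_channels` is non-empty.
#' @param lowpass,highpass Band edges (Hz).
#' @param target_rate Output rate (Hz).
#' @param notch Notch center frequency (Hz), `NULL` to skip.
#' @return The preprocessed [eeg_recording()] at `target_rate`.
#' @export
preprocess_eeg <- function(rec, bad_channels = character(0), montage = NULL,
                           lowpass = 50, highpass = 0.1, target_rate = 1000,
                           notch = 25) {
  stopifnot(inherits(rec, "eeg_recording"))
  n_ch <- nrow(rec$data)
  if (length(bad_channels) > 0.25 * n_ch) {
    stop("more than 25% of channels listed bad (", length(bad_channels),
         " of ", n_ch, ")")
  }
  x <- rec$data
  # average reference
  x <- sweep(x, 2, colMeans(x))

  bf_lo <- signal::butter(4, lowpass / (rec$rate / 2), type = "low")
  x <- t(apply(x, 1, function(ch) as.numeric(signal::filtfilt(bf_lo, ch))))

  dec <- round(rec$rate / target_rate)
  if (dec > 1) {
    x <- x[, seq(1, ncol(x), by = dec), drop = FALSE]
  }
  rate <- rec$rate / max(dec, 1)

  # demean per channel before the high-pass: the filter's edge transients
  # on a strong DC offset are long relative to typical epochs, while the
  # offset itself is removed exactly by the subtraction
  x <- x - rowMeans(x)
  bf_hi <- signal::butter(2, highpass / (rate / 2), type = "high")
  x <- t(apply(x, 1, function(ch) as.numeric(signal::filtfilt(bf_hi, ch))))

  if (!is.null(notch)) {
    bf_n <- signal::butter(2, c(notch - 1, notch + 1) / (rate / 2), type = "stop")
    x <- t(apply(x, 1, function(ch) as.numeric(signal::filtfilt(bf_n, ch))))
  }

  if (length(bad_channels) > 0) {
    if (is.null(montage)) stop("montage positions required to interpolate bad channels")
    bad_idx <- match(bad_channels, rec$labels)
    if (anyNA(bad_idx)) stop("unknown bad channel label(s)")
    pos <- montage[match(rec$labels, montage$label), c("x", "y", "z")]
    if (anyNA(pos)) stop("montage is missing positions for some channels")
    pos <- as.matrix(pos)
    good_idx <- setdiff(seq_len(n_ch), bad_idx)
    M <- spline_interp_matrix(pos[good_idx, , drop = FALSE],
                              pos[bad_idx, , drop = FALSE])
    x[bad_idx, ] <- M %*% x[good_idx, , drop = FALSE]
  }
  rownames(x) <- rec$labels
  eeg_recording(x, rate, rec$labels)
}

#' Frequency band specification
#'
#' @param name `"alpha"` (8-13 Hz) or `"theta"` (4-8 Hz), or `"custom"`
#'   with explicit `lo`/`hi`.
#' @param lo,hi Band edges (Hz); defaulted from `name`.
#' @param n_cycles Morlet wavelet cycles (default 6).
#' @param baseline Baseline window (s) for power correction, default
#'   `c(-1, 0)`.
#' @return A list of class `band_spec`.
#' @export
band_spec <- function(name = c("alpha", "theta", "custom"), lo = NULL, hi = NULL,
                      n_cycles = 6, baseline = c(-1, 0)) {
  name <- match.arg(name)
  if (name == "alpha") { lo <- 8; hi <- 13 }
  if (name == "theta") { lo <- 4; hi <- 8 }
  stopifnot(!is.null(lo), !is.null(hi), lo < hi, n_cycles > 0)
  structure(list(name = name, lo = lo, hi = hi, n_cycles = n_cycles,
                 baseline = baseline), class = "band_spec")
}

# Complex Morlet wavelet power of one signal at one frequency (same-length
# FFT convolution). The kernel is normalized so that a unit-amplitude
# sinusoid at the centre frequency yields its mean-square power (1/2),
# making the output directly comparable to spectral power estimates.
morlet_power_1f <- function(x, rate, freq, n_cycles) {
  sigma_t <- n_cycles / (2 * pi * freq)
  half <- ceiling(4 * sigma_t * rate)
  tk <- (-half:half) / rate
  kern <- exp(2i * pi * freq * tk) * exp(-tk^2 / (2 * sigma_t^2))
  kern <- kern / sum(Mod(kern))
  n <- length(x)
  L <- stats::nextn(n + length(kern) - 1, 2)
  X <- stats::fft(c(x, rep(0, L - n)))
  K <- stats::fft(c(kern, rep(0, L - length(kern))))
  conv <- stats::fft(X * K, inverse = TRUE) / L
  centre <- conv[(half + 1):(half + n)]
  2 * Mod(centre)^2
}

#' Morlet-wavelet band power of stimulation epochs
#'
#' For each 1 Hz step inside the band, power is computed with a complex
#' Morlet wavelet of `n_cycles` cycles and averaged across frequencies;
#' the mean over the pre-stimulus baseline window is subtracted per
#' channel (unless `baseline` is `NULL`), and power is averaged across
#' epochs.
#'
#' @param epochs Array `epochs x channels x times` (uV), or a matrix
#'   `channels x times` for a single epoch.
#' @param rate Sampling rate (Hz).
#' @param times Time axis (s) relative to stimulation onset; must include
#'   the baseline window.
#' @param band A [band_spec()].
#' @return A list of class `band_power` with `power` (channels x times,
#'   baseline-corrected unless `baseline = NULL`), `times`, `band`, and
#'   `edge` (logical: samples within half a wavelet of the epoch edge).
#' @export
morlet_band_power <- function(epochs, rate, times, band = band_spec("alpha")) {
  if (is.matrix(epochs)) epochs <- array(epochs, dim = c(1, dim(epochs)))
  stopifnot(length(dim(epochs)) == 3, dim(epochs)[3] == length(times))
  n_ep <- dim(epochs)[1]; n_ch <- dim(epochs)[2]; n_t <- dim(epochs)[3]
  freqs <- seq(band$lo, band$hi, by = 1)
  if (!is.null(band$baseline) && times[1] > band$baseline[1]) {
    stop("epochs must include the baseline window (>= 1 s pre-stimulus)")
  }
  acc <- matrix(0, n_ch, n_t)
  for (ep in seq_len(n_ep)) {
    for (ch in seq_len(n_ch)) {
      p <- rowMeans(vapply(freqs, function(f) {
        morlet_power_1f(epochs[ep, ch, ], rate, f, band$n_cycles)
      }, numeric(n_t)))
      acc[ch, ] <- acc[ch, ] + p
    }
  }
  power <- acc / n_ep
  sigma_max <- band$n_cycles / (2 * pi * band$lo)
  half <- ceiling(4 * sigma_max * rate)
  edge <- seq_len(n_t) <= half | seq_len(n_t) > n_t - half
  if (!is.null(band$baseline)) {
    bidx <- times >= band$baseline[1] & times <= band$baseline[2]
    power <- power - rowMeans(power[, bidx, drop = FALSE])
  }
  structure(list(power = power, times = times, band = band, edge = edge),
            class = "band_power")
}

#' P300 peak amplitude from No-Go-locked epochs
#'
#' Epochs are baseline-corrected over the pre-stimulus window, averaged,
#' and the peak is the maximum amplitude of the target channel within the
#' search window.
#'
#' @param epochs Array `epochs x channels x times` (uV).
#' @param times Time axis (s) relative to stimulus onset.
#' @param labels Channel labels.
#' @param channel Measurement channel (default `"Pz"`).
#' @param baseline Baseline window (s), default `c(-0.2, 0)`.
#' @param window Peak search window (s), default `c(0.25, 0.7)`.
#' @param min_epochs Minimum epochs required (default 5).
#' @return A list with `peak_amplitude` (uV), `peak_time` (s), and `erp`
#'   (averaged channels x times matrix).
#' @export
erp_p300 <- function(epochs, times, labels, channel = "Pz",
                     baseline = c(-0.2, 0), window = c(0.25, 0.7),
                     min_epochs = 5) {
  stopifnot(length(dim(epochs)) == 3, dim(epochs)[3] == length(times))
  if (dim(epochs)[1] < min_epochs) {
    stop("at least ", min_epochs, " epochs are required")
  }
  ch <- match(channel, labels)
  if (is.na(ch)) stop("channel ", channel, " not present in epochs")
  bidx <- times >= baseline[1] & times <= baseline[2]
  # baseline-correct each epoch per channel, then average
  bmean <- apply(epochs[, , bidx, drop = FALSE], c(1, 2), mean)
  corrected <- sweep(epochs, c(1, 2), bmean)
  erp <- apply(corrected, c(2, 3), mean)
  widx <- which(times >= window[1] & times <= window[2])
  peak_i <- widx[which.max(erp[ch, widx])]
  list(peak_amplitude = erp[ch, peak_i], peak_time = times[peak_i], erp = erp)
}
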