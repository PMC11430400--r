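#!/usr/bin/env Rscript
# Step 5 - EEG: demonstrates the raw preprocessing chain on a short
# multichannel recording (average reference, 0.1-50 Hz band-pass,
# 10 kHz -> 1 kHz, 25 Hz notch, spherical-spline interpolation), Morlet
# alpha/theta band power of stimulation epochs, and cluster permutation
# inference on subject-level band-power differences (one null band, one
# with an injected effect). P300 peaks are extracted from synthetic
# No-Go-locked epochs.

suppressMessages(library(tavnspipe))

seed <- 20240
dir.create("results", showWarnings = FALSE)
set.seed(seed)

## raw preprocessing demonstration (short 10 kHz segment, 16 channels)
mont <- standard_montage_64()
labels16 <- mont$label[1:16]
rate_raw <- 10000
t_raw <- seq(0, 2 - 1 / rate_raw, by = 1 / rate_raw)
raw <- matrix(rnorm(16 * length(t_raw), sd = 10), 16)
raw <- raw + matrix(rep(5 * sin(2 * pi * 25 * t_raw), each = 16), 16)  # stim artifact
rec <- eeg_recording(raw, rate_raw, labels16)
pp <- preprocess_eeg(rec, bad_channels = labels16[3], montage = mont)
message(sprintf("preprocessed: %d channels x %d samples at %g Hz",
                nrow(pp$data), ncol(pp$data), pp$rate))

## Morlet band power of one stimulation epoch with an alpha burst
rate <- 1000
times <- seq(-1.5, 4, by = 1 / rate)
burst <- exp(-(times - 1.5)^2 / 0.5) * sin(2 * pi * 10 * times)
epoch <- matrix(rnorm(4 * length(times), sd = 0.3), 4)
epoch[2, ] <- epoch[2, ] + 3 * burst
bp <- morlet_band_power(epoch, rate, times, band_spec("alpha"))
peak_ch <- which.max(apply(bp$power, 1, max))
message(sprintf("alpha burst localized to channel %d (truth: 2), peak at %.2f s",
                peak_ch, times[which.max(bp$power[peak_ch, ])]))

## cluster inference on band-power differences, 32 channels
adj <- build_adjacency(mont[1:32, ])
for (band in c("alpha", "theta")) {
  injected <- band == "theta"
  g <- gen_eeg_epochs(16, 32, 50,
                      effect_window = if (injected) list(channels = 3:8, times = 20:40),
                      effect_size = if (injected) 1.2 else 0,
                      seed = sample.int(1e6, 1))
  res <- cluster_permutation_test(g$data, adj, n_permutations = 1000,
                                  seed = sample.int(1e6, 1))
  n_sig <- sum(res$clusters$significant)
  message(sprintf("%s band (%s): %d candidate cluster(s), %d significant",
                  band, if (injected) "effect injected" else "null",
                  nrow(res$clusters), n_sig))
  write_cluster_tsv(res, sprintf("results/eeg_clusters_%s.tsv", band),
                    channel_labels = mont$label[1:32])
}

## P300 from synthetic No-Go epochs
g <- gen_erp_epochs(n_epochs = 40, peak_amp = 8, noise_sd = 6,
                    seed = sample.int(1e6, 1))
pk <- erp_p300(g$epochs, g$times, g$labels)
message(sprintf("P300 peak at Pz: %.1f uV at %.0f ms (truth: 8 uV at 500 ms)",
                pk$peak_amplitude, 1000 * pk$peak_time))
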