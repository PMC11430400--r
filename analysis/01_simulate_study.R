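#!/usr/bin/env Rscript
# Step 1 - materialize a synthetic two-protocol sham-controlled crossover
# on disk: pupil recordings with stimulation events, light-reflex sessions,
# saliva samples, behavioral trial tables and band-power arrays. All later
# steps regenerate what they need from the same master seed, so this step
# exists to inspect the raw-level inputs and to exercise the CSV readers.

suppressMessages(library(tavnspipe))

seed <- 20240
out <- "results/synthetic_study"
dir.create("results", showWarnings = FALSE)

message("Writing synthetic study (seed ", seed, ") to ", out)
write_synthetic_study(out, seed = seed, n_subjects = 3)

files <- list.files(out)
message("wrote ", length(files), " files, e.g.: ",
        paste(head(files, 5), collapse = ", "))

# sanity: the pupil CSV round-trips through the reader
rec <- read_pupil_csv(file.path(out, "pupil_rest_s01.csv"))
message(sprintf("subject 1 resting recording: %d samples at %.0f Hz",
                length(rec$time), rec$rate))
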