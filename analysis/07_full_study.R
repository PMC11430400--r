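#!/usr/bin/env Rscript
# Step 7 - the whole pipeline in one call: run_study() executes every
# modality over a synthetic crossover and writes the complete results
# bundle (tables mirroring the saliva summary layout, cluster tables,
# test-result TSVs and the exclusion log) into results/full_study/.

suppressMessages(library(tavnspipe))

seed <- 20240
bundle <- suppressWarnings(run_study(
  seed = seed, out_dir = "results/full_study", n_subjects = 8,
  effects = list(saliva = 40, pupil = 0.15, eeg = 0, behavior = 10),
  n_permutations = 1000))

message("modalities run: ",
        paste(intersect(c("saliva", "pupil", "plr", "eeg", "behavior", "erp"),
                        names(bundle)), collapse = ", "))
message("log:")
for (l in bundle$log) message("  ", l)
message("results written to results/full_study/")
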