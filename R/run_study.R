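# End-to-end pipeline over a synthetic two-protocol sham-controlled
# crossover: saliva, resting pupil + cluster inference, light reflex + LMM,
# band power + cluster inference, Go/No-Go + SST + P300, and the
# difference-score statistics, with every exclusion logged.

conditions_grid <- function() {
  expand.grid(protocol = c("3.4s", "30s"), arm = c("real", "sham"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Run the full pipeline on a synthetic study
#'
#' Generates every modality with the synthetic module, runs the complete
#' analysis chain and (optionally) writes result tables to a directory.
#' All randomness derives from the single `seed`, so two runs with the
#' same seed produce identical results.
#'
#' @param seed Master integer seed.
#' @param out_dir Output directory for TSV tables, or `NULL` to skip
#'   writing.
#' @param n_subjects Number of synthetic subjects.
#' @param effects Named list of injected ground-truth effects:
#'   `saliva` (U/mL added to real stimulation samples), `pupil`
#'   (stimulation-locked dilation amplitude in mm for the real arm),
#'   `eeg` (standardized band-power shift in the injected window) and
#'   `behavior` (ms added to the real-arm go RT mean).
#' @param n_permutations Permutations for the cluster tests.
#' @param modalities Subset of
#'   `c("saliva", "pupil", "plr", "eeg", "behavior", "erp")` to run; a
#'   missing modality is skipped with a logged warning.
#' @return A results bundle (named list), invisibly the same content that
#'   is written to `out_dir`.
#' @export
run_study <- function(seed = 1, out_dir = NULL, n_subjects = 8,
                      effects = list(saliva = 25, pupil = 0.1, eeg = 0,
                                     behavior = 0),
                      n_permutations = 500,
                      modalities = c("saliva", "pupil", "plr", "eeg",
                                     "behavior", "erp")) {
  sub_seeds <- with_seed(seed, sample.int(1e6, 4096))
  seed_at <- local({
    i <- 0L
    function() {
      i <<- i + 1L
      sub_seeds[i]
    }
  })
  bundle <- list(seed = seed, n_subjects = n_subjects)
  grid <- conditions_grid()
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  ## ---- saliva -------------------------------------------------------
  if ("saliva" %in% modalities) {
    sal <- gen_saliva_table(n_subjects, condition_effect = effects$saliva,
                            seed = seed_at())
    sal$secretion <- compute_secretion(sal$concentration, sal$sample_weight_g,
                                       sal$collection_duration_min)
    sal$daytime <- assign_daytime_bin(sal$clock_time)
    long <- rbind(
      data.frame(subject = sal$subject, measure = "concentration",
                 condition = paste(sal$protocol, sal$arm), phase = sal$phase,
                 value = sal$concentration),
      data.frame(subject = sal$subject, measure = "secretion",
                 condition = paste(sal$protocol, sal$arm), phase = sal$phase,
                 value = sal$secretion))
    diffs <- difference_scores(long)
    tests <- list()
    for (meas in c("concentration", "secretion")) {
      for (proto in c("3.4s", "30s")) {
        d <- diffs[diffs$measure == meas, ]
        real <- d$diff[d$condition == paste(proto, "real")][order(d$subject[d$condition == paste(proto, "real")])]
        sham <- d$diff[d$condition == paste(proto, "sham")][order(d$subject[d$condition == paste(proto, "sham")])]
        res <- paired_compare(real, sham)
        res$measure <- meas
        res$protocol <- proto
        tests[[length(tests) + 1]] <- res
      }
    }
    base_wide <- with(sal[sal$phase == "baseline", ], {
      key <- paste(protocol, arm)
      tapply(concentration, list(subject, key), mean)
    })
    stim <- sal[sal$phase == "stim", ]
    lmm <- fit_random_intercept_lmm(stim, "concentration",
                                    fixed = "arm * daytime",
                                    subject = "subject")
    bundle$saliva <- list(table = sal, diffs = diffs,
                          tests = do.call(rbind, tests),
                          baseline_check = baseline_check(base_wide),
                          lmm = lmm)
    note("saliva: %d samples, %d tests", nrow(sal), length(tests))
  } else note("saliva: skipped (modality not requested)")

  ## ---- resting pupil + cluster test --------------------------------
  if ("pupil" %in% modalities) {
    pupil <- list()
    for (proto_lab in c("3.4s", "30s")) {
      proto <- protocol_spec(proto_lab)
      cycle <- proto$stim_duration + if (proto_lab == "30s") 30 else 26.6
      onsets <- seq(30, by = cycle, length.out = 4)
      dur <- max(onsets) + proto$stim_duration + proto$post_duration + 5
      traces <- list(left = list(), right = list())
      qc_all <- list()
      for (s in seq_len(n_subjects)) {
        base_d <- with_seed(seed_at(), stats::rnorm(1, 4.5, 0.4))
        for (arm in c("real", "sham")) {
          amp <- if (arm == "real") effects$pupil else 0
          cfg <- pupil_gen_config(duration = dur, stim_onsets = onsets,
                                  baseline_diameter = base_d,
                                  stim_response_amplitude = amp,
                                  blink_rate = 4, seed = seed_at())
          rec <- gen_pupil_rest_recording(cfg)$recording
          res <- process_pupil_rest(rec, onsets, proto)
          qc <- res$qc
          qc$subject <- s; qc$arm <- arm; qc$protocol <- proto_lab
          qc_all[[length(qc_all) + 1]] <- qc
          for (eye in c("left", "right")) {
            tr <- res$traces[[eye]]
            if (inherits(tr, "subject_excluded")) {
              note("pupil: subject %d %s %s %s excluded (%s)",
                   s, proto_lab, arm, eye, tr$reason)
              next
            }
            traces[[eye]][[paste(s, arm)]] <- tr$trace
          }
        }
      }
      clusters <- list()
      for (eye in c("left", "right")) {
        keys <- names(traces[[eye]])
        subj_ids <- unique(sub(" .*", "", keys))
        rows <- list()
        for (sid in subj_ids) {
          kr <- paste(sid, "real"); ks <- paste(sid, "sham")
          if (kr %in% keys && ks %in% keys) {
            rows[[sid]] <- traces[[eye]][[kr]] - traces[[eye]][[ks]]
          }
        }
        if (length(rows) >= 3) {
          mat <- do.call(rbind, rows)
          clusters[[eye]] <- cluster_permutation_test(
            mat, adjacency = NULL, n_permutations = n_permutations,
            seed = seed_at())
        } else {
          note("pupil: %s %s cluster test skipped (<3 complete subjects)",
               proto_lab, eye)
        }
      }
      pupil[[proto_lab]] <- list(clusters = clusters,
                                 qc = do.call(rbind, qc_all))
    }
    bundle$pupil <- pupil
  } else note("pupil: skipped (modality not requested)")

  ## ---- light reflex + LMM -------------------------------------------
  if ("plr" %in% modalities) {
    flash_times <- seq(5, by = 11, length.out = 12)
    rows <- list()
    for (s in seq_len(n_subjects)) {
      # subject-level reflex morphology (stable across conditions)
      subj_model <- with_seed(seed_at(), {
        d1 <- stats::rnorm(1, 6.5, 0.4)
        tl <- stats::rnorm(1, 0.25, 0.02)
        plr_gen_model(d1 = d1, d2 = d1 - stats::rnorm(1, 2.5, 0.3),
                      t_latency = tl, t_min = tl + stats::rnorm(1, 0.85, 0.05),
                      redil_tau = stats::rnorm(1, 2, 0.2), noise_sd = 0.02)
      })
      for (k in seq_len(nrow(grid))) {
        gen <- gen_plr_recording(subj_model, flash_times, seed = seed_at())
        epochs <- preprocess_plr(gen$recording, flash_times)
        for (ep in epochs) {
          if (qc_plr(ep) != "pass") next
          p <- extract_plr_parameters(ep)
          p$subject <- s
          p$protocol <- grid$protocol[k]
          p$arm <- grid$arm[k]
          rows[[length(rows) + 1]] <- p
        }
      }
    }
    params <- do.call(rbind, rows)
    id_cols <- c("subject", "protocol", "arm", "eye", "intensity")
    par_cols <- setdiff(names(params), c(id_cols, "flash_time"))
    long <- stats::reshape(params[, c(id_cols, par_cols)],
                           varying = par_cols, v.names = "value",
                           times = par_cols, timevar = "parameter",
                           direction = "long")
    rownames(long) <- NULL
    long$id <- NULL
    agg <- aggregate_plr(long, by = c("subject", "protocol", "arm", "eye",
                                      "intensity"))
    lmm_rows <- list()
    for (par in par_cols) {
      dat <- agg[agg$parameter == par & !is.na(agg$value), ]
      fitres <- tryCatch(
        fit_random_intercept_lmm(dat, "value",
                                 fixed = c("protocol * arm", "eye",
                                           "factor(intensity)"),
                                 subject = "subject", m = length(par_cols)),
        error = function(e) NULL)
      if (is.null(fitres)) {
        note("plr: LMM for %s failed", par)
        next
      }
      fitres$parameter <- par
      lmm_rows[[par]] <- fitres
    }
    bundle$plr <- list(parameters = agg, lmm = do.call(rbind, lmm_rows),
                       n_outliers_removed = attr(agg, "removed"))
    note("plr: %d parameter sets, %d outliers removed",
         nrow(params), attr(agg, "removed"))
  } else note("plr: skipped (modality not requested)")

  ## ---- EEG band power + cluster test --------------------------------
  if ("eeg" %in% modalities) {
    montage <- standard_montage_64()
    labels <- montage$label[seq_len(32)]
    adj <- build_adjacency(montage[seq_len(32), ])
    eeg <- list()
    for (band_name in c("alpha", "theta")) {
      win <- if (effects$eeg != 0) {
        list(channels = 1:5, times = 15:30)
      } else NULL
      g <- gen_eeg_epochs(n_subjects, 32, 50, effect_window = win,
                          effect_size = effects$eeg, seed = seed_at())
      eeg[[band_name]] <- list(
        result = cluster_permutation_test(g$data, adj,
                                          n_permutations = n_permutations,
                                          seed = seed_at()),
        truth = g$truth)
    }
    bundle$eeg <- eeg
    bundle$eeg_labels <- labels
  } else note("eeg: skipped (modality not requested)")

  ## ---- behavior: GNG + SST ------------------------------------------
  if ("behavior" %in% modalities) {
    score_rows <- list()
    for (s in seq_len(n_subjects)) {
      for (k in seq_len(nrow(grid))) {
        for (phase in c("baseline", "stim")) {
          shift <- if (grid$arm[k] == "real" && phase == "stim") effects$behavior else 0
          gng <- gen_gng_trials(rt_mu = 420 + shift, seed = seed_at())
          sc <- score_gng(gng)
          agent <- race_agent(go_mu = 400 + shift, omission_rate = 0.02,
                              choice_error_rate = 0.02)
          sst <- run_staircase_session(agent, seed = seed_at())
          ssrt <- estimate_ssrt(sst)
          score_rows[[length(score_rows) + 1]] <- data.frame(
            subject = s, protocol = grid$protocol[k], arm = grid$arm[k],
            phase = phase, accuracy = sc$accuracy,
            error_rate = sc$error_rate, mean_go_rt = sc$mean_go_rt,
            ssrt = as.numeric(ssrt))
        }
      }
    }
    scores <- do.call(rbind, score_rows)
    tests <- list()
    for (meas in c("accuracy", "error_rate", "mean_go_rt", "ssrt")) {
      long <- data.frame(subject = scores$subject, measure = meas,
                         condition = paste(scores$protocol, scores$arm),
                         phase = scores$phase, value = scores[[meas]])
      diffs <- difference_scores(long)
      for (proto in c("3.4s", "30s")) {
        real <- diffs$diff[diffs$condition == paste(proto, "real")]
        sham <- diffs$diff[diffs$condition == paste(proto, "sham")]
        res <- tryCatch(paired_compare(real, sham), error = function(e) NULL)
        if (is.null(res)) next
        res$measure <- meas; res$protocol <- proto
        tests[[length(tests) + 1]] <- res
      }
    }
    bundle$behavior <- list(scores = scores, tests = do.call(rbind, tests))
    note("behavior: %d sessions scored", nrow(scores))
  } else note("behavior: skipped (modality not requested)")

  ## ---- P300 ----------------------------------------------------------
  if ("erp" %in% modalities) {
    p3_rows <- list()
    for (s in seq_len(n_subjects)) {
      for (k in seq_len(nrow(grid))) {
        for (phase in c("baseline", "stim")) {
          g <- gen_erp_epochs(n_epochs = 20, seed = seed_at())
          pk <- erp_p300(g$epochs, g$times, g$labels)
          p3_rows[[length(p3_rows) + 1]] <- data.frame(
            subject = s, protocol = grid$protocol[k], arm = grid$arm[k],
            phase = phase, p300 = pk$peak_amplitude)
        }
      }
    }
    p3 <- do.call(rbind, p3_rows)
    long <- data.frame(subject = p3$subject, measure = "p300",
                       condition = paste(p3$protocol, p3$arm),
                       phase = p3$phase, value = p3$p300)
    diffs <- difference_scores(long)
    tests <- list()
    for (proto in c("3.4s", "30s")) {
      real <- diffs$diff[diffs$condition == paste(proto, "real")]
      sham <- diffs$diff[diffs$condition == paste(proto, "sham")]
      res <- paired_compare(real, sham)
      res$measure <- "p300"; res$protocol <- proto
      tests[[length(tests) + 1]] <- res
    }
    bundle$erp <- list(peaks = p3, tests = do.call(rbind, tests))
  } else note("erp: skipped (modality not requested)")

  bundle$log <- log_lines

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(bundle$saliva)) {
      wt(bundle$saliva$table, "saliva_table.tsv")
      wt(bundle$saliva$tests, "saliva_tests.tsv")
      wt(bundle$saliva$lmm, "saliva_lmm.tsv")
    }
    if (!is.null(bundle$pupil)) {
      for (proto in names(bundle$pupil)) {
        wt(bundle$pupil[[proto]]$qc,
           sprintf("pupil_qc_%s.tsv", gsub("[.]", "_", proto)))
        for (eye in names(bundle$pupil[[proto]]$clusters)) {
          write_cluster_tsv(bundle$pupil[[proto]]$clusters[[eye]],
                            file.path(out_dir, sprintf("pupil_clusters_%s_%s.tsv",
                                                       gsub("[.]", "_", proto), eye)))
        }
      }
    }
    if (!is.null(bundle$plr)) {
      wt(bundle$plr$parameters, "plr_parameters.tsv")
      wt(bundle$plr$lmm, "plr_lmm.tsv")
    }
    if (!is.null(bundle$eeg)) {
      for (band in names(bundle$eeg)) {
        write_cluster_tsv(bundle$eeg[[band]]$result,
                          file.path(out_dir, sprintf("eeg_clusters_%s.tsv", band)),
                          channel_labels = bundle$eeg_labels)
      }
    }
    if (!is.null(bundle$behavior)) {
      wt(bundle$behavior$scores, "behavior_scores.tsv")
      wt(bundle$behavior$tests, "behavior_tests.tsv")
    }
    if (!is.null(bundle$erp)) wt(bundle$erp$tests, "p300_tests.tsv")
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  invisible(bundle)
}

#' Materialize a full synthetic study on disk
#'
#' Writes the raw-level synthetic inputs (pupil CSVs, event logs, saliva
#' table, behavioral trial tables, band-power arrays) in the same layouts
#' the package's readers accept.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param n_subjects Number of subjects.
#' @return The directory path, invisibly.
#' @export
write_synthetic_study <- function(dir, seed = 1, n_subjects = 3) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sub_seeds <- with_seed(seed, sample.int(1e6, 1024))
  i <- 0L
  nxt <- function() {
    i <<- i + 1L
    sub_seeds[i]
  }
  sal <- gen_saliva_table(n_subjects, condition_effect = 25, seed = nxt())
  utils::write.csv(sal, file.path(dir, "saliva.csv"), row.names = FALSE)
  onsets <- seq(30, by = 30, length.out = 4)
  for (s in seq_len(n_subjects)) {
    cfg <- pupil_gen_config(duration = 160, stim_onsets = onsets,
                            seed = nxt())
    rec <- gen_pupil_rest_recording(cfg)$recording
    write_pupil_csv(rec, file.path(dir, sprintf("pupil_rest_s%02d.csv", s)))
    utils::write.csv(data.frame(timestamp_s = onsets, event_type = "stim_on"),
                     file.path(dir, sprintf("events_s%02d.csv", s)),
                     row.names = FALSE)
    flashes <- seq(5, by = 11, length.out = 12)
    plr <- gen_plr_recording(plr_gen_model(), flashes, seed = nxt())
    write_pupil_csv(plr$recording, file.path(dir, sprintf("plr_s%02d.csv", s)))
    gng <- gen_gng_trials(seed = nxt())
    utils::write.csv(gng, file.path(dir, sprintf("gng_s%02d.csv", s)),
                     row.names = FALSE)
    sst <- run_staircase_session(race_agent(), seed = nxt())
    utils::write.csv(sst, file.path(dir, sprintf("sst_s%02d.csv", s)),
                     row.names = FALSE)
  }
  g <- gen_eeg_epochs(max(n_subjects, 3), 16, 40, seed = nxt())
  for (s in seq_len(dim(g$data)[1])) {
    utils::write.table(g$data[s, , ],
                       file.path(dir, sprintf("bandpower_s%02d.tsv", s)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}
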