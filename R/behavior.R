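# Stop-signal task: staircase execution against an independent-race agent
# and SSRT estimation (integration method with omission replacement);
# Go/No-Go scoring per the accuracy / error-rate / Go-RT definitions.

#' Independent-race agent for stop-signal simulation
#'
#' Go finishing times are ex-Gaussian; the stop process finishes a fixed
#' `ssrt_true` ms after the stop signal. On a stop trial a response is
#' emitted iff the go finishing time beats `SSD + ssrt_true`
#' (independent-race assumption).
#'
#' @param go_mu,go_sigma,go_tau Ex-Gaussian go finishing-time parameters (ms).
#' @param ssrt_true True stop finishing time (ms).
#' @param omission_rate P(no response) on a go trial.
#' @param choice_error_rate P(wrong hand) on an answered go trial.
#' @return A list of class `race_agent`.
#' @export
race_agent <- function(go_mu = 400, go_sigma = 50, go_tau = 60,
                       ssrt_true = 220, omission_rate = 0,
                       choice_error_rate = 0) {
  stopifnot(go_mu > 0, go_sigma > 0, go_tau > 0, ssrt_true > 0,
            omission_rate >= 0, omission_rate <= 1,
            choice_error_rate >= 0, choice_error_rate <= 1)
  structure(list(go_mu = go_mu, go_sigma = go_sigma, go_tau = go_tau,
                 ssrt_true = ssrt_true, omission_rate = omission_rate,
                 choice_error_rate = choice_error_rate),
            class = "race_agent")
}

#' Simulate a stop-signal session with SSD staircase tracking
#'
#' Trials are randomized per block with the stated stop/go mix. Go trials
#' sample an ex-Gaussian finishing time (times past the deadline are
#' omissions). On stop trials the response is emitted iff the go finishing
#' time is below `SSD + ssrt_true`; after every stop trial the SSD moves by
#' `ssd_step` (up after successful inhibition, down after a response; floor
#' at 0).
#'
#' @param agent A [race_agent()].
#' @param n_blocks,trials_per_block,stop_fraction Session structure
#'   (defaults 4 blocks x 64 trials, 25% stop).
#' @param ssd_init Initial SSD (ms, default 300).
#' @param ssd_step Staircase step (ms, default 50).
#' @param deadline Response deadline (ms, default 1250).
#' @param seed Integer seed.
#' @return A data.frame trial table (`task = "SST"`) with columns `block`,
#'   `trial`, `stimulus`, `is_stop`, `ssd`, `response`, `rt_ms`,
#'   `stop_success`.
#' @export
run_staircase_session <- function(agent, n_blocks = 4, trials_per_block = 64,
                                  stop_fraction = 0.25, ssd_init = 300,
                                  ssd_step = 50, deadline = 1250, seed = 1L) {
  stopifnot(inherits(agent, "race_agent"), stop_fraction > 0, stop_fraction < 1)
  with_seed(seed, {
    ssd <- ssd_init
    rows <- vector("list", n_blocks)
    for (b in seq_len(n_blocks)) {
      n_stop <- round(trials_per_block * stop_fraction)
      is_stop <- sample(rep(c(TRUE, FALSE), c(n_stop, trials_per_block - n_stop)))
      stim <- sample(c("go_left", "go_right"), trials_per_block, replace = TRUE)
      ssd_rec <- rep(NA_real_, trials_per_block)
      response <- character(trials_per_block)
      rt <- rep(NA_real_, trials_per_block)
      success <- rep(NA, trials_per_block)
      ft <- rexgauss(trials_per_block, agent$go_mu, agent$go_sigma, agent$go_tau)
      omit <- stats::runif(trials_per_block) < agent$omission_rate
      wrong <- stats::runif(trials_per_block) < agent$choice_error_rate
      for (i in seq_len(trials_per_block)) {
        hand <- if (stim[i] == "go_left") "left" else "right"
        if (wrong[i]) hand <- setdiff(c("left", "right"), hand)
        if (is_stop[i]) {
          ssd_rec[i] <- ssd
          responded <- !omit[i] && ft[i] < ssd + agent$ssrt_true && ft[i] <= deadline
          if (responded) {
            response[i] <- hand
            rt[i] <- ft[i]
            success[i] <- FALSE
            ssd <- max(0, ssd - ssd_step)
          } else {
            response[i] <- "none"
            success[i] <- TRUE
            ssd <- ssd + ssd_step
          }
        } else {
          if (omit[i] || ft[i] > deadline) {
            response[i] <- "none"
          } else {
            response[i] <- hand
            rt[i] <- ft[i]
          }
        }
      }
      rows[[b]] <- data.frame(block = b, trial = seq_len(trials_per_block),
                              task = "SST", stimulus = ifelse(is_stop, "stop", stim),
                              is_stop = is_stop, ssd = ssd_rec,
                              response = response, rt_ms = rt,
                              stop_success = success)
    }
    out <- do.call(rbind, rows)
    out$trial_index <- seq_len(nrow(out))
    out
  })
}

#' Estimate the stop-signal reaction time (integration method)
#'
#' SSRT is estimated with the integration method with omission
#' replacement: with `p = P(respond | stop trial)`, omitted go RTs are
#' replaced by the deadline, and `SSRT = p-th quantile of the go RT
#' distribution - mean SSD`.
#'
#' @param trials A stop-signal trial table from [run_staircase_session()]
#'   (or with the same columns).
#' @param deadline Deadline (ms) substituted for omitted go responses.
#' @param min_stop_trials Minimum number of stop trials (default 32).
#' @return The SSRT estimate (ms) with attributes `p_respond` and
#'   `mean_ssd`; `NA` (flagged via attribute `reason`) when all or no
#'   stops were successful, which carries no race information.
#' @export
estimate_ssrt <- function(trials, deadline = 1250, min_stop_trials = 32) {
  stop_tr <- trials[trials$is_stop, ]
  if (nrow(stop_tr) < min_stop_trials) {
    stop("need at least ", min_stop_trials, " stop trials")
  }
  p_respond <- mean(stop_tr$response != "none")
  if (p_respond == 0 || p_respond == 1) {
    out <- NA_real_
    attr(out, "reason") <- "degenerate_inhibition_rate"
    return(out)
  }
  go_tr <- trials[!trials$is_stop, ]
  go_rt <- ifelse(go_tr$response == "none", deadline, go_tr$rt_ms)
  ssrt <- as.numeric(stats::quantile(go_rt, p_respond)) - mean(stop_tr$ssd)
  attr(ssrt, "p_respond") <- p_respond
  attr(ssrt, "mean_ssd") <- mean(stop_tr$ssd)
  ssrt
}

#' Score a Go/No-Go session
#'
#' Accuracy is the number of correct Go responses plus correct No-Go
#' rejections divided by the total number of stimuli; the error rate counts
#' No-Go commissions plus incorrect (wrong-hand) Go responses over the
#' total; mean RT is over correct Go responses only.
#'
#' @param trials A GNG trial table from [gen_gng_trials()] (columns
#'   `is_go`, `correct_response`, `response`, `rt_ms`).
#' @return A list with `accuracy`, `error_rate`, `mean_go_rt` and the
#'   reconciling `counts` (correct_go, correct_nogo, commission,
#'   go_wrong_hand, go_omission, total).
#' @export
score_gng <- function(trials) {
  if (nrow(trials) == 0) stop("empty trial table")
  go <- trials$is_go
  resp <- trials$response
  correct_go <- go & resp != "none" &
    (trials$correct_response == "either" | resp == trials$correct_response)
  correct_nogo <- !go & resp == "none"
  commission <- !go & resp != "none"
  go_wrong <- go & resp != "none" & trials$correct_response != "either" &
    resp != trials$correct_response
  go_omit <- go & resp == "none"
  n <- nrow(trials)
  list(
    accuracy = (sum(correct_go) + sum(correct_nogo)) / n,
    error_rate = (sum(commission) + sum(go_wrong)) / n,
    mean_go_rt = mean(trials$rt_ms[correct_go]),
    counts = c(correct_go = sum(correct_go), correct_nogo = sum(correct_nogo),
               commission = sum(commission), go_wrong_hand = sum(go_wrong),
               go_omission = sum(go_omit), total = n))
}
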