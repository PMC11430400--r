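# Difference-score statistical layer: condition-minus-baseline scores, MAD
# outlier removal, paired t / Wilcoxon comparisons with Cohen's d, Friedman
# baseline checks with pairwise follow-ups, and random-intercept mixed
# models with sum-coded contrasts and Bonferroni correction.

#' Condition-minus-baseline difference scores
#'
#' For every subject x measure x condition, subtracts the matching baseline
#' value from the stimulation value. A missing baseline yields a missing
#' difference (flagged in the `"missing"` attribute).
#'
#' @param df Long data.frame with columns `subject`, `measure`,
#'   `condition`, `phase` (`"baseline"`/`"stim"`) and `value`.
#' @return A data.frame with columns `subject`, `measure`, `condition`,
#'   `diff`.
#' @export
difference_scores <- function(df) {
  need <- c("subject", "measure", "condition", "phase", "value")
  stopifnot(all(need %in% names(df)))
  base <- df[df$phase == "baseline", c("subject", "measure", "condition", "value")]
  names(base)[4] <- "baseline"
  stim <- df[df$phase == "stim", c("subject", "measure", "condition", "value")]
  m <- merge(stim, base, by = c("subject", "measure", "condition"), all.x = TRUE)
  m$diff <- m$value - m$baseline
  out <- m[order(m$subject, m$measure, m$condition),
           c("subject", "measure", "condition", "diff")]
  rownames(out) <- NULL
  miss <- which(is.na(out$diff))
  if (length(miss)) attr(out, "missing") <- miss
  out
}

#' MAD-based outlier removal
#'
#' Removes values more than `k` median absolute deviations (consistency
#' scaled) from the median.
#'
#' @param values Numeric vector (length >= 3).
#' @param k Threshold in MADs (default 3).
#' @return A list with `kept` (values retained), `removed_idx` (indices
#'   removed) and `keep` (logical mask).
#' @export
remove_outliers_mad <- function(values, k = 3) {
  stopifnot(length(values) >= 3)
  med <- stats::median(values, na.rm = TRUE)
  m <- stats::mad(values, na.rm = TRUE)
  keep <- is.na(values) | abs(values - med) <= k * m
  list(kept = values[keep & !is.na(values)], removed_idx = which(!keep),
       keep = keep)
}

#' Paired comparison with automatic test selection
#'
#' Pair differences are tested for normality (Shapiro-Wilk at 0.05); a
#' paired t-test is used when normality is not rejected, otherwise a
#' Wilcoxon signed-rank test (exact for n < 26; zero differences dropped).
#' When the result is significant at `alpha`, Cohen's d for paired designs
#' (mean of pair differences over their SD) is attached.
#'
#' @param x,y Paired numeric vectors (condition, comparison), `n >= 5`
#'   complete pairs.
#' @param alpha Significance level (default 0.05).
#' @return A one-row data.frame of class `paired_test`: `test`,
#'   `statistic`, `df` (t only), `p`, `effect_size_d` (when significant),
#'   `n_pairs`, `degenerate`.
#' @export
paired_compare <- function(x, y, alpha = 0.05) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) stop("need at least 5 complete pairs, got ", n)
  d <- x - y
  if (all(d == 0)) {
    return(structure(data.frame(test = "none", statistic = NA_real_,
                                df = NA_real_, p = NA_real_,
                                effect_size_d = NA_real_, n_pairs = n,
                                degenerate = TRUE), class = c("paired_test", "data.frame")))
  }
  sw_p <- tryCatch(stats::shapiro.test(d)$p.value, error = function(e) 0)
  if (sw_p > 0.05) {
    tt <- stats::t.test(x, y, paired = TRUE)
    res <- data.frame(test = "paired_t", statistic = unname(tt$statistic),
                      df = unname(tt$parameter), p = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                              exact = n < 26))
    res <- data.frame(test = "wilcoxon", statistic = unname(wt$statistic),
                      df = NA_real_, p = wt$p.value)
  }
  res$effect_size_d <- if (res$p <= alpha) mean(d) / stats::sd(d) else NA_real_
  res$n_pairs <- n
  res$degenerate <- FALSE
  structure(res, class = c("paired_test", "data.frame"))
}

#' Friedman baseline check with pairwise follow-ups
#'
#' Tests whether the baseline columns differ across conditions with a
#' Friedman rank sum test on complete blocks. If significant at `alpha`,
#' all pairwise Wilcoxon signed-rank tests between condition columns are
#' computed (the design is within-subject, so the paired rank test is
#' used).
#'
#' @param baselines Numeric matrix or data.frame `subjects x conditions`.
#' @param alpha Level for triggering the pairwise follow-up (default 0.05).
#' @return A list with `friedman` (data.frame: `chisq`, `df`, `p`, `n`)
#'   and `pairwise` (data.frame of condition pairs with `W` and `p`, or
#'   `NULL`).
#' @export
baseline_check <- function(baselines, alpha = 0.05) {
  m <- as.matrix(baselines)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 2) stop("need at least 2 complete blocks")
  ft <- stats::friedman.test(m)
  chisq <- unname(ft$statistic)
  p <- ft$p.value
  if (is.nan(chisq)) {
    # complete within-block ties (e.g. identical columns): the statistic's
    # limit is 0 and there is no evidence of any difference
    chisq <- 0
    p <- 1
  }
  out <- list(friedman = data.frame(chisq = chisq,
                                    df = unname(ft$parameter),
                                    p = p, n = nrow(m)),
              pairwise = NULL)
  if (!is.na(p) && p <= alpha) {
    cn <- colnames(m)
    if (is.null(cn)) cn <- paste0("cond", seq_len(ncol(m)))
    pairs <- utils::combn(ncol(m), 2)
    out$pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      wt <- suppressWarnings(stats::wilcox.test(m[, i1], m[, i2],
                                                paired = TRUE,
                                                exact = nrow(m) < 26))
      data.frame(cond1 = cn[i1], cond2 = cn[i2],
                 W = unname(wt$statistic), p = wt$p.value)
    }))
  }
  out
}

#' Random-intercept linear mixed model with sum-coded contrasts
#'
#' Fits a Gaussian mixed model by REML with a random intercept per subject
#' and sum-coded contrasts on all factor predictors, returning fixed-effect
#' estimates with Satterthwaite-approximated degrees of freedom and
#' Bonferroni-adjusted p-values per family of tested contrasts.
#'
#' @param data Long data.frame.
#' @param outcome Outcome column name.
#' @param fixed Character vector of fixed-effect terms (may include
#'   interactions, e.g. `"arm * daytime"`).
#' @param subject Grouping column for the random intercept (default
#'   `"subject"`).
#' @param m Bonferroni family size; defaults to the number of
#'   non-intercept fixed-effect rows.
#' @return A data.frame (one row per fixed effect): `term`, `estimate`,
#'   `se`, `df`, `t`, `p`, `p_bonferroni`; the fitted model is attached as
#'   the `"model"` attribute.
#' @export
fit_random_intercept_lmm <- function(data, outcome, fixed, subject = "subject",
                                     m = NULL) {
  stopifnot(outcome %in% names(data), subject %in% names(data))
  data <- as.data.frame(data)
  data[[subject]] <- factor(data[[subject]])
  # sum-code every factor predictor
  fvars <- names(data)[vapply(data, function(c) is.character(c) || is.factor(c),
                              logical(1))]
  fvars <- setdiff(fvars, subject)
  for (v in fvars) {
    data[[v]] <- factor(data[[v]])
    if (nlevels(data[[v]]) >= 2) {
      stats::contrasts(data[[v]]) <- stats::contr.sum(nlevels(data[[v]]))
    }
  }
  fml <- stats::as.formula(paste(outcome, "~", paste(fixed, collapse = " + "),
                                 "+ (1 |", subject, ")"))
  fit <- lmerTest::lmer(fml, data = data, REML = TRUE)
  if (lme4::isSingular(fit, tol = 1e-5)) {
    message("random-intercept variance is (near) zero; fixed effects match OLS")
  }
  co <- stats::coef(summary(fit))
  res <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                    se = co[, "Std. Error"], df = co[, "df"],
                    t = co[, "t value"], p = co[, "Pr(>|t|)"],
                    row.names = NULL)
  if (is.null(m)) m <- max(1, nrow(res) - 1)
  res$p_bonferroni <- pmin(1, res$p * m)
  attr(res, "model") <- fit
  res
}

#' Bonferroni adjustment
#'
#' @param p P-values.
#' @param m Family size (default `length(p)`).
#' @return Adjusted p-values, capped at 1.
#' @export
bonferroni <- function(p, m = length(p)) pmin(1, p * m)
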