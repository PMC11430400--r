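# Salivary marker computations: flow-rate-independent secretion and
# circadian time-of-day binning.

#' Salivary secretion from concentration and sample weight
#'
#' The salivary flow rate is the sample weight (grams, saliva density
#' 1 g/mL) divided by the collection duration; secretion is concentration
#' times flow rate (U/mL x mL/min = U/min), which removes the influence of
#' salivary flow on the concentration measure.
#'
#' @param concentration Concentration (U/mL for alpha-amylase).
#' @param sample_weight_g Sample weight (g) over the collection.
#' @param collection_duration_min Collection duration (min, default 2).
#' @return Secretion (U/min); `NA` (flagged via the `"missing"` attribute)
#'   where the weight is missing.
#' @export
compute_secretion <- function(concentration, sample_weight_g,
                              collection_duration_min = 2) {
  stopifnot(all(collection_duration_min > 0, na.rm = TRUE))
  flow <- sample_weight_g / collection_duration_min
  out <- concentration * flow
  miss <- which(is.na(sample_weight_g))
  if (length(miss)) attr(out, "missing") <- miss
  out
}

#' Assign saliva collection times to circadian bins
#'
#' Bins: morning 07:30-10:30, midday 10:35-13:35, afternoon 13:40-16:30
#' (inclusive bounds as printed). Times falling in the 5-minute gaps
#' between printed bins are assigned to the later bin; times outside
#' 07:30-16:30 are flagged unbinned (`NA`).
#'
#' @param clock_time Times as `"HH:MM"` strings or decimal hours.
#' @return A factor with levels `morning`, `midday`, `afternoon`; `NA` for
#'   out-of-range times.
#' @export
assign_daytime_bin <- function(clock_time) {
  h <- parse_clock_hours(clock_time)
  bin <- rep(NA_character_, length(h))
  bin[h >= 7.5 & h <= 10.5] <- "morning"
  bin[h > 10.5 & h <= 13 + 35 / 60] <- "midday"
  bin[h > 13 + 35 / 60 & h <= 16.5] <- "afternoon"
  factor(bin, levels = c("morning", "midday", "afternoon"))
}
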