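#' Binocular pupil recording container
#'
#' Holds a timestamped binocular pupil-diameter trace with per-eye tracker
#' confidence, the raw substrate for both the resting-pupil and the
#' pupillary-light-reflex pipelines. Diameters are in millimetres, time in
#' seconds, confidence in \code{[0, 1]}.
#'
#' @param time Numeric vector of timestamps (s), strictly increasing.
#' @param left,right Numeric vectors of pupil diameters (mm), same length as
#'   `time`.
#' @param left_conf,right_conf Tracker confidence per sample in `[0, 1]`.
#' @param rate Nominal sampling rate in Hz.
#' @return An object of class `pupil_recording`.
#' @export
pupil_recording <- function(time, left, right,
                            left_conf = rep(1, length(time)),
                            right_conf = rep(1, length(time)),
                            rate) {
  n <- length(time)
  stopifnot(length(left) == n, length(right) == n,
            length(left_conf) == n, length(right_conf) == n, rate > 0)
  structure(
    list(time = as.numeric(time),
         eyes = list(
           left = list(diameter = as.numeric(left), confidence = as.numeric(left_conf)),
           right = list(diameter = as.numeric(right), confidence = as.numeric(right_conf))),
         rate = rate),
    class = "pupil_recording")
}

#' @export
print.pupil_recording <- function(x, ...) {
  cat(sprintf("<pupil_recording> %d samples @ %g Hz (%.1f s), eyes: left/right\n",
              length(x$time), x$rate, diff(range(x$time))))
  invisible(x)
}

#' Write a pupil recording to CSV (long format)
#'
#' Columns: `timestamp_s`, `eye`, `diameter_mm`, `confidence` — the layout
#' the readers of this package accept.
#'
#' @param rec A [pupil_recording()].
#' @param path Output file path.
#' @export
write_pupil_csv <- function(rec, path) {
  stopifnot(inherits(rec, "pupil_recording"))
  long <- do.call(rbind, lapply(c("left", "right"), function(eye) {
    data.frame(timestamp_s = rec$time, eye = eye,
               diameter_mm = rec$eyes[[eye]]$diameter,
               confidence = rec$eyes[[eye]]$confidence)
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read a pupil recording from CSV (long format)
#'
#' @param path CSV with columns `timestamp_s`, `eye`, `diameter_mm`,
#'   `confidence`.
#' @param rate Sampling rate in Hz; if `NULL`, estimated from the median
#'   timestamp step.
#' @return A [pupil_recording()].
#' @export
read_pupil_csv <- function(path, rate = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp_s", "eye", "diameter_mm", "confidence")
  if (!all(need %in% names(df))) {
    stop("pupil CSV must have columns: ", paste(need, collapse = ", "))
  }
  l <- df[df$eye == "left", ]
  r <- df[df$eye == "right", ]
  l <- l[order(l$timestamp_s), ]
  r <- r[order(r$timestamp_s), ]
  if (is.null(rate)) rate <- 1 / stats::median(diff(l$timestamp_s))
  pupil_recording(l$timestamp_s, l$diameter_mm, r$diameter_mm,
                  l$confidence, r$confidence, rate = rate)
}
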