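# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG state
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state on
#' exit, so generators take one explicit integer seed and leave no hidden
#' global state behind.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Centered rolling mean with shrinking windows at the edges. For an even
# window the centre is offset left by half a sample (floor((w-1)/2) samples
# before, the rest after), matching the usual convention.
rollmean_shrink <- function(x, width) {
  stopifnot(width >= 1)
  n <- length(x)
  if (width == 1 || n == 0) return(x)
  half_l <- floor((width - 1) / 2)
  half_r <- width - 1 - half_l
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - half_l)
  hi <- pmin(n, i + half_r)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Sample from an ex-Gaussian distribution (Gaussian + independent
# exponential), the standard descriptive model for response times.
rexgauss <- function(n, mu, sigma, tau) {
  stats::rnorm(n, mean = mu, sd = sigma) + stats::rexp(n, rate = 1 / tau)
}

# Merge overlapping/touching intervals given as a 2-column matrix
# (onset, offset); returns a matrix sorted by onset.
merge_intervals <- function(intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("onset", "offset"))))
  }
  ord <- order(intervals[, 1])
  intervals <- intervals[ord, , drop = FALSE]
  out <- intervals[1, , drop = FALSE]
  if (nrow(intervals) > 1) {
    for (i in 2:nrow(intervals)) {
      k <- nrow(out)
      if (intervals[i, 1] <= out[k, 2]) {
        out[k, 2] <- max(out[k, 2], intervals[i, 2])
      } else {
        out <- rbind(out, intervals[i, , drop = FALSE])
      }
    }
  }
  colnames(out) <- c("onset", "offset")
  out
}

# Logical run-length encoding: start/end indices of TRUE runs.
true_runs <- function(flag) {
  if (!any(flag)) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# Parse "HH:MM" clock strings (or pass numeric hours through) to decimal hours.
parse_clock_hours <- function(x) {
  if (is.numeric(x)) return(x)
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    as.numeric(p[1]) + as.numeric(p[2]) / 60 + if (length(p) > 2) as.numeric(p[3]) / 3600 else 0
  }, numeric(1))
}
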