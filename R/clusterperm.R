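# One-sample, two-tailed spatio-temporal cluster-based permutation test.
# Candidate clusters are connected components of supra-threshold,
# same-signed t-values under temporal adjacency (consecutive samples) plus
# channel adjacency at equal time; the max-|cluster mass| statistic over
# subject-wise sign flips provides family-wise control.

# Connected components of candidate cells (one sign) on the channel x time
# grid. Cells are flattened channel-fastest: cell = ch + (t - 1) * n_ch.
cluster_components_idx <- function(idx, n_ch, n_t, neighbors) {
  if (length(idx) == 0) return(list())
  n_cells <- n_ch * n_t
  inset <- logical(n_cells)
  inset[idx] <- TRUE
  visited <- logical(n_cells)
  comps <- list()
  for (s in idx) {
    if (visited[s]) next
    visited[s] <- TRUE
    stack <- s
    members <- integer(0)
    while (length(stack) > 0) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      members <- c(members, cur)
      ch <- ((cur - 1L) %% n_ch) + 1L
      tt <- ((cur - 1L) %/% n_ch) + 1L
      cand <- integer(0)
      if (tt > 1L) cand <- c(cand, cur - n_ch)
      if (tt < n_t) cand <- c(cand, cur + n_ch)
      if (length(neighbors) >= ch && length(neighbors[[ch]]) > 0) {
        cand <- c(cand, neighbors[[ch]] + (tt - 1L) * n_ch)
      }
      cand <- cand[inset[cand] & !visited[cand]]
      if (length(cand) > 0) {
        visited[cand] <- TRUE
        stack <- c(stack, cand)
      }
    }
    comps[[length(comps) + 1L]] <- members
  }
  comps
}

# Maximum absolute cluster mass of one t-map (both signs).
max_cluster_mass <- function(tvec, thr, n_ch, n_t, neighbors) {
  best <- 0
  for (sign_dir in c(1, -1)) {
    idx <- if (sign_dir > 0) which(tvec > thr) else which(tvec < -thr)
    comps <- cluster_components_idx(idx, n_ch, n_t, neighbors)
    for (m in comps) {
      mass <- abs(sum(tvec[m]))
      if (mass > best) best <- mass
    }
  }
  best
}

#' One-sample two-tailed cluster-based permutation test
#'
#' Computes a per-datapoint one-sample t statistic across subjects, forms
#' candidate clusters from supra-threshold datapoints of equal sign
#' (connected through consecutive time samples and neighboring channels at
#' equal time), and compares each cluster's mass (summed t) against the
#' distribution of the maximum absolute cluster mass under random
#' subject-wise sign flips.
#'
#' @param data Numeric array `subjects x channels x times`, or a matrix
#'   `subjects x times` for single-channel (e.g. pupil) data.
#' @param adjacency A [build_adjacency()] result, or `NULL` for no channel
#'   neighbors.
#' @param n_permutations Number of random sign flips (default 1000).
#' @param alpha Significance level of the test (default 0.05).
#' @param threshold Cluster-forming threshold on |t|; defaults to the
#'   parametric two-sided t critical value at `alpha` with `n - 1` df.
#' @param seed Integer seed for the sign flips.
#' @return An object of class `cluster_result`: `clusters` (data.frame
#'   with `id`, `sign`, `mass`, `n_members`, `p`, `significant`),
#'   `members` (list of two-column matrices channel/time per cluster),
#'   `t_map` (channels x times), `threshold_t`, `null_max`,
#'   `n_permutations`, `alpha`, `tail = "two-sided"`.
#' @export
cluster_permutation_test <- function(data, adjacency = NULL,
                                     n_permutations = 1000, alpha = 0.05,
                                     threshold = NULL, seed = 1L) {
  if (is.matrix(data)) data <- array(data, dim = c(nrow(data), 1L, ncol(data)))
  stopifnot(length(dim(data)) == 3)
  n <- dim(data)[1]
  n_ch <- dim(data)[2]
  n_t <- dim(data)[3]
  if (n <= 2) stop("at least 3 subjects are required (t undefined otherwise)")
  if (!all(is.finite(data))) stop("data must be finite")
  neighbors <- if (is.null(adjacency)) {
    rep(list(integer(0)), n_ch)
  } else {
    stopifnot(inherits(adjacency, "channel_adjacency"))
    if (length(adjacency$neighbors) > 0 && length(adjacency$neighbors) != n_ch) {
      stop("adjacency has ", length(adjacency$neighbors),
           " channels but data has ", n_ch)
    }
    if (length(adjacency$neighbors) == 0) rep(list(integer(0)), n_ch)
    else adjacency$neighbors
  }
  if (is.null(threshold)) threshold <- stats::qt(1 - alpha / 2, df = n - 1)

  n_cells <- n_ch * n_t
  X <- matrix(data, nrow = n, ncol = n_cells)  # cell = ch + (t-1)*n_ch
  ss <- colSums(X^2)

  obs_mean <- colMeans(X)
  obs_var <- (ss - n * obs_mean^2) / (n - 1)
  obs_t <- obs_mean / sqrt(pmax(obs_var, .Machine$double.eps) / n)

  clusters <- list()
  members <- list()
  for (sign_dir in c(1, -1)) {
    idx <- if (sign_dir > 0) which(obs_t > threshold) else which(obs_t < -threshold)
    comps <- cluster_components_idx(idx, n_ch, n_t, neighbors)
    for (m in comps) {
      clusters[[length(clusters) + 1L]] <-
        data.frame(sign = sign_dir, mass = sum(obs_t[m]),
                   n_members = length(m))
      members[[length(members) + 1L]] <-
        cbind(channel = ((m - 1L) %% n_ch) + 1L,
              time = ((m - 1L) %/% n_ch) + 1L)
    }
  }

  # permutation null: max |cluster mass| under subject-wise sign flips,
  # computed in chunks; t denominators reuse the flip-invariant sum of
  # squares (sum x^2 is unchanged by per-subject sign flips)
  null_max <- numeric(n_permutations)
  with_seed(seed, {
    chunk <- 250L
    done <- 0L
    while (done < n_permutations) {
      k <- min(chunk, n_permutations - done)
      S <- matrix(sample(c(-1, 1), k * n, replace = TRUE), nrow = k)
      M <- (S %*% X) / n
      Vden <- sqrt(pmax(sweep(-n * M^2, 2, ss, `+`), .Machine$double.eps) /
                     ((n - 1) * n))
      Tm <- M / Vden
      for (i in seq_len(k)) {
        null_max[done + i] <- max_cluster_mass(Tm[i, ], threshold,
                                               n_ch, n_t, neighbors)
      }
      done <- done + k
    }
  })

  if (length(clusters) > 0) {
    cl <- do.call(rbind, clusters)
    cl$id <- seq_len(nrow(cl))
    cl$p <- vapply(cl$mass, function(m) {
      # tolerance so flips reproducing the observed labeling count as ties
      tol <- 1e-8 * max(1, abs(m))
      (1 + sum(null_max >= abs(m) - tol)) / (n_permutations + 1)
    }, numeric(1))
    cl$significant <- cl$p <= alpha
    cl <- cl[, c("id", "sign", "mass", "n_members", "p", "significant")]
  } else {
    cl <- data.frame(id = integer(0), sign = numeric(0), mass = numeric(0),
                     n_members = integer(0), p = numeric(0),
                     significant = logical(0))
  }
  structure(list(clusters = cl, members = members,
                 t_map = matrix(obs_t, n_ch, n_t),
                 threshold_t = threshold, null_max = null_max,
                 n_permutations = n_permutations, alpha = alpha,
                 tail = "two-sided"),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), threshold |t| > %.3f, %d permutations, alpha = %g\n",
              nrow(x$clusters), x$threshold_t, x$n_permutations, x$alpha))
  if (nrow(x$clusters) > 0) print(x$clusters)
  invisible(x)
}

#' Write a cluster table to TSV
#'
#' Emits one row per cluster member with the cluster id, sign, mass and
#' p-value alongside the member's channel/time coordinates.
#'
#' @param result A `cluster_result`.
#' @param path Output TSV path.
#' @param channel_labels Optional channel labels.
#' @export
write_cluster_tsv <- function(result, path, channel_labels = NULL) {
  rows <- list()
  for (i in seq_len(nrow(result$clusters))) {
    m <- result$members[[i]]
    ch <- if (!is.null(channel_labels)) channel_labels[m[, "channel"]] else m[, "channel"]
    rows[[i]] <- data.frame(cluster = i, channel = ch, time_index = m[, "time"],
                            sign = result$clusters$sign[i],
                            mass = result$clusters$mass[i],
                            p = result$clusters$p[i])
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(0), channel = character(0),
               time_index = integer(0), sign = numeric(0), mass = numeric(0),
               p = numeric(0))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
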