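# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities with naive implementations so the tests never share
# code paths with the package functions they check.

# Exact signed-rank null: p-value of the two-sided Wilcoxon signed-rank
# statistic by full enumeration of the 2^n sign assignments of the ranks.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_null <- as.numeric(signs %*% r)
  ev <- n * (n + 1) / 4
  mean(abs(v_null - ev) >= abs(v_obs - ev))
}

# Friedman chi-square statistic from first principles (within-subject ranks).
oracle_friedman_chisq <- function(m) {
  ranks <- t(apply(m, 1, rank))
  n <- nrow(m); k <- ncol(m)
  12 / (n * k * (k + 1)) * sum(colSums(ranks)^2) - 3 * n * (k + 1)
}

# Exact permutation p of the Friedman statistic by enumerating all (k!)^n
# within-subject orderings (small n and k only).
oracle_friedman_exact_p <- function(m) {
  n <- nrow(m); k <- ncol(m)
  perms <- gtools_permutations(k)
  obs <- oracle_friedman_chisq(m)
  idx <- rep(1L, n)
  total <- nrow(perms)^n
  count <- 0L
  for (code in seq_len(total) - 1L) {
    x <- code
    mm <- m
    for (i in seq_len(n)) {
      p <- perms[(x %% nrow(perms)) + 1L, ]
      x <- x %/% nrow(perms)
      mm[i, ] <- m[i, p]
    }
    if (oracle_friedman_chisq(mm) >= obs - 1e-9) count <- count + 1L
  }
  count / total
}

# All permutations of 1..k (tiny k), no external dependency.
gtools_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(k - 1)
  out <- NULL
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# Naive connected-component max cluster mass on a channels x time t-map
# (temporal neighbors plus channel neighbors at equal time, same sign).
oracle_max_cluster_mass <- function(tmat, thr, nb) {
  n_ch <- nrow(tmat); n_t <- ncol(tmat)
  best <- 0
  for (sgn in c(1, -1)) {
    flag <- if (sgn > 0) tmat > thr else tmat < -thr
    lab <- matrix(0L, n_ch, n_t); cur <- 0L
    for (c0 in seq_len(n_ch)) for (t0 in seq_len(n_t)) {
      if (!flag[c0, t0] || lab[c0, t0] > 0) next
      cur <- cur + 1L
      queue <- list(c(c0, t0)); lab[c0, t0] <- cur
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        cand <- list(c(p[1], p[2] - 1L), c(p[1], p[2] + 1L))
        for (ch2 in nb[[p[1]]]) cand <- c(cand, list(c(ch2, p[2])))
        for (q in cand) {
          if (q[2] >= 1 && q[2] <= n_t && flag[q[1], q[2]] && lab[q[1], q[2]] == 0) {
            lab[q[1], q[2]] <- cur; queue <- c(queue, list(q))
          }
        }
      }
    }
    if (cur > 0) {
      for (kk in seq_len(cur)) best <- max(best, abs(sum(tmat[lab == kk])))
    }
  }
  best
}

# One-sample t per cell for a subjects x cells matrix.
oracle_t <- function(X) {
  m <- colMeans(X); s <- apply(X, 2, stats::sd)
  m / (s / sqrt(nrow(X)))
}
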