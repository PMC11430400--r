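# Cluster-based permutation inference: adjacency geometry, exact oracle
# equivalence, effect localization and symmetry invariants.

test_that("adjacency handles degenerate and standard montages", {
  expect_length(build_adjacency(NULL)$neighbors, 0)
  one <- data.frame(label = "a", x = 0, y = 0, z = 0)
  expect_equal(nrow(build_adjacency(one)$pairs), 0)
  two <- data.frame(label = c("a", "b"), x = c(0, 0), y = 0, z = 0)
  expect_equal(nrow(build_adjacency(two)$pairs), 1)
  dup <- data.frame(label = c("a", "a"), x = c(0, 1), y = 0, z = 0)
  expect_error(build_adjacency(dup), "duplicate")
  mont <- standard_montage_64()
  expect_equal(nrow(mont), 64)
  adj <- build_adjacency(mont)
  expect_true(all(lengths(adj$neighbors) >= 2))
  # symmetry: i in neighbors(j) <=> j in neighbors(i)
  for (i in seq_along(adj$neighbors)) {
    for (j in adj$neighbors[[i]]) expect_true(i %in% adj$neighbors[[j]])
  }
})

test_that("all-zero data yields no supra-threshold datapoints", {
  x <- array(0, dim = c(5, 2, 10))
  res <- cluster_permutation_test(x, n_permutations = 100, seed = 1)
  expect_equal(nrow(res$clusters), 0)
  expect_error(cluster_permutation_test(array(0, dim = c(2, 2, 4))), "3 subjects")
})

test_that("permutation p-values match the exhaustive sign-flip oracle at n = 5", {
  set.seed(42)
  n <- 5; n_ch <- 2; n_t <- 6
  x <- array(rnorm(n * n_ch * n_t, mean = 0.8), dim = c(n, n_ch, n_t))
  pos <- data.frame(label = c("a", "b"), x = c(0, 0.01), y = 0, z = 0)
  adj <- build_adjacency(pos)
  res <- cluster_permutation_test(x, adj, n_permutations = 10000, seed = 9)
  expect_gt(nrow(res$clusters), 0)
  thr <- res$threshold_t
  X <- matrix(x, n)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  null_exact <- apply(signs, 1, function(s) {
    tv <- oracle_t(s * X)
    oracle_max_cluster_mass(matrix(tv, n_ch, n_t), thr, adj$neighbors)
  })
  p_exact <- vapply(res$clusters$mass,
                    function(m) mean(null_exact >= abs(m) - 1e-9), numeric(1))
  expect_true(all(abs(res$clusters$p - p_exact) < 0.02))
})

test_that("observed cluster masses match a brute-force component search", {
  set.seed(7)
  x <- array(rnorm(8 * 4 * 12), dim = c(8, 4, 12))
  x[, 2:3, 4:8] <- x[, 2:3, 4:8] + 1.5
  pos <- data.frame(label = letters[1:4], x = c(0, 0.01, 0.02, 0.5), y = 0, z = 0)
  adj <- build_adjacency(pos, radius = 0.015)
  res <- cluster_permutation_test(x, adj, n_permutations = 200, seed = 3)
  tv <- oracle_t(matrix(x, 8))
  expect_equal(max(abs(res$clusters$mass)),
               oracle_max_cluster_mass(matrix(tv, 4, 12), res$threshold_t,
                                       adj$neighbors))
})

test_that("an injected effect is detected and localized", {
  g <- gen_eeg_epochs(20, 8, 40, effect_window = list(channels = 2:6, times = 10:29),
                      effect_size = 2.0, seed = 11)
  mont <- standard_montage_64()[1:8, ]
  adj <- build_adjacency(mont)
  res <- cluster_permutation_test(g$data, adj, n_permutations = 500, seed = 12)
  sig <- res$clusters[res$clusters$significant, ]
  expect_gte(nrow(sig), 1)
  big <- which.max(abs(res$clusters$mass))
  mem <- res$members[[big]]
  truth_cells <- which(g$truth)
  mem_cells <- (mem[, "time"] - 1) * 8 + mem[, "channel"]
  coverage <- mean(truth_cells %in% mem_cells)
  expect_gte(coverage, 0.5)
})

test_that("p-values are bounded below by 1/(n_permutations + 1)", {
  g <- gen_eeg_epochs(15, 4, 20, effect_window = list(channels = 1:4, times = 1:20),
                      effect_size = 3, seed = 13)
  res <- cluster_permutation_test(g$data, n_permutations = 200, seed = 14)
  expect_true(all(res$clusters$p >= 1 / 201))
  expect_true(all(res$clusters$p <= 1))
})

test_that("global sign flip mirrors cluster signs with identical p-values", {
  g <- gen_eeg_epochs(12, 3, 15, effect_window = list(channels = 1:2, times = 5:10),
                      effect_size = 1.5, seed = 15)
  r1 <- cluster_permutation_test(g$data, n_permutations = 300, seed = 16)
  r2 <- cluster_permutation_test(-g$data, n_permutations = 300, seed = 16)
  o1 <- order(-abs(r1$clusters$mass))
  o2 <- order(-abs(r2$clusters$mass))
  expect_equal(r1$clusters$mass[o1], -r2$clusters$mass[o2])
  expect_equal(r1$clusters$p[o1], r2$clusters$p[o2])
})

test_that("channel relabeling leaves masses and p-values unchanged", {
  set.seed(17)
  x <- array(rnorm(10 * 4 * 10, mean = 0.5), dim = c(10, 4, 10))
  pos <- data.frame(label = letters[1:4],
                    x = c(0, 0.01, 0.02, 0.03), y = 0, z = 0)
  adj <- build_adjacency(pos, radius = 0.012)
  perm <- c(3, 1, 4, 2)
  xp <- x[, perm, ]
  adj_p <- build_adjacency(pos[perm, ], radius = 0.012)
  r1 <- cluster_permutation_test(x, adj, n_permutations = 400, seed = 18)
  r2 <- cluster_permutation_test(xp, adj_p, n_permutations = 400, seed = 18)
  expect_equal(sort(r1$clusters$mass), sort(r2$clusters$mass))
  expect_equal(sort(r1$clusters$p), sort(r2$clusters$p))
})

test_that("single-channel (pupil) matrices are accepted with empty adjacency", {
  set.seed(19)
  mat <- matrix(rnorm(8 * 30), 8, 30)
  res <- cluster_permutation_test(mat, n_permutations = 200, seed = 20)
  expect_s3_class(res, "cluster_result")
  expect_equal(nrow(res$t_map), 1)
})
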