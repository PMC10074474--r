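# build an array whose per-cell t map is fully controlled: every cell holds
# near-constant values across participants so t is 0 (mean 0) or huge
controlled_array <- function(n, nf, nt, hot, signs = NULL) {
  x <- array(0, c(n, nf, nt))
  for (k in seq_len(nrow(hot))) {
    s <- if (is.null(signs)) 1 else signs[k]
    x[, hot[k, 1], hot[k, 2]] <- s * (5 + seq_len(n) / 100)  # mean>>sd
  }
  x
}

test_that("all-zero differences form no clusters", {
  x <- array(0, c(6, 4, 5))
  fc <- form_clusters(x)
  expect_equal(nrow(fc$clusters), 0)
  expect_true(all(fc$tmap == 0))
  ct <- cluster_test(x, n_permutations = 100, seed = 1)
  expect_equal(min_cluster_p(ct), 1)
})

test_that("one isolated supra-threshold cell is a size-1 cluster with t-sum = t", {
  x <- controlled_array(6, 4, 5, hot = matrix(c(2, 3), 1))
  fc <- form_clusters(x)
  expect_equal(nrow(fc$clusters), 1)
  expect_equal(fc$clusters$n_cells, 1L)
  tt <- t.test(x[, 2, 3])$statistic
  expect_equal(fc$clusters$tsum, unname(tt), tolerance = 1e-10)
  expect_equal(unname(which(fc$labels == 1, arr.ind = TRUE)[1, ]), c(2, 3))
})

test_that("diagonal neighbours are separate clusters under 4-adjacency", {
  hot <- matrix(c(1, 1, 2, 2), 2, byrow = TRUE)
  x <- controlled_array(6, 3, 3, hot)
  fc <- form_clusters(x)
  expect_equal(nrow(fc$clusters), 2)   # diagonals are not adjacent
  # making them orthogonal neighbours merges them
  hot2 <- matrix(c(1, 1, 2, 1), 2, byrow = TRUE)
  fc2 <- form_clusters(controlled_array(6, 3, 3, hot2))
  expect_equal(nrow(fc2$clusters), 1)
  expect_equal(fc2$clusters$n_cells, 2L)
})

test_that("opposite-sign neighbours never join a cluster", {
  hot <- matrix(c(2, 2, 2, 3), 2, byrow = TRUE)
  x <- controlled_array(6, 4, 5, hot, signs = c(1, -1))
  fc <- form_clusters(x)
  expect_equal(nrow(fc$clusters), 2)
  expect_setequal(fc$clusters$sign, c(1L, -1L))
})

test_that("observed clustering agrees with an independent BFS oracle", {
  set.seed(14)
  x <- array(rnorm(10 * 8 * 12, mean = 0.4), c(10, 8, 12))
  fc <- form_clusters(x)
  oracle <- sort(oracle_cluster_sums(oracle_tmap(x), fc$tcrit))
  expect_equal(sort(fc$clusters$tsum), oracle, tolerance = 1e-10)
})

test_that("the permutation test is deterministic and negation-symmetric", {
  set.seed(2)
  x <- array(rnorm(8 * 5 * 9, mean = 0.5), c(8, 5, 9))
  a <- cluster_test(x, n_permutations = 500, seed = 42)
  b <- cluster_test(x, n_permutations = 500, seed = 42)
  expect_identical(a$clusters, b$clusters)
  expect_identical(a$perm_max, b$perm_max)
  neg <- cluster_test(-x, n_permutations = 500, seed = 42)
  expect_equal(neg$clusters$tsum, -a$clusters$tsum, tolerance = 1e-12)
  expect_equal(neg$clusters$sign, -a$clusters$sign)
  expect_identical(neg$clusters$p, a$clusters$p)
  expect_identical(neg$perm_max, a$perm_max)
})

test_that("p values are invariant under transposing the time-frequency grid", {
  set.seed(5)
  x <- array(rnorm(7 * 6 * 10, mean = 0.5), c(7, 6, 10))
  a <- cluster_test(x, n_permutations = 400, seed = 9)
  b <- cluster_test(aperm(x, c(1, 3, 2)), n_permutations = 400, seed = 9)
  expect_equal(sort(a$clusters$tsum), sort(b$clusters$tsum), tolerance = 1e-12)
  expect_equal(a$clusters$p[order(a$clusters$tsum)],
               b$clusters$p[order(b$clusters$tsum)])
})

test_that("extreme effects floor the p value at 1/n_permutations", {
  # n large enough that the identity/all-flip sign patterns (which tie the
  # observed statistic exactly) are essentially never drawn
  set.seed(6)
  x <- array(5 + rnorm(20 * 4 * 6, sd = 0.2), c(20, 4, 6))
  ct <- cluster_test(x, n_permutations = 1000, seed = 3)
  expect_equal(min_cluster_p(ct), 1 / 1000)
  ct1 <- cluster_test(x, n_permutations = 1000, seed = 3, plus_one = TRUE)
  expect_equal(min_cluster_p(ct1), 1 / 1001)
})

test_that("degenerate inputs are rejected", {
  expect_error(form_clusters(array(0, c(1, 3, 3))), "2 participants")
  x <- array(0, c(4, 3, 3)); x[1, 1, 1] <- NA
  expect_error(form_clusters(x), "undefined")
  expect_error(cluster_test(array(rnorm(36), c(4, 3, 3)), n_permutations = 0),
               "at least 1")
})

test_that("Monte-Carlo p matches exhaustive enumeration for 5 participants", {
  set.seed(11)
  x <- array(rnorm(5 * 4 * 5, mean = 0.9), c(5, 4, 5))
  oracle <- oracle_exact_p(x)
  exact <- cluster_test_exact(x)
  expect_equal(sort(exact$clusters$tsum), sort(oracle$obs), tolerance = 1e-10)
  expect_equal(exact$clusters$p[order(exact$clusters$tsum)],
               oracle$p[order(oracle$obs)], tolerance = 1e-12)
  mc <- cluster_test(x, n_permutations = 10000, seed = 21)
  for (k in seq_len(nrow(mc$clusters))) {
    p_ex <- exact$clusters$p[k]
    se <- sqrt(p_ex * (1 - p_ex) / 10000)
    expect_lt(abs(mc$clusters$p[k] - p_ex), max(2 * se, 2 / 10000))
  }
})

test_that("the family-wise false-positive rate is near nominal under the null", {
  set.seed(33)
  reps <- 200
  hits <- 0
  for (r in seq_len(reps)) {
    x <- array(rnorm(20 * 10 * 50), c(20, 10, 50))
    ct <- cluster_test(x, n_permutations = 1000, seed = 1000 + r)
    if (min_cluster_p(ct) < 0.05) hits <- hits + 1
  }
  rate <- hits / reps
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
})
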