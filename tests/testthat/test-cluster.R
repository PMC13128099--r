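test_that("dtw satisfies its closed-form identities", {
  set.seed(1)
  S <- matrix(rnorm(12), 4, 3)
  expect_equal(dtw_distance(S, S), 0)
  # single admissible path for length-1 sequences
  a <- matrix(rnorm(3), 1); b <- matrix(rnorm(3), 1)
  expect_equal(dtw_distance(a, b), sqrt(sum((a - b)^2)))
  # a repeated point can be absorbed at zero cost
  expect_equal(dtw_distance(c(1, 2, 3), c(1, 2, 2, 3)), 0)
  expect_error(dtw_distance(matrix(0, 0, 1), a), "empty")
  expect_error(dtw_distance(matrix(0, 2, 2), matrix(0, 2, 3)), "dimensions")
})

test_that("dtw path satisfies the warping-path invariants", {
  set.seed(2)
  a <- matrix(rnorm(10), 5, 2); b <- matrix(rnorm(8), 4, 2)
  res <- dtw_distance(a, b, return_path = TRUE)
  p <- res$path
  expect_equal(p[1, ], c(1, 1))
  expect_equal(p[nrow(p), ], c(5, 4))
  steps <- diff(p)
  expect_true(all(steps >= 0 & steps <= 1))
  expect_true(all(rowSums(steps) >= 1))
  # path cost equals the reported distance
  cost <- sum(vapply(seq_len(nrow(p)), function(l) {
    sqrt(sum((a[p[l, 1], ] - b[p[l, 2], ])^2))
  }, numeric(1)))
  expect_equal(cost, res$distance)
})

test_that("dtw equals exhaustive warping-path enumeration and is symmetric", {
  set.seed(3)
  for (rep in 1:60) {
    n <- sample(1:6, 1); m <- sample(1:6, 1); d <- sample(1:3, 1)
    a <- matrix(rnorm(n * d), n, d)
    b <- matrix(rnorm(m * d), m, d)
    expect_equal(dtw_distance(a, b), dtw_bruteforce(a, b), tolerance = 1e-12)
    expect_equal(dtw_distance(a, b), dtw_distance(b, a))
    expect_gte(dtw_distance(a, b), 0)
  }
})

# two tight bundles of sequences around distinct level patterns
planted_bundles <- function(n_per, noise = 0.05, seed = 4) {
  set.seed(seed)
  centers <- list(c(0, 0), c(3, -3))
  seqs <- list(); truth <- integer(0)
  for (g in 1:2) {
    for (i in seq_len(n_per)) {
      len <- sample(6:10, 1)
      seqs[[length(seqs) + 1L]] <-
        matrix(rep(centers[[g]], each = len), len) +
        matrix(rnorm(len * 2, sd = noise), len)
      truth <- c(truth, g)
    }
  }
  names(seqs) <- sprintf("S%02d", seq_along(seqs))
  list(seqs = seqs, truth = truth)
}

test_that("ts_kmeans recovers planted bundles and is seeded-deterministic", {
  pb <- planted_bundles(12)
  km1 <- ts_kmeans(pb$seqs, K = 2, seed = 11)
  km2 <- ts_kmeans(pb$seqs, K = 2, seed = 11)
  expect_identical(km1$cluster, km2$cluster)
  expect_equal(km1$objective, km2$objective)
  expect_equal(mclust::adjustedRandIndex(km1$cluster, pb$truth), 1)
  # objective history is non-increasing
  expect_true(all(diff(km1$history) <= 1e-9))
})

test_that("K equal to the number of sequences drives the objective to zero", {
  pb <- planted_bundles(3)
  km <- ts_kmeans(pb$seqs, K = length(pb$seqs), seed = 2, n_init = 2)
  expect_equal(km$objective, 0)
})

test_that("silhouette behaves at its extremes and matches the precomputed-matrix path", {
  pb <- planted_bundles(8, noise = 0)   # exact duplicates within groups
  ss <- silhouette_dtw(pb$seqs, pb$truth)
  expect_equal(ss, 1)
  # random labels on homogeneous data hover near zero
  set.seed(9)
  flat <- lapply(1:40, function(i) matrix(rnorm(16, sd = 1), 8, 2))
  lab <- sample(1:2, 40, replace = TRUE)
  expect_lt(abs(silhouette_dtw(flat, lab)), 0.15)
  # precomputed distance matrix equals on-the-fly computation
  D <- dtw_pairwise(pb$seqs)
  expect_equal(silhouette_dtw(NULL, pb$truth, distmat = D),
               silhouette_dtw(pb$seqs, pb$truth))
  expect_error(silhouette_dtw(pb$seqs, rep(1, length(pb$seqs))),
               "two clusters")
})

test_that("davies-bouldin agrees with a brute-force reimplementation and flags degeneracy", {
  pb <- planted_bundles(10, noise = 0.3)
  km <- ts_kmeans(pb$seqs, K = 2, seed = 3)
  expect_equal(dbi_dtw(pb$seqs, km),
               dbi_bruteforce(pb$seqs, km$centroids, km$cluster))
  expect_gte(dbi_dtw(pb$seqs, km), 0)
  # duplicated centroids diverge
  degen <- list(centroids = list(pb$seqs[[1]], pb$seqs[[1]]),
                cluster = pb$truth)
  expect_warning(v <- dbi_dtw(pb$seqs, degen), "coincident")
  expect_true(is.infinite(v))
})

test_that("select_k scans the requested range and flags the planted K", {
  pb <- planted_bundles(10, noise = 0.1)
  tab <- select_k(pb$seqs, k_range = 2:5, seed = 7, n_init = 3)
  expect_equal(nrow(tab), 4L)
  expect_true(tab$acceptable[tab$K == 2])
  expect_equal(which.max(tab$silhouette), 1L)
})

test_that("hungarian assignment matches brute force on random costs", {
  set.seed(12)
  for (n in c(2, 3, 4, 5, 6)) {
    cost <- matrix(runif(n * n), n)
    got <- hungarian_assignment(cost)
    want <- assignment_bruteforce(cost)
    expect_equal(sum(cost[cbind(seq_len(n), got)]), want$cost,
                 tolerance = 1e-12)
  }
})

test_that("bootstrap stability is exact for a trivial resample and invariant to label permutation", {
  pb <- planted_bundles(8, noise = 0.1)
  ref <- ts_kmeans(pb$seqs, K = 2, seed = 5)
  bs <- bootstrap_stability(pb$seqs, K = 2, n_iter = 1, frac = 1,
                            seed = 5, reference = ref)
  expect_equal(unname(bs$jaccard_mean), c(1, 1))
  # permuting reference cluster ids leaves the matched Jaccard unchanged
  ref_perm <- ref
  ref_perm$cluster <- 3L - ref$cluster
  ref_perm$centroids <- rev(ref$centroids)
  bs_perm <- bootstrap_stability(pb$seqs, K = 2, n_iter = 5, frac = 0.8,
                                 seed = 6, reference = ref_perm)
  bs_orig <- bootstrap_stability(pb$seqs, K = 2, n_iter = 5, frac = 0.8,
                                 seed = 6, reference = ref)
  expect_equal(sort(bs_perm$jaccard_mean), sort(bs_orig$jaccard_mean))
  # well-separated bundles are stable
  expect_gte(mean(bs_orig$per_iteration$jaccard_mean), 0.8)
})
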