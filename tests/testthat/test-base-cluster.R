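test_that("select_representatives honors the k-means/random mixture contract", {
  set.seed(3)
  z <- matrix(rnorm(100), 50, 2)
  # p = n, mix_frac = 0: all cells, as a permutation
  r <- select_representatives(z, 50, mix_frac = 0, seed = 1)
  expect_equal(nrow(r$points), 50)
  expect_true(all(r$source_flags == "random_cell"))
  expect_equal(r$points[order(r$points[, 1]), ], z[order(z[, 1]), ],
               ignore_attr = TRUE)
  # p = 1, mix_frac = 1: the single 1-means center is the sample centroid
  r1 <- select_representatives(z, 1, mix_frac = 1, seed = 2)
  expect_equal(as.vector(r1$points), colMeans(z), tolerance = 1e-6)
  # determinism
  expect_identical(select_representatives(z, 10, 0.5, seed = 9)$points,
                   select_representatives(z, 10, 0.5, seed = 9)$points)
  expect_error(select_representatives(z, 51, 0.5, 1), "p must lie")
})

test_that("sparse_affinity equals the dense K-nearest Gaussian kernel", {
  set.seed(13)
  z <- matrix(rnorm(40), 20, 2)
  reps <- z[1:5, ]
  S <- as.matrix(sparse_affinity(z, reps, K = 3, sigma = 0.8))
  # brute force
  for (i in 1:20) {
    d2 <- colSums((t(reps) - z[i, ])^2)
    nn <- order(d2)[1:3]
    expect_equal(sum(S[i, ] > 0), 3)
    for (j in 1:5) {
      want <- if (j %in% nn) exp(-d2[j] / (2 * 0.8^2)) else 0
      expect_equal(S[i, j], want, tolerance = 1e-12)
    }
  }
  # coincident cell/representative with K >= 1 gives affinity exactly 1
  expect_equal(max(S[1, ]), 1)
  # K = p equals the dense kernel row
  Sfull <- as.matrix(sparse_affinity(z, reps, K = 5, sigma = 0.8))
  d2full <- outer(rowSums(z^2), rowSums(reps^2), "+") - 2 * z %*% t(reps)
  expect_equal(Sfull, exp(-pmax(d2full, 0) / (2 * 0.8^2)),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(sparse_affinity(z, reps, K = 6), "exceeds")
  expect_error(sparse_affinity(z, reps, K = 3, sigma = 0), "positive")
})

test_that("bipartite_spectral separates blobs and is seed-stable", {
  b <- make_aligned_spaces(80, 2, 1, dim = 2, sep = 8, seed = 5)
  z <- b$Z$spaces[[1]]
  reps <- select_representatives(z, 30, 0.5, seed = 1)
  S <- sparse_affinity(z, reps, K = 5)
  p1 <- bipartite_spectral(S, 2, seed = 4)
  expect_equal(ari(b$labels, p1$labels), 1)
  p2 <- bipartite_spectral(S, 2, seed = 4)
  expect_identical(p1$labels, p2$labels)
  expect_error(bipartite_spectral(S, 1), "k must be")
})

test_that("with p = n and K = p the transfer cut matches dense spectral clustering", {
  for (s in 1:3) {
    b <- make_aligned_spaces(30, 3, 1, dim = 2, sep = 7, seed = 200 + s)
    z <- b$Z$spaces[[1]]
    reps <- select_representatives(z, 30, mix_frac = 0, seed = s)
    S <- sparse_affinity(z, reps, K = 30, sigma = 1.5)
    ours <- bipartite_spectral(S, 3, seed = s)$labels
    A <- exp(-as.matrix(dist(z))^2 / (2 * 1.5^2))
    ref <- oracle_spectral(A, 3, seed = s)
    expect_gte(ari(ours, ref), 0.99)
  }
})

test_that("community detection respects graph structure, resolution and seed", {
  # two disconnected cliques (knn saturates each group) -> two
  # communities at resolution <= 1
  set.seed(6)
  z <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
             matrix(rnorm(40, 50, 0.1), 20, 2))
  for (m in c("louvain", "leiden")) {
    p <- community_partition(z, m, resolution = 1, knn = 19, seed = 1)
    expect_equal(p$k, 2L)
    expect_equal(ari(rep(1:2, each = 20), p$labels), 1)
    expect_identical(community_partition(z, m, 1, 10, seed = 2)$labels,
                     community_partition(z, m, 1, 10, seed = 2)$labels)
  }
  expect_error(community_partition(z, "louvain", resolution = 0), "positive")

  # larger resolution yields at least as many clusters in expectation
  b <- make_aligned_spaces(120, 3, 1, dim = 3, sep = 4, seed = 77)
  kc <- function(res) mean(vapply(1:5, function(s)
    community_partition(b$Z$spaces[[1]], "louvain", res, 10, seed = s)$k,
    integer(1)))
  expect_lte(kc(0.3), kc(2))
})

test_that("generate_ensemble produces D x T grouped, reproducible, diverse partitions", {
  sp <- make_aligned_spaces(90, 3, 3, sep = 3, seed = 55)
  ens <- generate_ensemble(sp$Z, k = 3, T_runs = 4, seed = 8, p = 60)
  expect_equal(length(ens$partitions), 12L)
  subs <- vapply(ens$partitions, `[[`, integer(1), "subspace_index")
  expect_equal(as.vector(table(subs)), rep(4L, 3))
  # determinism of the whole ensemble
  ens2 <- generate_ensemble(sp$Z, k = 3, T_runs = 4, seed = 8, p = 60)
  expect_identical(lapply(ens$partitions, `[[`, "labels"),
                   lapply(ens2$partitions, `[[`, "labels"))
  # minimal ensemble: T = 1 gives D partitions
  e1 <- generate_ensemble(sp$Z, k = 3, T_runs = 1, seed = 8, p = 60)
  expect_equal(length(e1$partitions), 3L)
  # diversity: on overlapping blobs not all runs are identical
  lab_strings <- vapply(ens$partitions, function(p)
    paste(p$labels, collapse = ","), character(1))
  expect_gt(length(unique(lab_strings)), 1L)
})
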