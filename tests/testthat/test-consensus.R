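test_that("cluster_uncertainty is the fragmentation entropy in bits", {
  # 8 cells, cluster = cells 1:4
  p_intact <- base_partition(c(1, 1, 1, 1, 2, 2, 2, 2), subspace_index = 1, run_index = 1)
  p_split <- base_partition(c(1, 1, 2, 2, 3, 3, 3, 3), k = 3, subspace_index = 1, run_index = 2)
  ens1 <- cluster_ensemble(list(p_intact))
  expect_equal(cluster_uncertainty(1:4, ens1), 0)
  # split 50/50 by one partition, intact in the other -> 1 bit
  ens2 <- cluster_ensemble(list(p_intact, p_split))
  expect_equal(cluster_uncertainty(1:4, ens2), 1)
  expect_error(cluster_uncertainty(integer(), ens1), "empty")
})

test_that("eci follows exp(-U / (theta D N)) with its limits", {
  expect_equal(eci(0, 0.4, 3, 10), 1)
  expect_equal(eci(0.4 * 3 * 10, 0.4, 3, 10), exp(-1))
  grid <- seq(0, 5, by = 0.25)
  vals <- vapply(grid, eci, numeric(1), theta = 0.4, D = 2, N = 5)
  expect_true(all(diff(vals) < 0))
  expect_error(eci(1, -1, 2, 5), "theta")
})

test_that("lwca_matrix: degenerate ensembles give block structure, uniform mode gives frequencies", {
  lab <- c(1, 1, 2, 2, 2)
  parts <- lapply(1:4, function(i) base_partition(lab, subspace_index = 1, run_index = i))
  ens <- cluster_ensemble(parts)
  ca <- lwca_matrix(ens, theta = 0.4)
  expect_s3_class(ca, "CoAssociationMatrix")
  expect_true(isSymmetric(ca$values))
  expect_equal(ca$values[1, 2], ca$values[1, 1])   # same block, intact clusters
  expect_equal(ca$values[1, 3], 0)
  expect_equal(max(ca$values), 1)                  # U = 0 -> ECI = 1 everywhere

  set.seed(5)
  mixed <- random_ensemble(12, 3, 5, seed = 50)
  cu <- lwca_matrix(mixed, weighting = "uniform")$values
  freq <- Reduce(`+`, lapply(mixed$partitions, function(p)
    outer(p$labels, p$labels, "=="))) / 5
  expect_equal(cu, freq + 0, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("lwca_matrix matches the brute-force triple loop", {
  for (s in 1:3) {
    ens <- random_ensemble(15, 3, 4, seed = 70 + s, D = 2L)
    got <- lwca_matrix(ens, theta = 0.4)$values
    want <- oracle_lwca(ens$partitions, theta = 0.4)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("agglomerative_consensus recovers blocks and handles k = n", {
  # block co-association with 3 blocks
  lab <- rep(1:3, times = c(3, 4, 5))
  ca <- outer(lab, lab, "==") + 0
  part <- agglomerative_consensus(ca, k = 3)
  expect_equal(ari(lab, part$labels), 1)
  singl <- agglomerative_consensus(ca, k = 12)
  expect_equal(sort(singl$labels), 1:12)
  expect_error(agglomerative_consensus(ca, k = 13), "exceeds")
})

test_that("agglomerative_consensus agrees with a naive average-linkage oracle", {
  set.seed(9)
  for (rep in 1:5) {
    n <- 12
    ca <- matrix(runif(n * n), n, n)
    ca <- (ca + t(ca)) / 2
    diag(ca) <- 1
    k <- sample(2:4, 1)
    got <- agglomerative_consensus(ca, k)$labels
    dmat <- 1 - ca / max(ca); diag(dmat) <- 0
    want <- oracle_average_linkage(dmat, k)
    expect_equal(ari(got, want), 1)
  }
})

test_that("consensus of agreeing ensembles returns the shared partition", {
  sp <- make_aligned_spaces(60, 3, 1, sep = 8, seed = 3)
  parts <- lapply(1:5, function(i)
    base_partition(sp$labels, subspace_index = 1, run_index = i))
  ens <- cluster_ensemble(parts)
  out <- consensus_cluster(ens, 3)
  expect_equal(ari(out$labels, sp$labels), 1)
  # theta does not matter when the ensemble is unanimous
  for (th in c(0.2, 0.4, 0.8)) {
    expect_equal(ari(consensus_cluster(ens, 3, theta = th)$labels,
                     out$labels), 1)
  }
  # single-partition ensemble: consensus returns it (up to relabeling)
  one <- cluster_ensemble(parts[1])
  expect_equal(ari(consensus_cluster(one, 3)$labels, sp$labels), 1)
})

test_that("ensembles round-trip through the CSV + JSON export", {
  ens <- random_ensemble(25, 3, 6, seed = 345, D = 2L)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_ensemble(ens, csv)
  back <- read_ensemble(csv)
  expect_equal(length(back$partitions), 6L)
  expect_identical(lapply(back$partitions, `[[`, "labels"),
                   lapply(ens$partitions, `[[`, "labels"))
  expect_identical(vapply(back$partitions, `[[`, integer(1), "subspace_index"),
                   vapply(ens$partitions, `[[`, integer(1), "subspace_index"))
  expect_equal(back$D, 2L)
})

test_that("consensus on a D x T ensemble of separable blobs recovers the planted labels", {
  sp <- make_aligned_spaces(150, 3, 3, sep = 8, seed = 21)
  ens <- generate_ensemble(sp$Z, k = 3, T_runs = 4, seed = 31, p = 100)
  out <- consensus_cluster(ens, 3)
  expect_gte(ari(out$labels, sp$labels), 0.95)
})
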