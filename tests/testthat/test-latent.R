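test_that("NNKAE parameters stay non-negative and training is deterministic", {
  set.seed(71)
  M <- matrix(runif(200), 20, 10)
  m1 <- fit_nnkae(M, hidden_dim = 4, epochs = 15, seed = 2)
  expect_true(all(m1$W_E >= 0) && all(m1$W_D >= 0))
  expect_true(all(m1$b_E >= 0) && all(m1$b_D >= 0))
  expect_equal(m1$gene_scores, rowSums(m1$W_E))
  m2 <- fit_nnkae(M, hidden_dim = 4, epochs = 15, seed = 2)
  expect_identical(m1$gene_scores, m2$gene_scores)
})

test_that("NNKAE reduces reconstruction error on low-rank input", {
  set.seed(72)
  u <- runif(30); v <- runif(8)
  M <- outer(u, v)                      # rank 1
  m <- fit_nnkae(M, hidden_dim = 1, epochs = 200, seed = 3)
  expect_lt(tail(m$loss_trace, 1), m$loss_trace[1])
})

test_that("all-zero gene columns score at the bottom of the NNKAE ranking", {
  set.seed(73)
  M <- matrix(runif(400, 0.2, 1), 40, 10)
  M[, c(3, 8)] <- 0
  m <- fit_nnkae(M, hidden_dim = 4, epochs = 300, seed = 5)
  zero_scores <- m$gene_scores[c(3, 8)]
  live_scores <- m$gene_scores[-c(3, 8)]
  expect_true(max(zero_scores) < min(live_scores))
  keep <- select_informative_genes(m, 8)
  expect_false(any(c(3, 8) %in% keep))
})

test_that("select_informative_genes returns sorted top-score indices with index tie-break", {
  expect_equal(select_informative_genes(c(3, 1, 2), 2), c(1L, 3L))
  expect_equal(select_informative_genes(c(3, 1, 2), 3), 1:3)
  expect_equal(select_informative_genes(c(1, 1, 1), 1), 1L)
  expect_error(select_informative_genes(c(1, 2), 3), "n_keep")
})

test_that("the Bayesian autoencoder is seeded, has positive sigma, and separates easy populations", {
  sp <- make_aligned_spaces(80, 2, 1, dim = 6, sep = 9, seed = 81)
  A <- (sp$Z$spaces[[1]] - min(sp$Z$spaces[[1]]))
  A <- A / max(A)
  enc1 <- fit_stacked_bayesian_ae(A, latent_dim = 2, epochs = 150, seed = 4,
                                  hidden = 16)
  enc2 <- fit_stacked_bayesian_ae(A, latent_dim = 2, epochs = 150, seed = 4,
                                  hidden = 16)
  ms1 <- depf:::encode_mu_sigma(enc1, A)
  ms2 <- depf:::encode_mu_sigma(enc2, A)
  expect_identical(ms1$mu, ms2$mu)
  expect_true(all(ms1$sigma > 0))
  # between-population centroid distance exceeds mean within-population spread
  mu <- ms1$mu
  c1 <- colMeans(mu[sp$labels == 1, ]); c2 <- colMeans(mu[sp$labels == 2, ])
  between <- sqrt(sum((c1 - c2)^2))
  within <- mean(c(sqrt(rowSums(sweep(mu[sp$labels == 1, ], 2, c1)^2)),
                   sqrt(rowSums(sweep(mu[sp$labels == 2, ], 2, c2)^2))))
  expect_gt(between, within)
  expect_error(fit_stacked_bayesian_ae(A, latent_dim = ncol(A)), "smaller")
})

test_that("sample_latent_spaces is reproducible, stochastic, and centred on mu", {
  set.seed(83)
  A <- matrix(runif(300), 30, 10)
  enc <- fit_stacked_bayesian_ae(A, latent_dim = 3, epochs = 50, seed = 6,
                                 hidden = 8)
  Z1 <- sample_latent_spaces(enc, A, d = 3, seed = 11)
  Z2 <- sample_latent_spaces(enc, A, d = 3, seed = 11)
  expect_identical(Z1$spaces, Z2$spaces)
  expect_length(Z1$spaces, 3)
  expect_false(identical(Z1$spaces[[1]], Z1$spaces[[2]]))
  # deterministic mode collapses to the posterior mean
  Zmu <- sample_latent_spaces(enc, A, d = 1, seed = 11, deterministic = TRUE)
  ms <- depf:::encode_mu_sigma(enc, A)
  expect_equal(Zmu$spaces[[1]], ms$mu)
  # law of large numbers: the mean of many draws approaches mu
  Zm <- sample_latent_spaces(enc, A, d = 200, seed = 12)
  avg <- Reduce(`+`, Zm$spaces) / 200
  mc_tol <- 4 * max(ms$sigma) / sqrt(200)
  expect_lt(max(abs(avg - ms$mu)), mc_tol)
})

test_that("svd fallback embeddings are deterministic near-copies", {
  set.seed(85)
  A <- matrix(runif(400), 40, 10)
  Z <- svd_embedding(A, latent_dim = 4, d = 3, seed = 2)
  expect_equal(Z$mode, "svd")
  expect_length(Z$spaces, 3)
  expect_identical(Z$spaces, svd_embedding(A, 4, 3, seed = 2)$spaces)
  rel <- max(abs(Z$spaces[[1]] - Z$spaces[[2]])) / mean(abs(Z$spaces[[1]]))
  expect_lt(rel, 0.05)
})

test_that("k-means on a sampled latent space recovers well-separated planted populations", {
  sim <- simulate_counts(simulation_spec(n_cells = 300, n_genes = 400, k = 3,
                                         lfc = 3, de_frac = 0.15,
                                         dropout_mid = -Inf, seed = 19))
  M <- minmax_normalize(log_transform(sim$matrix))
  Z <- compute_latent_spaces(M, n_keep = 300, latent_dim = 10, d = 2,
                             epochs_vae = 600, seed = 29)
  for (z in Z$spaces) {
    set.seed(1)
    km <- kmeans(z, centers = 3, nstart = 10)
    expect_gte(ari(sim$labels, km$cluster), 0.9)
  }
})
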