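#' Select representatives for bipartite spectral clustering
#'
#' A hybrid scheme: `round(mix_frac * p)` representatives are the centers
#' of a seeded k-means run on a random sub-sample of cells, the remainder
#' are distinct randomly chosen cells. Deterministic given `seed`.
#'
#' @param z latent coordinate matrix (cells x dims).
#' @param p number of representatives, `1 <= p <= n`.
#' @param mix_frac fraction of representatives taken from k-means centers.
#' @param seed integer seed.
#' @return list of class `RepresentativeSet` with `points` (p x dims) and
#'   `source_flags` (`"kmeans_center"` / `"random_cell"`).
#' @export
select_representatives <- function(z, p, mix_frac = 0.5, seed = 1L) {
  n <- nrow(z)
  if (p < 1 || p > n) stopf("p must lie in [1, %d]", n)
  n_km <- round(mix_frac * p)
  n_rand <- p - n_km
  with_seed(seed, {
    pts <- NULL; flags <- character()
    if (n_km > 0) {
      sub_n <- min(n, max(10L * n_km, 100L))
      sub <- z[sample.int(n, sub_n), , drop = FALSE]
      km <- suppressWarnings(kmeans(sub, centers = n_km, nstart = 1,
                                    iter.max = 30))
      pts <- km$centers
      flags <- rep("kmeans_center", n_km)
    }
    if (n_rand > 0) {
      idx <- sample.int(n, n_rand)
      pts <- rbind(pts, z[idx, , drop = FALSE])
      flags <- c(flags, rep("random_cell", n_rand))
    }
    rownames(pts) <- NULL
    structure(list(points = pts, source_flags = flags),
              class = "RepresentativeSet")
  })
}

#' Sparse cell-to-representative affinity matrix
#'
#' Gaussian kernel affinities `s_ij = exp(-||x_i - r_j||^2 / (2 sigma^2))`
#' kept only for the `K` representatives nearest each cell (ties trimmed
#' by lower representative index), zero elsewhere. `sigma = "auto"`
#' resolves to the mean of the retained cell-to-representative distances.
#'
#' @param z latent coordinates (n x dims).
#' @param reps a [select_representatives()] result (or plain matrix).
#' @param K neighbors retained per cell, `K <= p`.
#' @param sigma Gaussian bandwidth, positive number or `"auto"`.
#' @return sparse `dgCMatrix` (n x p), exactly `K` nonzeros per row
#'   (coincident points yield affinity 1).
#' @export
sparse_affinity <- function(z, reps, K = 5L, sigma = "auto") {
  pts <- if (inherits(reps, "RepresentativeSet")) reps$points else reps
  p <- nrow(pts)
  n <- nrow(z)
  if (K > p) stopf("K = %d exceeds number of representatives %d", K, p)
  if (is.numeric(sigma) && sigma <= 0) stopf("sigma must be positive")
  d2 <- cross_dist2(z, pts)
  # K nearest per row, deterministic tie-break by column index
  nb <- t(apply(d2, 1, function(r) order(r)[seq_len(K)]))
  ii <- rep(seq_len(n), K)
  jj <- as.vector(nb)
  dd2 <- d2[cbind(ii, jj)]
  if (identical(sigma, "auto")) {
    sigma <- mean(sqrt(dd2))
    if (sigma <= 0) sigma <- 1        # all points coincident
  }
  vals <- exp(-dd2 / (2 * sigma^2))
  Matrix::sparseMatrix(i = ii, j = jj, x = vals, dims = c(n, p))
}

#' Bipartite spectral clustering (transfer cut)
#'
#' Treats the sparse affinity matrix as a bipartite graph between cells
#' and representatives, solves the normalized adjacency eigenproblem on
#' the small p-side, stacks the `(n + p) x k` eigenvector matrix
#' (cell-side rows recovered from the p-side solution), row-normalizes,
#' and partitions the cell rows with seeded k-means.
#'
#' @param S sparse n x p affinity from [sparse_affinity()].
#' @param k number of clusters, `k >= 2`.
#' @param seed integer seed for the embedding k-means.
#' @return A [base_partition()] with `method = "uspec"`.
#' @export
bipartite_spectral <- function(S, k, seed = 1L) {
  if (k < 2) stopf("k must be >= 2")
  n <- nrow(S); p <- ncol(S)
  d1 <- Matrix::rowSums(S)
  if (any(d1 <= 0)) stopf("affinity rows must have positive sums")
  d2 <- pmax(Matrix::colSums(S), .Machine$double.eps)
  St <- Matrix::Diagonal(x = 1 / sqrt(d1)) %*% S %*% Matrix::Diagonal(x = 1 / sqrt(d2))
  G <- as.matrix(Matrix::crossprod(St))          # p x p
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  m <- min(k, p)
  V <- eg$vectors[, seq_len(m), drop = FALSE]
  sv <- sqrt(pmax(eg$values[seq_len(m)], 0))
  U <- as.matrix(St %*% V)
  U <- sweep(U, 2, pmax(sv, .Machine$double.eps), "/")
  # Ncut embedding: D^{-1/2}-scaled eigenvectors, stacked then row-normalized
  emb <- rbind(U / sqrt(d1), V / sqrt(d2))
  nrm <- sqrt(rowSums(emb^2))
  emb <- emb / pmax(nrm, .Machine$double.eps)
  cells <- emb[seq_len(n), , drop = FALSE]
  cl <- with_seed(seed,
    suppressWarnings(kmeans(cells, centers = k, nstart = 10, iter.max = 50)))
  sizes <- tabulate(cl$cluster, nbins = k)
  if (any(sizes == 0))
    warning("degenerate partition: some spectral clusters are empty")
  base_partition(cl$cluster, k = k, method = "uspec")
}

#' Community detection base clusterer
#'
#' Builds a k-nearest-neighbor graph on the latent coordinates (an edge
#' joins two cells when either lists the other among its `knn` nearest;
#' unit weights) and partitions it with Louvain or Leiden modularity
#' optimization at the given resolution. The number of clusters is
#' inferred from the result.
#'
#' @param z latent coordinates (n x dims).
#' @param method `"louvain"` or `"leiden"`.
#' @param resolution positive resolution parameter; larger values yield
#'   more, finer communities.
#' @param knn neighbors per cell, `knn < n`.
#' @param seed integer seed.
#' @return A [base_partition()].
#' @export
community_partition <- function(z, method = c("louvain", "leiden"),
                                resolution = 1, knn = 15L, seed = 1L) {
  method <- match.arg(method)
  if (resolution <= 0) stopf("resolution must be positive")
  n <- nrow(z)
  if (knn >= n) stopf("knn must be smaller than the number of cells")
  d2 <- cross_dist2(z, z)
  diag(d2) <- Inf
  nb <- t(apply(d2, 1, function(r) order(r)[seq_len(knn)]))
  edges <- cbind(rep(seq_len(n), knn), as.vector(nb))
  edges <- t(apply(edges, 1, sort))
  edges <- unique(edges)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comm <- with_seed(seed, {
    if (method == "louvain") {
      igraph::cluster_louvain(g, resolution = resolution)
    } else {
      igraph::cluster_leiden(g, objective_function = "modularity",
                             resolution = resolution, n_iterations = 3)
    }
  })
  labels <- as.integer(igraph::membership(comm))
  base_partition(labels, k = max(labels), method = method)
}

#' Generate the base-clustering ensemble
#'
#' Runs the configured base clusterer `T` times in each latent space with
#' distinct derived seeds (each bipartite-spectral run draws a fresh
#' jittered representative set), yielding `D x T` partitions grouped by
#' subspace.
#'
#' @param Z a `LatentSpaces` object (see [sample_latent_spaces()]) or a
#'   plain list of coordinate matrices.
#' @param k number of clusters per base partition (`uspec` method).
#' @param T_runs runs per subspace.
#' @param method `"uspec"`, `"louvain"` or `"leiden"`.
#' @param seed master seed; per-run seeds are derived deterministically
#'   from `(seed, subspace_index, run_index)`.
#' @param p,K,mix_frac,sigma ultra-scalable spectral parameters (see
#'   [select_representatives()] and [sparse_affinity()]); `p` defaults to
#'   `min(n, 1000)`.
#' @param resolution,knn community-detection parameters.
#' @return A [cluster_ensemble()] with `D x T_runs` partitions.
#' @export
generate_ensemble <- function(Z, k, T_runs = 10L,
                              method = c("uspec", "louvain", "leiden"),
                              seed = 1L, p = NULL, K = 5L, mix_frac = 0.5,
                              sigma = "auto", resolution = 1, knn = 15L) {
  method <- match.arg(method)
  spaces <- if (inherits(Z, "LatentSpaces")) Z$spaces else Z
  if (T_runs < 1) stopf("T_runs must be >= 1")
  parts <- list()
  for (d in seq_along(spaces)) {
    z <- spaces[[d]]
    n <- nrow(z)
    p_d <- min(n, p %||% min(n, 1000L))
    for (t in seq_len(T_runs)) {
      run_seed <- derive_seed(seed, d, t)
      part <- if (method == "uspec") {
        reps <- select_representatives(z, p_d, mix_frac, seed = run_seed)
        S <- sparse_affinity(z, reps, K = min(K, p_d), sigma = sigma)
        bipartite_spectral(S, k, seed = run_seed)
      } else {
        community_partition(z, method, resolution = resolution,
                            knn = knn, seed = run_seed)
      }
      part$subspace_index <- d
      part$run_index <- t
      parts[[length(parts) + 1L]] <- part
    }
  }
  cluster_ensemble(parts)
}
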