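#' Construct a base partition
#'
#' @param labels integer cluster labels `1..k` for every cell.
#' @param k number of clusters (defaults to `max(labels)`).
#' @param subspace_index,run_index 1-based indices of the latent space and
#'   run that produced this partition.
#' @param method one of `"uspec"`, `"louvain"`, `"leiden"`, `"external"`.
#' @return An object of class `BasePartition`.
#' @export
base_partition <- function(labels, k = max(labels), subspace_index = 1L,
                           run_index = 1L, method = "external") {
  labels <- as.integer(labels)
  if (any(labels < 1L) || any(labels > k)) stopf("labels must lie in 1..k")
  structure(list(labels = labels, k = as.integer(k),
                 subspace_index = as.integer(subspace_index),
                 run_index = as.integer(run_index), method = method),
            class = "BasePartition")
}

#' Construct a clustering ensemble
#'
#' @param partitions list of [base_partition()] objects over the same cells.
#' @return Object of class `ClusterEnsemble` with fields `partitions`
#'   (ordered by subspace then run), `D` (number of subspaces), `T_runs`
#'   (runs per subspace; maximum when unequal after pruning) and `n`.
#' @export
cluster_ensemble <- function(partitions) {
  if (!length(partitions)) stopf("ensemble must contain at least one partition")
  ns <- vapply(partitions, function(p) length(p$labels), integer(1))
  if (length(unique(ns)) != 1) stopf("partitions disagree on cell count")
  ord <- order(vapply(partitions, `[[`, integer(1), "subspace_index"),
               vapply(partitions, `[[`, integer(1), "run_index"))
  partitions <- partitions[ord]
  subs <- vapply(partitions, `[[`, integer(1), "subspace_index")
  structure(list(partitions = partitions, D = length(unique(subs)),
                 T_runs = max(table(subs)), n = ns[1]),
            class = "ClusterEnsemble")
}

#' @export
print.ClusterEnsemble <- function(x, ...) {
  cat(sprintf("ClusterEnsemble: %d partitions over %d cells (%d subspaces)\n",
              length(x$partitions), x$n, x$D))
  invisible(x)
}

subset_ensemble <- function(ensemble, idx) {
  cluster_ensemble(ensemble$partitions[idx])
}

#' Cross-ensemble uncertainty of a cluster
#'
#' Entropy (in bits) of how a set of cells is fragmented across the
#' clusters of every base partition in the ensemble:
#' `U(c) = -sum_pi sum_j p_j log2 p_j` with `p_j = |c ∩ c_j| / |c|` over
#' the clusters `c_j` of partition `pi`; `0 log 0 := 0`. A cluster kept
#' intact by every partition has `U = 0`.
#'
#' @param cluster integer vector of cell indices (1-based).
#' @param ensemble a [cluster_ensemble()].
#' @return non-negative scalar (bits).
#' @export
cluster_uncertainty <- function(cluster, ensemble) {
  if (!length(cluster)) stopf("empty cluster")
  size <- length(cluster)
  u <- 0
  for (p in ensemble$partitions) {
    tab <- tabulate(p$labels[cluster], nbins = p$k)
    pr <- tab[tab > 0] / size
    u <- u - sum(pr * log2(pr))
  }
  u
}

#' Ensemble-driven cluster index (reliability weight)
#'
#' `ECI = exp(-U / (theta * D * N))` where `U` is the cluster uncertainty,
#' `D` the number of subspaces, `N` the (mean) number of base partitions
#' per subspace, and `theta` an adjustment factor. `U = 0` gives
#' `ECI = 1`; larger uncertainty decays the weight toward 0.
#'
#' @param U non-negative uncertainty (bits).
#' @param theta positive adjustment factor.
#' @param D number of subspaces.
#' @param N base partitions per subspace.
#' @return scalar in `(0, 1]`.
#' @export
eci <- function(U, theta, D, N) {
  if (theta <= 0) stopf("theta must be positive")
  if (D <= 0 || N <= 0) stopf("D and N must be positive")
  exp(-U / (theta * D * N))
}

#' Locally weighted co-association matrix
#'
#' For every pair of cells, averages over base partitions the reliability
#' (ECI) of the cluster in which the pair is co-clustered (0 when not
#' co-clustered). With `weighting = "uniform"` every cluster weighs 1 and
#' the matrix reduces to the classic co-association (co-clustering
#' frequency). The ECI normalization uses `theta * (total partitions)`,
#' i.e. `N` is the mean per-subspace partition count, which is exact for
#' balanced ensembles and degrades gracefully after pruning.
#'
#' @param ensemble a [cluster_ensemble()].
#' @param theta positive adjustment factor for [eci()].
#' @param weighting `"eci"` (default) or `"uniform"`.
#' @return list of class `CoAssociationMatrix` with `values` (n x n dense
#'   symmetric, entries in `[0, 1]`, unit diagonal) and `weighting`.
#' @export
lwca_matrix <- function(ensemble, theta = 0.4, weighting = c("eci", "uniform")) {
  weighting <- match.arg(weighting)
  n <- ensemble$n
  P <- length(ensemble$partitions)
  D <- ensemble$D
  N_mean <- P / D
  ca <- matrix(0, n, n)
  for (p in ensemble$partitions) {
    for (cl in seq_len(p$k)) {
      members <- which(p$labels == cl)
      if (!length(members)) next
      w <- if (weighting == "eci") {
        eci(cluster_uncertainty(members, ensemble), theta, D, N_mean)
      } else 1
      ca[members, members] <- ca[members, members] + w
    }
  }
  ca <- ca / P
  structure(list(values = ca, weighting = weighting, theta = theta),
            class = "CoAssociationMatrix")
}

#' Agglomerative consensus from a co-association matrix
#'
#' Average-linkage hierarchical clustering on the distance
#' `1 - ca / max(ca)`, cut at `k` clusters. Self-distance is 0 by
#' construction.
#'
#' @param caM a [lwca_matrix()] result (or plain symmetric matrix).
#' @param k number of consensus clusters, `2 <= k <= n`.
#' @return Object of class `ConsensusPartition`: `labels` (1..k),
#'   `k`, and the `coassoc` used.
#' @export
agglomerative_consensus <- function(caM, k) {
  ca <- if (inherits(caM, "CoAssociationMatrix")) caM$values else caM
  n <- nrow(ca)
  if (k > n) stopf("k = %d exceeds number of cells %d", k, n)
  if (k < 1) stopf("k must be >= 1")
  mx <- max(ca)
  dmat <- if (mx > 0) 1 - ca / mx else matrix(1, n, n)
  diag(dmat) <- 0
  hc <- hclust(as.dist(dmat), method = "average")
  labels <- cutree(hc, k = k)
  structure(list(labels = as.integer(labels), k = as.integer(k),
                 coassoc = caM),
            class = "ConsensusPartition")
}

#' @export
print.ConsensusPartition <- function(x, ...) {
  cat(sprintf("ConsensusPartition: %d cells in %d clusters\n",
              length(x$labels), x$k))
  invisible(x)
}

#' Locally weighted ensemble consensus clustering
#'
#' Full composition: cluster uncertainties, ECI reliabilities, weighted
#' co-association matrix, average-linkage agglomerative cut at `k`.
#'
#' @param ensemble a [cluster_ensemble()].
#' @param k number of consensus clusters.
#' @param theta ECI adjustment factor (default 0.4).
#' @param weighting `"eci"` or `"uniform"`.
#' @return A `ConsensusPartition`.
#' @export
consensus_cluster <- function(ensemble, k, theta = 0.4,
                              weighting = c("eci", "uniform")) {
  weighting <- match.arg(weighting)
  agglomerative_consensus(lwca_matrix(ensemble, theta, weighting), k)
}
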