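# Internal: full pairwise Euclidean distance matrix, reused across
# objective evaluations of the same coordinate set.
dist_matrix <- function(coords) as.matrix(dist(coords))

#' Compactness of a partition
#'
#' Weighted mean within-cluster pairwise distance:
#' `Cp = (1/N) * sum_k m_k * [ sum_{i<j in c_k} d(x_i, x_j) / (m_k (m_k - 1) / 2) ]`
#' with Euclidean distance. Singleton clusters have no pairs and
#' contribute 0. Smaller is more compact.
#'
#' @param labels integer cluster labels `1..k`.
#' @param coords numeric matrix of cell coordinates (rows = cells).
#' @param dmat optional precomputed distance matrix for `coords`.
#' @return non-negative scalar.
#' @export
compactness <- function(labels, coords, dmat = NULL) {
  n <- length(labels)
  if (!is.null(coords) && nrow(coords) != n) stopf("labels/coords mismatch")
  if (is.null(dmat)) dmat <- dist_matrix(coords)
  total <- 0
  for (cl in unique(labels)) {
    members <- which(labels == cl)
    m <- length(members)
    if (m < 2) next
    s <- sum(dmat[members, members]) / 2        # each pair counted twice
    total <- total + m * s / (m * (m - 1) / 2)
  }
  total / n
}

#' Deviation of a partition
#'
#' Sum over clusters of member distances to the cluster centroid
#' (arithmetic mean of member coordinates). Smaller is tighter.
#'
#' @inheritParams compactness
#' @return non-negative scalar.
#' @export
deviation <- function(labels, coords) {
  n <- length(labels)
  if (nrow(coords) != n) stopf("labels/coords mismatch")
  total <- 0
  for (cl in unique(labels)) {
    members <- which(labels == cl)
    sub <- coords[members, , drop = FALSE]
    ctr <- colMeans(sub)
    total <- total + sum(sqrt(rowSums(sweep(sub, 2, ctr)^2)))
  }
  total
}

#' Silhouette coefficients of a partition
#'
#' Per-cell silhouette with the three-branch form: `1 - a/b` if `a < b`,
#' `0` if `a = b`, `b/a - 1` if `a > b`, where `a` is the mean distance
#' to co-members of the cell's own cluster and `b` the mean distance to
#' the members of the nearest other cluster. Cells in singleton clusters
#' score 0 (neutral).
#'
#' @inheritParams compactness
#' @return list of class `SilhouetteReport` with `per_cell` (in
#'   `[-1, 1]`), `msc` (mean) and `min_sc` (minimum).
#' @export
silhouette_report <- function(labels, coords, dmat = NULL) {
  n <- length(labels)
  ks <- sort(unique(labels))
  if (length(ks) < 2) stopf("silhouette requires at least 2 clusters")
  if (is.null(dmat)) dmat <- dist_matrix(coords)
  sizes <- tabulate(labels)
  # mean distance from every cell to every cluster, n x k
  memb <- outer(labels, ks, "==") + 0
  sums <- dmat %*% memb
  sc <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    m <- sizes[own]
    if (m <= 1) { sc[i] <- 0; next }
    a <- sums[i, match(own, ks)] / (m - 1)
    others <- ks[ks != own]
    b <- min(sums[i, match(others, ks)] / sizes[others])
    sc[i] <- if (a < b) 1 - a / b else if (a > b) b / a - 1 else 0
  }
  structure(list(per_cell = sc, msc = mean(sc), min_sc = min(sc)),
            class = "SilhouetteReport")
}

#' Optimization direction from the silhouette indicator
#'
#' Returns `+1` when every cell's silhouette lies in the closed interval
#' `[eps, 1]` — the objectives (Dev, Cp) are then minimized — and `-1`
#' when any cell falls below `eps`, flipping the search to maximization
#' (the signed pair `(-Dev, -Cp)` is minimized).
#'
#' @param report a [silhouette_report()].
#' @param eps direction threshold (default -0.6).
#' @return `+1` or `-1`.
#' @export
decide_direction <- function(report, eps = -0.6) {
  if (report$min_sc >= eps) 1L else -1L
}

#' Signed bi-objective pair
#'
#' @param dev,cp non-negative Deviation and Compactness values.
#' @param direction `+1` or `-1`.
#' @return list of class `ObjectivePair` with `dev`, `cp`, `direction`
#'   and `signed = direction * c(dev, cp)` (always minimized).
#' @export
objective_pair <- function(dev, cp, direction = 1L) {
  if (dev < 0 || cp < 0) stopf("objectives must be non-negative")
  if (!direction %in% c(-1L, 1L)) stopf("direction must be +1 or -1")
  structure(list(dev = dev, cp = cp, direction = as.integer(direction),
                 signed = direction * c(dev, cp)),
            class = "ObjectivePair")
}

#' Evaluate a pruning mask on one subspace
#'
#' Computes the locally weighted consensus of the base partitions
#' selected by `mask`, then the signed (Dev, Cp) pair of that consensus
#' on the subspace coordinates.
#'
#' @param mask binary vector over the subspace's base partitions; at
#'   least one bit must be set.
#' @param subspace_partitions list of [base_partition()] for one subspace.
#' @param coords latent coordinates of that subspace.
#' @param k number of consensus clusters.
#' @param direction `+1` or `-1`.
#' @param theta ECI adjustment factor.
#' @param dmat optional precomputed distance matrix for `coords`.
#' @return An [objective_pair()] with attribute `"labels"` holding the
#'   consensus labels evaluated.
#' @export
evaluate_mask <- function(mask, subspace_partitions, coords, k,
                          direction = 1L, theta = 0.4, dmat = NULL) {
  if (length(mask) != length(subspace_partitions))
    stopf("mask length %d != %d partitions", length(mask), length(subspace_partitions))
  if (!any(mask == 1)) stopf("all-zero mask must be repaired before evaluation")
  ens <- cluster_ensemble(subspace_partitions[mask == 1])
  part <- consensus_cluster(ens, k, theta)
  dv <- deviation(part$labels, coords)
  cp <- compactness(part$labels, coords, dmat = dmat)
  out <- objective_pair(dv, cp, direction)
  attr(out, "labels") <- part$labels
  out
}

#' Pareto dominance of signed objective pairs
#'
#' `a` dominates `b` iff `a$signed <= b$signed` componentwise with strict
#' inequality in at least one component (both pairs are minimized).
#'
#' @param a,b [objective_pair()] objects with the same direction.
#' @return logical.
#' @export
dominates <- function(a, b) {
  if (a$direction != b$direction) stopf("cannot compare pairs with mixed directions")
  all(a$signed <= b$signed) && any(a$signed < b$signed)
}
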