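# Independent brute-force oracles. Deliberately naive (explicit loops,
# no shared code with the package internals) so they can arbitrate.

oracle_compactness <- function(labels, coords) {
  n <- length(labels)
  total <- 0
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    m <- length(idx)
    if (m < 2) next
    s <- 0
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      s <- s + sqrt(sum((coords[idx[i], ] - coords[idx[j], ])^2))
    }
    total <- total + m * s / (m * (m - 1) / 2)
  }
  total / n
}

oracle_deviation <- function(labels, coords) {
  total <- 0
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    ctr <- colMeans(coords[idx, , drop = FALSE])
    for (i in idx) total <- total + sqrt(sum((coords[i, ] - ctr)^2))
  }
  total
}

oracle_silhouette <- function(labels, coords) {
  n <- length(labels)
  sc <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (!length(own)) { sc[i] <- 0; next }
    a <- mean(sapply(own, function(j) sqrt(sum((coords[i, ] - coords[j, ])^2))))
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      idx <- which(labels == cl)
      d <- mean(sapply(idx, function(j) sqrt(sum((coords[i, ] - coords[j, ])^2))))
      b <- min(b, d)
    }
    sc[i] <- if (a < b) 1 - a / b else if (a > b) b / a - 1 else 0
  }
  sc
}

oracle_uncertainty <- function(cluster, partitions) {
  u <- 0
  for (p in partitions) {
    for (cl in unique(p$labels)) {
      inter <- sum(p$labels[cluster] == cl)
      if (inter == 0) next
      pr <- inter / length(cluster)
      u <- u - pr * log2(pr)
    }
  }
  u
}

oracle_lwca <- function(partitions, theta) {
  n <- length(partitions[[1]]$labels)
  P <- length(partitions)
  D <- length(unique(sapply(partitions, function(p) p$subspace_index)))
  ca <- matrix(0, n, n)
  for (p in partitions) {
    for (cl in unique(p$labels)) {
      idx <- which(p$labels == cl)
      u <- oracle_uncertainty(idx, partitions)
      w <- exp(-u / (theta * D * (P / D)))
      for (i in idx) for (j in idx) ca[i, j] <- ca[i, j] + w
    }
  }
  ca / P
}

oracle_nmi <- function(truth, pred) {
  n <- length(truth)
  tt <- unique(truth); pp <- unique(pred)
  mi <- 0
  for (a in tt) for (b in pp) {
    nij <- sum(truth == a & pred == b)
    if (nij == 0) next
    mi <- mi + (nij / n) * log((nij * n) / (sum(truth == a) * sum(pred == b)))
  }
  ent <- function(lab) {
    s <- 0
    for (a in unique(lab)) { p <- mean(lab == a); s <- s - p * log(p) }
    s
  }
  ht <- ent(truth); hp <- ent(pred)
  if (ht + hp == 0) return(1)
  2 * mi / (ht + hp)
}

oracle_ari <- function(truth, pred) {
  n <- length(truth)
  a <- b <- cc <- d <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    st <- truth[i] == truth[j]; sp <- pred[i] == pred[j]
    if (st && sp) a <- a + 1
    else if (st && !sp) b <- b + 1
    else if (!st && sp) cc <- cc + 1
    else d <- d + 1
  }
  tot <- a + b + cc + d
  exp_idx <- (a + b) * (a + cc) / tot
  max_idx <- ((a + b) + (a + cc)) / 2
  if (max_idx == exp_idx) return(if (a == exp_idx) 1 else 0)
  (a - exp_idx) / (max_idx - exp_idx)
}

# dense normalized-cut spectral clustering on a full affinity matrix
oracle_spectral <- function(A, k, seed) {
  dvec <- rowSums(A)
  L <- diag(1 / sqrt(dvec)) %*% A %*% diag(1 / sqrt(dvec))
  eg <- eigen((L + t(L)) / 2, symmetric = TRUE)
  V <- eg$vectors[, seq_len(k), drop = FALSE]
  V <- diag(1 / sqrt(dvec)) %*% V
  V <- V / pmax(sqrt(rowSums(V^2)), 1e-300)
  set.seed(seed)
  kmeans(V, centers = k, nstart = 10, iter.max = 50)$cluster
}

# naive average-linkage agglomeration down to k groups
oracle_average_linkage <- function(dmat, k) {
  n <- nrow(dmat)
  groups <- as.list(seq_len(n))
  while (length(groups) > k) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(length(groups) - 1)) for (j in (i + 1):length(groups)) {
      d <- mean(dmat[groups[[i]], groups[[j]]])
      if (d < bestd) { bestd <- d; best <- c(i, j) }
    }
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  labels <- integer(n)
  for (g in seq_along(groups)) labels[groups[[g]]] <- g
  labels
}
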