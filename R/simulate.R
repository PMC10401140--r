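#' Specification for a synthetic scRNA-seq simulation
#'
#' Defaults describe a small but realistic droplet-style experiment:
#' overdispersed negative-binomial counts around log-normal baseline
#' means, a fraction of genes differentially expressed per population,
#' and logistic dropout inflating zeros for weakly expressed genes.
#'
#' @param n_cells,n_genes,k dimensions and number of planted populations.
#' @param de_frac fraction of genes differentially expressed per cluster.
#' @param lfc log-fold-change magnitude (natural log) of DE genes.
#' @param dispersion NB overdispersion (variance = mu + dispersion*mu^2).
#' @param dropout_mid logistic dropout midpoint on the `log1p(mu)` scale;
#'   `-Inf` disables dropout.
#' @param proportions cluster mixing weights (default equal); must sum
#'   to 1.
#' @param seed integer seed.
#' @return list of class `SimulationSpec`.
#' @export
simulation_spec <- function(n_cells = 500L, n_genes = 1500L, k = 3L,
                            de_frac = 0.1, lfc = 1.5, dispersion = 0.3,
                            dropout_mid = 1, proportions = NULL,
                            seed = 1L) {
  if (k > n_cells) stopf("k (%d) cannot exceed n_cells (%d)", k, n_cells)
  if (is.null(proportions)) proportions <- rep(1 / k, k)
  if (length(proportions) != k) stopf("proportions must have length k")
  if (abs(sum(proportions) - 1) > 1e-8) stopf("proportions must sum to 1")
  if (dispersion <= 0) stopf("dispersion must be positive")
  if (de_frac < 0 || de_frac > 1) stopf("de_frac must lie in [0, 1]")
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 k = as.integer(k), de_frac = de_frac, lfc = lfc,
                 dispersion = dispersion, dropout_mid = dropout_mid,
                 proportions = proportions, seed = as.integer(seed)),
            class = "SimulationSpec")
}

#' Simulate an overdispersed scRNA-seq count matrix
#'
#' Baseline gene means are log-normal; each planted population shifts
#' its own random `de_frac` subset of genes by `±lfc` on the log scale;
#' counts are negative binomial with the given overdispersion; zeros
#' are then inflated by a logistic dropout whose probability decreases
#' with `log1p(mu)`. Fully deterministic given the spec's seed.
#'
#' @param spec a [simulation_spec()].
#' @return list with `matrix` (an [expression_matrix()] of counts),
#'   `labels` (integer population assignments 1..k) and `de_genes`
#'   (list of per-cluster DE gene indices).
#' @export
simulate_counts <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "SimulationSpec"))
  with_seed(spec$seed, {
    n <- spec$n_cells; g <- spec$n_genes; k <- spec$k
    sizes <- floor(spec$proportions * n)
    rem <- n - sum(sizes)
    if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    labels <- sample(rep(seq_len(k), times = sizes))
    base_mu <- rlnorm(g, meanlog = 0.5, sdlog = 1)
    n_de <- round(spec$de_frac * g)
    # cluster-specific DE genes: disjoint marker blocks when the gene
    # pool allows, overlapping random draws otherwise
    de_genes <- if (n_de == 0) {
      replicate(k, integer(0), simplify = FALSE)
    } else if (n_de * k <= g) {
      pool <- sample.int(g, n_de * k)
      split(pool, rep(seq_len(k), each = n_de))
    } else {
      lapply(seq_len(k), function(cl) sample.int(g, n_de))
    }
    lfc_mat <- matrix(0, k, g)
    for (cl in seq_len(k)) {
      signs <- sample(c(-1, 1), n_de, replace = TRUE)
      lfc_mat[cl, de_genes[[cl]]] <- signs * spec$lfc
    }
    mu <- exp(sweep(lfc_mat[labels, , drop = FALSE], 2, log(base_mu), "+"))
    size <- 1 / spec$dispersion
    counts <- matrix(rnbinom(n * g, mu = mu, size = size), n, g)
    if (is.finite(spec$dropout_mid)) {
      p_drop <- plogis(spec$dropout_mid - log1p(mu))
      keep <- matrix(rbinom(n * g, 1, 1 - p_drop), n, g)
      counts <- counts * keep
    }
    em <- expression_matrix(counts,
                            cell_ids = sprintf("cell%04d", seq_len(n)),
                            gene_ids = sprintf("gene%05d", seq_len(g)))
    list(matrix = em, labels = labels, de_genes = de_genes,
         params = list(base_mu = base_mu, lfc_mat = lfc_mat))
  })
}

#' Simulate Gaussian latent blobs
#'
#' Isotropic Gaussian clusters in `dim` dimensions with unit
#' within-cluster standard deviation and centroid spacing
#' `separation` (so `separation` is in units of the within-cluster sd).
#' Centroid directions are random orthonormal-ish draws.
#'
#' @param n number of points.
#' @param dim dimensionality.
#' @param k number of clusters.
#' @param separation centroid spacing in within-cluster sd units.
#' @param seed integer seed.
#' @return list with `coords` (n x dim matrix) and `labels` (1..k).
#' @export
simulate_latent_blobs <- function(n, dim = 2L, k = 3L, separation = 6,
                                  seed = 1L) {
  if (k > n) stopf("k cannot exceed n")
  with_seed(seed, {
    labels <- sort(rep_len(seq_len(k), n))
    centers <- matrix(rnorm(k * dim), k, dim)
    if (k > 1 && separation > 0) {
      # rescale so the minimum centroid spacing equals `separation`
      dmin <- min(dist(centers))
      centers <- centers * (separation / max(dmin, 1e-12))
    } else if (separation == 0) {
      centers[] <- 0
    }
    coords <- centers[labels, , drop = FALSE] + matrix(rnorm(n * dim), n, dim)
    ord <- sample.int(n)                 # random row order
    list(coords = coords[ord, , drop = FALSE], labels = labels[ord])
  })
}

#' Corrupt ensemble members for pruning experiments
#'
#' Replaces `n_bad_per_subspace` randomly chosen members in every
#' subspace either by a label-shuffled copy (`"shuffle"`) or by uniform
#' random labels over the same k (`"random_k"`). The replaced positions
#' are recorded in the `"corrupted"` attribute so tests know the ground
#' truth.
#'
#' @param ensemble a [cluster_ensemble()].
#' @param n_bad_per_subspace members to corrupt per subspace.
#' @param mode `"shuffle"` or `"random_k"`.
#' @param seed integer seed.
#' @return The corrupted [cluster_ensemble()]; attribute `"corrupted"`
#'   is a logical vector over `ensemble$partitions`.
#' @export
corrupt_ensemble <- function(ensemble, n_bad_per_subspace,
                             mode = c("shuffle", "random_k"), seed = 1L) {
  mode <- match.arg(mode)
  subs <- vapply(ensemble$partitions, `[[`, integer(1), "subspace_index")
  flags <- rep(FALSE, length(ensemble$partitions))
  if (n_bad_per_subspace == 0) {
    attr(ensemble, "corrupted") <- flags
    return(ensemble)
  }
  with_seed(seed, {
    for (d in unique(subs)) {
      idx <- which(subs == d)
      if (n_bad_per_subspace > length(idx))
        stopf("cannot corrupt %d of %d members", n_bad_per_subspace, length(idx))
      bad <- sample(idx, n_bad_per_subspace)
      for (b in bad) {
        p <- ensemble$partitions[[b]]
        p$labels <- if (mode == "shuffle") {
          sample(p$labels)
        } else {
          sample.int(p$k, length(p$labels), replace = TRUE)
        }
        ensemble$partitions[[b]] <- p
        flags[b] <- TRUE
      }
    }
  })
  attr(ensemble, "corrupted") <- flags
  ensemble
}
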