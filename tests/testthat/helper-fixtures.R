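# Shared fixture builders (all seeded, built at test time).

# D latent views of the same cells: identical planted labels, different
# random centroid geometry per view.
make_aligned_spaces <- function(n, k, D, dim = 5, sep = 6, seed = 1) {
  labels <- rep_len(seq_len(k), n)
  spaces <- lapply(seq_len(D), function(d) {
    set.seed(seed * 1000 + d)
    centers <- matrix(rnorm(k * dim), k, dim)
    centers <- centers * (sep / min(dist(centers)))
    centers[labels, , drop = FALSE] + matrix(rnorm(n * dim), n, dim)
  })
  Z <- structure(list(spaces = spaces, seed_record = seq_len(D),
                      mode = "direct"), class = "LatentSpaces")
  list(Z = Z, labels = labels)
}

random_partition <- function(n, k, seed, subspace = 1L, run = 1L) {
  set.seed(seed)
  lab <- c(seq_len(k), sample.int(k, n - k, replace = TRUE))
  base_partition(lab, k = k, subspace_index = subspace, run_index = run)
}

random_ensemble <- function(n, k, n_parts, seed, D = 1L) {
  parts <- lapply(seq_len(n_parts), function(i) {
    random_partition(n, k, seed + i,
                     subspace = ((i - 1L) %% D) + 1L,
                     run = ((i - 1L) %/% D) + 1L)
  })
  cluster_ensemble(parts)
}

tiny_counts_csv <- function(path) {
  df <- data.frame(cell_id = c("c1", "c2", "c3"),
                   gA = c(1, 0, 3), gB = c(2, 5, 0))
  write.csv(df, path, row.names = FALSE)
  path
}
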