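#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default. Defaults
#' mirror the method's reference settings: direction threshold
#' `eps_direction = -0.6`, balance rate `alpha = 13`, `max_fes = 20`
#' iterations, population of `n_flies = 9`, `T_runs = 10` base runs per
#' subspace, `d = 3` latent spaces, ECI factor `theta = 0.4`, one
#' optimizer restart.
#'
#' @param k number of clusters (NULL to require `k_range` estimation).
#' @param k_range integer vector scanned by [estimate_k()] (default 2:15).
#' @param d number of latent spaces.
#' @param latent_dim latent dimensionality.
#' @param n_keep informative genes kept by the NNKAE filter.
#' @param epochs_nnkae,epochs_vae autoencoder training lengths.
#' @param embedding_mode `"autoencoder"` or `"svd_fallback"`.
#' @param base_method `"uspec"`, `"louvain"` or `"leiden"`.
#' @param T_runs base-clustering runs per subspace.
#' @param p,K,mix_frac,sigma ultra-scalable spectral parameters.
#' @param resolution,knn community-detection parameters.
#' @param eps_direction silhouette threshold for the direction.
#' @param alpha,max_fes,n_flies,bounds,eps_smell pruner parameters.
#' @param theta ECI adjustment factor.
#' @param restarts independent pruner restarts (metrics averaged).
#' @param do_qc,do_log,do_minmax preprocessing switches.
#' @param min_cells,min_features,max_mito_frac,mito_prefix QC thresholds.
#' @param seed master seed for every stochastic stage.
#' @return list of class `RunConfig`.
#' @export
depf_config <- function(k = NULL, k_range = 2:15, d = 3L, latent_dim = 15L,
                        n_keep = 5000L, epochs_nnkae = 30L, epochs_vae = 1000L,
                        embedding_mode = "autoencoder",
                        base_method = "uspec", T_runs = 10L, p = NULL,
                        K = 5L, mix_frac = 0.5, sigma = "auto",
                        resolution = 1, knn = 15L, eps_direction = -0.6,
                        alpha = 13, max_fes = 20L, n_flies = 9L,
                        bounds = c(0, 2), eps_smell = 1e-6, theta = 0.4,
                        restarts = 1L, do_qc = TRUE, do_log = TRUE,
                        do_minmax = TRUE, min_cells = 3L,
                        min_features = 200L, max_mito_frac = 0.05,
                        mito_prefix = "MT-", seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "RunConfig")
}

preprocess <- function(X, config) {
  if (config$do_qc)
    X <- qc_filter(X, config$min_cells, config$min_features,
                   config$max_mito_frac, config$mito_prefix)
  if (config$do_log) X <- log_transform(X)
  if (config$do_minmax) X <- minmax_normalize(X)
  X
}

# Shared core: latent spaces -> ensemble -> initial consensus ->
# direction -> prune -> final consensus. Returns everything the report
# needs. `Z` may be passed pre-computed to skip embedding.
depf_core <- function(Z, k, config, restart_seed = config$seed) {
  ens <- generate_ensemble(Z, k = k, T_runs = config$T_runs,
                           method = config$base_method,
                           seed = derive_seed(restart_seed, 11L),
                           p = config$p, K = config$K,
                           mix_frac = config$mix_frac, sigma = config$sigma,
                           resolution = config$resolution, knn = config$knn)
  zcat <- do.call(cbind, Z$spaces)
  initial <- consensus_cluster(ens, k, config$theta)
  sil <- silhouette_report(initial$labels, zcat)
  dir <- decide_direction(sil, config$eps_direction)
  pr <- prune_ensemble(ens, Z, k, direction = dir,
                       max_fes = config$max_fes, alpha = config$alpha,
                       n_flies = config$n_flies, bounds = config$bounds,
                       theta = config$theta, eps_smell = config$eps_smell,
                       seed = derive_seed(restart_seed, 13L))
  final <- consensus_cluster(pr$pruned_ensemble, k, config$theta)
  list(ensemble = ens, initial = initial, silhouette = sil,
       direction = dir, pruning = pr, final = final, zcat = zcat)
}

#' Run the full clustering pipeline
#'
#' read/accept -> QC -> log1p -> per-cell min-max -> hierarchical
#' autoencoder latent spaces -> base-clustering ensemble -> initial
#' locally weighted consensus -> silhouette-directed bi-objective
#' fruit-fly pruning -> final consensus; NMI/ARI are reported when
#' ground-truth labels are supplied.
#'
#' @param X an [expression_matrix()] (or path readable by
#'   [read_matrix()]).
#' @param config a [depf_config()]; `config$k` must be set (use
#'   [estimate_k()] otherwise).
#' @param truth optional ground-truth label vector (after QC filtering
#'   it must align with the retained cells).
#' @return list of class `DepfRun`: `labels`, `partition`, `report`
#'   (direction, min_sc, msc, masks, metrics, seeds), `pruning`,
#'   `latent`, `cell_ids`.
#' @export
run_pipeline <- function(X, config = depf_config(), truth = NULL) {
  if (is.character(X)) X <- read_matrix(X)
  stopifnot(inherits(X, "ExpressionMatrix"))
  if (is.null(config$k))
    stopf("config$k is not set; supply k or run estimate_k()")
  n0 <- nrow(X$values)
  M <- preprocess(X, config)
  kept_cells <- match(M$cell_ids, X$cell_ids)
  if (!is.null(truth)) {
    if (length(truth) != n0)
      stopf("truth has %d labels but the input has %d cells", length(truth), n0)
    truth <- truth[kept_cells]
  }
  Z <- compute_latent_spaces(M, n_keep = config$n_keep,
                             latent_dim = config$latent_dim, d = config$d,
                             epochs_nnkae = config$epochs_nnkae,
                             epochs_vae = config$epochs_vae,
                             mode = config$embedding_mode,
                             seed = derive_seed(config$seed, 5L))
  restarts <- max(1L, config$restarts)
  runs <- lapply(seq_len(restarts), function(r) {
    depf_core(Z, config$k, config,
              restart_seed = derive_seed(config$seed, 17L, r))
  })
  core <- runs[[1]]
  metrics <- NULL
  if (!is.null(truth)) {
    per_run <- vapply(runs, function(cr)
      c(nmi(truth, cr$final$labels), ari(truth, cr$final$labels)), numeric(2))
    metrics <- list(nmi = per_run[1, 1], ari = per_run[2, 1],
                    nmi_mean = mean(per_run[1, ]), nmi_sd = stats::sd(per_run[1, ]),
                    ari_mean = mean(per_run[2, ]), ari_sd = stats::sd(per_run[2, ]))
  }
  final_sil <- silhouette_report(core$final$labels, core$zcat)
  report <- list(
    n_cells = length(core$final$labels), n_cells_input = n0,
    k = config$k, direction = core$direction,
    min_sc = core$silhouette$min_sc, initial_msc = core$silhouette$msc,
    final_msc = final_sil$msc,
    masks = core$pruning$selected,
    archive = core$pruning$archive,
    kept_partitions = length(core$pruning$pruned_ensemble$partitions),
    total_partitions = length(core$ensemble$partitions),
    metrics = metrics, seed = config$seed, restarts = restarts,
    embedding_mode = Z$mode, latent_seeds = Z$seed_record
  )
  structure(list(labels = core$final$labels, partition = core$final,
                 report = report, pruning = core$pruning, latent = Z,
                 trace = core$pruning$trace, cell_ids = M$cell_ids),
            class = "DepfRun")
}

#' @export
print.DepfRun <- function(x, ...) {
  r <- x$report
  cat(sprintf("DEPF run: %d cells -> %d clusters (direction %+d, MSC %.3f)\n",
              r$n_cells, r$k, r$direction, r$final_msc))
  if (!is.null(r$metrics))
    cat(sprintf("  NMI %.3f  ARI %.3f\n", r$metrics$nmi, r$metrics$ari))
  invisible(x)
}

#' Estimate the number of clusters by mean silhouette
#'
#' Scans `k_range`, running the ensemble + pruning + consensus core per
#' candidate k (with a reduced optimizer budget by default) on latent
#' spaces computed once, and scores each final partition by its mean
#' silhouette coefficient (MSC) in the concatenated latent space. One
#' swarm is assigned to each candidate k.
#'
#' @param X an [expression_matrix()] or a precomputed `LatentSpaces`
#'   object.
#' @param config a [depf_config()]; `config$k_range` is the scan range.
#' @param budget_fes optimizer iterations per candidate k (default 5;
#'   set to `config$max_fes` for the full budget).
#' @param T_scan base runs per subspace during the scan (default 3).
#' @param p_scan representatives per subspace during the scan (default
#'   200).
#' @return list of class `KEstimate`: `k_best`, `msc_curve`
#'   (data.frame k, msc), `labels` for the best k.
#' @export
estimate_k <- function(X, config = depf_config(), budget_fes = 5L,
                       T_scan = 3L, p_scan = 200L) {
  if (inherits(X, "LatentSpaces")) {
    Z <- X
  } else {
    M <- preprocess(X, config)
    Z <- compute_latent_spaces(M, n_keep = config$n_keep,
                               latent_dim = config$latent_dim, d = config$d,
                               epochs_nnkae = config$epochs_nnkae,
                               epochs_vae = config$epochs_vae,
                               mode = config$embedding_mode,
                               seed = derive_seed(config$seed, 5L))
  }
  n <- nrow(Z$spaces[[1]])
  k_range <- config$k_range
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  scan_cfg <- config
  scan_cfg$max_fes <- budget_fes
  scan_cfg$T_runs <- T_scan
  scan_cfg$p <- min(p_scan, n)
  results <- lapply(k_range, function(k) {
    core <- depf_core(Z, k, scan_cfg,
                      restart_seed = derive_seed(config$seed, 19L, k))
    sil <- silhouette_report(core$final$labels, core$zcat)
    list(k = k, msc = sil$msc, labels = core$final$labels)
  })
  curve <- data.frame(k = k_range,
                      msc = vapply(results, `[[`, numeric(1), "msc"))
  best <- which.max(curve$msc)
  structure(list(k_best = curve$k[best], msc_curve = curve,
                 labels = results[[best]]$labels),
            class = "KEstimate")
}

#' @export
print.KEstimate <- function(x, ...) {
  cat(sprintf("Estimated k = %d (MSC %.3f)\n", x$k_best,
              max(x$msc_curve$msc)))
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Writes `labels.csv` (cell_id, label), `report.json`, `trace.csv`
#' (per-iteration best objectives) and optionally `coassoc.csv`.
#'
#' @param run a [run_pipeline()] result.
#' @param outdir output directory (created if missing).
#' @param write_coassoc also export the co-association matrix (dense
#'   CSV; emits a warning above 5000 cells).
#' @return character vector of written paths, invisibly.
#' @export
write_outputs <- function(run, outdir, write_coassoc = FALSE) {
  stopifnot(inherits(run, "DepfRun"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- character()
  lab_path <- file.path(outdir, "labels.csv")
  write.csv(data.frame(cell_id = run$cell_ids, label = run$labels),
            lab_path, row.names = FALSE)
  paths <- c(paths, lab_path)
  rep_path <- file.path(outdir, "report.json")
  jsonlite::write_json(run$report, rep_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths <- c(paths, rep_path)
  tr_path <- file.path(outdir, "trace.csv")
  write.csv(run$trace, tr_path, row.names = FALSE)
  paths <- c(paths, tr_path)
  if (write_coassoc) {
    ca <- run$partition$coassoc
    ca <- if (inherits(ca, "CoAssociationMatrix")) ca$values else ca
    if (nrow(ca) > 5000)
      warning("co-association matrix exceeds 5000 cells; file will be large")
    ca_path <- file.path(outdir, "coassoc.csv")
    utils::write.table(ca, ca_path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    paths <- c(paths, ca_path)
  }
  invisible(paths)
}
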