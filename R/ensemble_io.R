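#' Export a clustering ensemble
#'
#' Writes the ensemble as a labels CSV (one row per cell, one column per
#' base partition, columns named `p1..pP`) plus a JSON sidecar listing
#' `(subspace_index, run_index, method, k)` per column. This pair is
#' also the input contract for running the pruner standalone on an
#' externally produced ensemble.
#'
#' @param ensemble a [cluster_ensemble()].
#' @param csv_path output CSV path.
#' @param json_path sidecar path (default: `csv_path` with `.json`).
#' @return invisibly, the two paths.
#' @export
write_ensemble <- function(ensemble, csv_path,
                           json_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(inherits(ensemble, "ClusterEnsemble"))
  labs <- do.call(cbind, lapply(ensemble$partitions, `[[`, "labels"))
  colnames(labs) <- paste0("p", seq_len(ncol(labs)))
  write.csv(as.data.frame(labs), csv_path, row.names = FALSE)
  meta <- lapply(ensemble$partitions, function(p)
    list(subspace_index = p$subspace_index, run_index = p$run_index,
         method = p$method, k = p$k))
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE)
  invisible(c(csv_path, json_path))
}

#' Import a clustering ensemble written by [write_ensemble()]
#'
#' @param csv_path labels CSV.
#' @param json_path metadata sidecar.
#' @return a [cluster_ensemble()].
#' @export
read_ensemble <- function(csv_path,
                          json_path = sub("\\.csv$", ".json", csv_path)) {
  labs <- as.matrix(read.csv(csv_path))
  meta <- jsonlite::read_json(json_path, simplifyVector = FALSE)
  if (length(meta) != ncol(labs))
    stopf("sidecar describes %d partitions but CSV has %d columns",
          length(meta), ncol(labs))
  parts <- lapply(seq_along(meta), function(i) {
    m <- meta[[i]]
    base_partition(labs[, i], k = m$k, subspace_index = m$subspace_index,
                   run_index = m$run_index, method = m$method)
  })
  cluster_ensemble(parts)
}
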