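#' Expression matrix container
#'
#' Lightweight S3 container for a cells x genes expression matrix with cell
#' and gene identifiers. Values must be non-negative (raw counts or
#' expression); the matrix may be dense (base `matrix`) or sparse
#' (`Matrix::dgCMatrix`), and sparsity is preserved through the
#' preprocessing steps that allow it.
#'
#' @param values numeric matrix, n cells x m genes, entries >= 0.
#' @param cell_ids character vector of length n, no duplicates.
#' @param gene_ids character vector of length m.
#' @return An object of class `ExpressionMatrix` with elements `values`,
#'   `cell_ids`, `gene_ids` and a `provenance` character vector recording
#'   applied processing steps.
#' @export
expression_matrix <- function(values, cell_ids = NULL, gene_ids = NULL) {
  if (is.null(dim(values))) stopf("`values` must be a matrix")
  n <- nrow(values); m <- ncol(values)
  if (is.null(cell_ids)) cell_ids <- rownames(values) %||% paste0("cell", seq_len(n))
  if (is.null(gene_ids)) gene_ids <- colnames(values) %||% paste0("gene", seq_len(m))
  if (length(cell_ids) != n) stopf("cell_ids length %d != %d rows", length(cell_ids), n)
  if (length(gene_ids) != m) stopf("gene_ids length %d != %d columns", length(gene_ids), m)
  if (anyDuplicated(cell_ids)) stopf("duplicate cell_ids are not allowed")
  if (min_value(values) < 0) stopf("expression values must be non-negative")
  structure(
    list(values = values, cell_ids = as.character(cell_ids),
         gene_ids = as.character(gene_ids), provenance = character()),
    class = "ExpressionMatrix"
  )
}

min_value <- function(x) {
  if (inherits(x, "sparseMatrix")) {
    if (length(x@x) == 0) return(0)
    min(0, min(x@x))
  } else {
    if (length(x) == 0) 0 else min(x)
  }
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes (%s)\n",
              nrow(x$values), ncol(x$values),
              if (inherits(x$values, "sparseMatrix")) "sparse" else "dense"))
  if (length(x$provenance))
    cat("  steps:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Read an expression matrix from disk
#'
#' Supports the 10x-style Matrix Market triplet dialect (`matrix.mtx` with
#' adjacent `barcodes.tsv` and `features.tsv`/`genes.tsv`, plain or
#' gzipped) and dense CSV/TSV with a header row. The returned matrix is
#' always oriented cells x genes; use `orientation` to declare how the
#' file is laid out.
#'
#' @param path path to the `.mtx`/`.csv`/`.tsv` file (or the directory
#'   containing a 10x triplet).
#' @param format `"mtx_triplet"` or `"csv_dense"`.
#' @param orientation `"cells_rows"` or `"genes_rows"` (10x triplets are
#'   conventionally genes x cells, i.e. `"genes_rows"`).
#' @return An [expression_matrix()].
#' @export
read_matrix <- function(path, format = c("mtx_triplet", "csv_dense"),
                        orientation = c("cells_rows", "genes_rows")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "mtx_triplet") {
    read_mtx_triplet(path, orientation)
  } else {
    read_csv_dense(path, orientation)
  }
}

find_companion <- function(dir, stems) {
  for (stem in stems) for (ext in c("", ".gz")) {
    f <- file.path(dir, paste0(stem, ext))
    if (file.exists(f)) return(f)
  }
  NULL
}

read_mtx_triplet <- function(path, orientation) {
  if (dir.exists(path)) {
    mtx <- find_companion(path, c("matrix.mtx"))
    if (is.null(mtx)) stopf("no matrix.mtx under %s", path)
    path <- mtx
  }
  dir <- dirname(path)
  # validate the coordinate header / entry count before delegating
  con <- file(path, "r"); on.exit(close(con))
  hdr <- readLines(con, n = 1)
  if (!grepl("^%%MatrixMarket\\s+matrix\\s+coordinate", hdr))
    stopf("malformed MatrixMarket header: '%s'", hdr)
  repeat {
    ln <- readLines(con, n = 1)
    if (!length(ln)) stopf("truncated mtx file: %s", path)
    if (!startsWith(ln, "%")) break
  }
  dims <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
  if (length(dims) != 3 || anyNA(dims))
    stopf("malformed mtx size line: '%s'", ln)
  n_entries <- length(count.fields(con, comment.char = "%"))
  if (n_entries != dims[3])
    stopf("mtx declares %d entries but contains %d", dims[3], n_entries)
  m <- Matrix::readMM(path)
  m <- methods::as(m, "CsparseMatrix")
  bc <- find_companion(dir, c("barcodes.tsv", "barcodes.txt"))
  ft <- find_companion(dir, c("features.tsv", "genes.tsv", "features.txt"))
  barcodes <- if (!is.null(bc)) read.delim(bc, header = FALSE)[[1]] else NULL
  features <- if (!is.null(ft)) read.delim(ft, header = FALSE)[[1]] else NULL
  if (orientation == "genes_rows") m <- Matrix::t(m)
  n <- nrow(m); g <- ncol(m)
  if (!is.null(barcodes) && length(barcodes) != n)
    stopf("barcodes file lists %d cells but matrix has %d", length(barcodes), n)
  if (!is.null(features) && length(features) != g)
    stopf("features file lists %d genes but matrix has %d", length(features), g)
  expression_matrix(m, cell_ids = barcodes, gene_ids = features)
}

read_csv_dense <- function(path, orientation) {
  sep <- if (grepl("\\.tsv(\\.gz)?$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE)
  first_chr <- is.character(df[[1]]) && anyNA(suppressWarnings(as.numeric(df[[1]])))
  if (first_chr) {
    ids <- df[[1]]
    mat <- as.matrix(df[, -1, drop = FALSE])
    rownames(mat) <- ids
  } else {
    mat <- as.matrix(df)
  }
  storage.mode(mat) <- "double"
  if (anyNA(mat)) stopf("non-numeric entries in %s", path)
  if (orientation == "genes_rows") mat <- t(mat)
  expression_matrix(mat)
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_matrix()]: either a Matrix Market triplet (with
#' `barcodes.tsv`/`features.tsv` companions) or a dense CSV with cells in
#' rows and gene names in the header.
#'
#' @param X an [expression_matrix()].
#' @param path output file (`csv_dense`) or directory (`mtx_triplet`).
#' @param format output dialect; mtx triplets are written genes x cells as
#'   in the 10x convention.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(X, path, format = c("mtx_triplet", "csv_dense")) {
  format <- match.arg(format)
  stopifnot(inherits(X, "ExpressionMatrix"))
  if (format == "mtx_triplet") {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    m <- Matrix::Matrix(as.matrix(X$values), sparse = TRUE)
    m <- methods::as(m, "generalMatrix")
    Matrix::writeMM(Matrix::t(m), file.path(path, "matrix.mtx"))
    writeLines(X$cell_ids, file.path(path, "barcodes.tsv"))
    writeLines(X$gene_ids, file.path(path, "features.tsv"))
  } else {
    mat <- as.matrix(X$values)
    df <- data.frame(cell_id = X$cell_ids, mat, check.names = FALSE)
    colnames(df) <- c("cell_id", X$gene_ids)
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Quality-control filtering of cells and genes
#'
#' Applies the standard Seurat-style filters: genes expressed in fewer
#' than `min_cells` cells are removed first; then cells expressing fewer
#' than `min_features` retained genes, and cells whose fraction of counts
#' on mitochondrial genes (gene id matching `mito_prefix`,
#' case-insensitive) exceeds `max_mito_frac`, are removed.
#'
#' @param X an [expression_matrix()] of raw counts.
#' @param min_cells genes must be detected in at least this many cells.
#' @param min_features cells must express at least this many genes.
#' @param max_mito_frac maximum tolerated mitochondrial count fraction,
#'   in `[0, 1]`.
#' @param mito_prefix gene-id prefix marking mitochondrial genes.
#' @return A filtered [expression_matrix()].
#' @export
qc_filter <- function(X, min_cells = 3, min_features = 200,
                      max_mito_frac = 0.05, mito_prefix = "MT-") {
  stopifnot(inherits(X, "ExpressionMatrix"))
  if (min_cells < 0 || min_features < 0) stopf("thresholds must be >= 0")
  if (max_mito_frac < 0 || max_mito_frac > 1) stopf("max_mito_frac must lie in [0, 1]")
  v <- X$values
  gene_ncells <- Matrix::colSums(v > 0)
  keep_g <- gene_ncells >= min_cells
  v <- v[, keep_g, drop = FALSE]
  gene_ids <- X$gene_ids[keep_g]

  n_feat <- Matrix::rowSums(v > 0)
  is_mito <- grepl(paste0("^", mito_prefix), gene_ids, ignore.case = TRUE)
  tot <- Matrix::rowSums(v)
  mito_frac <- ifelse(tot > 0,
                      Matrix::rowSums(v[, is_mito, drop = FALSE]) / pmax(tot, 1), 0)
  keep_c <- n_feat >= min_features & mito_frac <= max_mito_frac
  if (!any(keep_c))
    stopf(paste("QC removed every cell; relax min_features (%d) or",
                "max_mito_frac (%.3f)"), min_features, max_mito_frac)
  out <- expression_matrix(v[keep_c, , drop = FALSE],
                           cell_ids = X$cell_ids[keep_c], gene_ids = gene_ids)
  out$provenance <- c(X$provenance,
                      sprintf("qc(min_cells=%d,min_features=%d,max_mito=%.3g)",
                              min_cells, min_features, max_mito_frac))
  out
}

#' Log transformation
#'
#' Replaces every entry by `log(1 + x)`. Zeros map to zero, so sparsity
#' is preserved.
#'
#' @param X an [expression_matrix()] with non-negative values.
#' @return The transformed [expression_matrix()].
#' @export
log_transform <- function(X) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  if (min_value(X$values) < 0) stopf("log transform requires non-negative values")
  v <- X$values
  if (inherits(v, "sparseMatrix")) v@x <- log1p(v@x) else v <- log1p(v)
  X$values <- v
  X$provenance <- c(X$provenance, "log1p")
  X
}

#' Per-cell min-max normalization
#'
#' Rescales each cell row linearly to `[0, 1]`:
#' `M[i, j] = (X[i, j] - min_j X[i, .]) / (max_j X[i, .] - min_j X[i, .])`.
#' A cell with zero range (all entries equal) carries no contrast between
#' genes and is mapped to an all-zero row.
#'
#' @param X an [expression_matrix()].
#' @return An [expression_matrix()] with class `NormalizedMatrix`
#'   prepended; entries in `[0, 1]`, dense.
#' @export
minmax_normalize <- function(X) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  v <- as.matrix(X$values)
  if (nrow(v) == 0 || ncol(v) == 0) stopf("cannot normalize an empty matrix")
  lo <- apply(v, 1, min)
  hi <- apply(v, 1, max)
  rng <- hi - lo
  scl <- ifelse(rng > 0, 1 / rng, 0)
  M <- (v - lo) * scl
  out <- X
  out$values <- M
  out$provenance <- c(X$provenance, "minmax")
  class(out) <- c("NormalizedMatrix", "ExpressionMatrix")
  out
}

#' Read a label file aligned to cell ids
#'
#' Accepts a one-label-per-line file or a two-column CSV
#' (`cell_id,label`); an optional header naming the last column `label`
#' (or similar) is skipped. The last comma-separated field of each line
#' is taken as the label.
#'
#' @param path path to the label file.
#' @return character vector of labels.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  x <- readLines(path)
  x <- x[nzchar(trimws(x))]
  lab <- vapply(strsplit(x, ","), function(f) trimws(f[length(f)]), character(1))
  lab <- gsub('^"|"$', "", lab)
  if (length(lab) && tolower(lab[1]) %in% c("label", "labels", "cluster")) lab <- lab[-1]
  lab
}
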