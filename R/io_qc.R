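# Count-matrix IO, validation, the standard gene/cell filters, and the
# depth-correlation QC check.

.validate_counts <- function(m) {
  if ((nrow(m) > 0 && is.null(rownames(m))) ||
      (ncol(m) > 0 && is.null(colnames(m))))
    stop("count matrix must carry gene (row) and cell (column) identifiers",
         call. = FALSE)
  if (anyDuplicated(rownames(m))) stop("duplicate gene identifiers", call. = FALSE)
  if (anyDuplicated(colnames(m))) stop("duplicate cell identifiers", call. = FALSE)
  v <- if (methods::is(m, "sparseMatrix")) m@x else as.vector(m)
  if (length(v) && (any(v < 0) || any(v != round(v))))
    stop("count matrix entries must be nonnegative integers", call. = FALSE)
  invisible(m)
}

#' Read a gene-by-cell count matrix
#'
#' Accepts either a 10x-style triplet directory (`matrix.mtx` +
#' `features.tsv` + `barcodes.tsv`, MatrixMarket 1-based coordinates) or a
#' dense TSV with gene ids in the first column and cell ids in the header.
#'
#' @param path Directory or TSV file path.
#' @return A sparse `dgCMatrix` (genes x cells) with gene/cell dimnames.
#' @export
read_counts <- function(path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    feat <- file.path(path, "features.tsv")
    barc <- file.path(path, "barcodes.tsv")
    if (!all(file.exists(mtx, feat, barc)))
      stop("triplet directory must contain matrix.mtx, features.tsv, barcodes.tsv",
           call. = FALSE)
    m <- tryCatch(Matrix::readMM(mtx),
                  error = function(e) stop("malformed matrix.mtx: ",
                                           conditionMessage(e), call. = FALSE))
    genes <- utils::read.table(feat, sep = "\t", stringsAsFactors = FALSE)[[1]]
    cells <- utils::read.table(barc, sep = "\t", stringsAsFactors = FALSE)[[1]]
    if (nrow(m) != length(genes))
      stop("features.tsv has ", length(genes), " entries but matrix declares ",
           nrow(m), " rows", call. = FALSE)
    if (ncol(m) != length(cells))
      stop("barcodes.tsv has ", length(cells), " entries but matrix declares ",
           ncol(m), " columns", call. = FALSE)
    m <- methods::as(m, "CsparseMatrix")
    m <- methods::as(m, "dMatrix")
    dimnames(m) <- list(genes, cells)
  } else if (file.exists(path)) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             row.names = 1, check.names = FALSE)
    m <- Matrix::Matrix(as.matrix(tab), sparse = TRUE)
  } else stop("no such file or directory: ", path, call. = FALSE)
  .validate_counts(m)
  m
}

#' Write a count matrix as a 10x-style triplet directory
#'
#' Emits `matrix.mtx` in MatrixMarket coordinate integer format (1-based
#' indices), plus `features.tsv` and `barcodes.tsv`. `Matrix::writeMM` is not
#' used because it types numeric sparse matrices as `real`.
#'
#' @param counts Genes x cells matrix of nonnegative integers with dimnames.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts <- function(counts, dir) {
  .validate_counts(counts)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(counts, "TsparseMatrix")
  con <- file(file.path(dir, "matrix.mtx"), "w")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               paste(nrow(m), ncol(m), length(m@x))), con)
  if (length(m@x)) {
    o <- order(m@j, m@i)
    writeLines(paste(m@i[o] + 1L, m@j[o] + 1L,
                     format(m@x[o], scientific = FALSE, trim = TRUE)), con)
  }
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Filter genes and cells by detection thresholds
#'
#' Keeps genes detected (count > 0) in at least `min_cells_per_gene` cells,
#' then, on the reduced matrix, cells with at least `min_genes_per_cell`
#' detected genes. The defaults (3 cells, 100 genes) are the conventional
#' droplet-data thresholds. A single ordered pass is the default; set
#' `iterate = TRUE` to repeat the pass until a fixpoint.
#'
#' @param counts Genes x cells count matrix.
#' @param min_cells_per_gene Minimum cells in which a gene must be detected.
#' @param min_genes_per_cell Minimum detected genes a cell must have.
#' @param iterate Repeat gene/cell passes to a fixpoint (default FALSE).
#' @return The filtered matrix (possibly with zero rows or columns).
#' @export
filter_counts <- function(counts, min_cells_per_gene = 3L,
                          min_genes_per_cell = 100L, iterate = FALSE) {
  .validate_counts(counts)
  repeat {
    d0 <- dim(counts)
    gk <- Matrix::rowSums(counts > 0) >= min_cells_per_gene
    counts <- counts[gk, , drop = FALSE]
    ck <- Matrix::colSums(counts > 0) >= min_genes_per_cell
    counts <- counts[, ck, drop = FALSE]
    if (!iterate || all(dim(counts) == d0)) break
  }
  counts
}

#' Per-group correlation between sequencing depth and detected genes
#'
#' For each group of cells (by default each cell type), computes the Pearson
#' correlation between per-cell total counts and per-cell number of detected
#' genes -- a standard droplet QC diagnostic. Reported for the raw matrix
#' and, for comparison, after per-cell library-size scaling (each cell scaled
#' to the median total). Scaling makes totals exactly constant, so the scaled
#' correlation is degenerate and reported as `NA`; it is retained to make the
#' before/after contrast explicit.
#'
#' @param counts Genes x cells count matrix.
#' @param meta Cell metadata data frame with a `cell_id` column, or `NULL`
#'   to treat all cells as one group.
#' @param group_by Metadata column defining the groups (default
#'   `"cell_type"`).
#' @return Data frame with columns group, n_cells, r_raw, r_scaled. Groups
#'   with fewer than 3 cells or zero variance in either quantity get `NA`.
#' @export
depth_correlation <- function(counts, meta = NULL, group_by = "cell_type") {
  .validate_counts(counts)
  totals <- Matrix::colSums(counts)
  ngene <- Matrix::colSums(counts > 0)
  if (is.null(meta)) {
    grp <- factor(rep("all", ncol(counts)))
  } else {
    stopifnot(group_by %in% names(meta), "cell_id" %in% names(meta))
    idx <- match(colnames(counts), meta$cell_id)
    if (anyNA(idx)) stop("metadata missing some cells", call. = FALSE)
    grp <- factor(meta[[group_by]][idx])
  }
  sf <- totals / stats::median(totals)
  totals_scaled <- totals / ifelse(sf > 0, sf, 1)
  safe_cor <- function(x, y) {
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(NA_real_)
    stats::cor(x, y)
  }
  res <- lapply(levels(grp), function(g) {
    i <- grp == g
    data.frame(group = g, n_cells = sum(i),
               r_raw = safe_cor(totals[i], ngene[i]),
               r_scaled = safe_cor(totals_scaled[i], ngene[i]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Read cell metadata from TSV
#'
#' @param path TSV with header; requires columns cell_id, sample_id, sex,
#'   cell_type (replicate optional).
#' @param counts Optional companion count matrix for cross-validation.
#' @return Validated data frame.
#' @export
read_metadata <- function(path, counts = NULL) {
  meta <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  validate_metadata(meta, counts)
}

#' Validate cell metadata against its count matrix
#'
#' Checks required columns, that sex is female/male for every cell, that each
#' sample maps to exactly one sex, and (if `counts` is given) that every cell
#' in the matrix is described.
#'
#' @param meta Metadata data frame.
#' @param counts Optional count matrix.
#' @return `meta`, invisibly usable.
#' @export
validate_metadata <- function(meta, counts = NULL) {
  need <- c("cell_id", "sample_id", "sex", "cell_type")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(meta$sex %in% c("female", "male")) || anyNA(meta$sex))
    stop("`sex` must be 'female' or 'male' for every cell", call. = FALSE)
  sx <- unique(meta[c("sample_id", "sex")])
  if (anyDuplicated(sx$sample_id))
    stop("a sample_id maps to more than one sex", call. = FALSE)
  if (!is.null(counts)) {
    missing_cells <- setdiff(colnames(counts), meta$cell_id)
    if (length(missing_cells))
      stop(length(missing_cells),
           " cell(s) in the count matrix lack metadata", call. = FALSE)
  }
  meta
}
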