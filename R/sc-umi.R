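#' Sparse UMI matrix container
#'
#' Cells (rows) by genes (columns) sparse integer counts plus a mitochondrial
#' flag per gene and optional per-cell metadata (e.g. a timepoint tag).
#'
#' @param counts a `Matrix::dgCMatrix` (or coercible), cells x genes, with
#'   dimnames (barcodes, gene symbols).
#' @param mito_genes either a logical vector per gene or a prefix rule applied
#'   to gene symbols (default `"mt-"`, the mouse convention).
#' @param cell_metadata optional tibble with one row per cell.
#' @return A `umi_matrix` object.
#' @export
umi_matrix <- function(counts, mito_genes = "mt-", cell_metadata = NULL) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_cd8("counts need barcode row names and gene column names", "bad_argument")
  }
  if (any(counts@x < 0) || any(counts@x != floor(counts@x))) {
    stop_cd8("UMI counts must be non-negative integers", "bad_argument")
  }
  mito <- if (is.logical(mito_genes)) {
    if (length(mito_genes) != ncol(counts)) {
      stop_cd8("logical `mito_genes` must have one entry per gene", "bad_argument")
    }
    mito_genes
  } else {
    startsWith(tolower(colnames(counts)), tolower(mito_genes))
  }
  structure(list(counts = counts, mito = stats::setNames(mito, colnames(counts)),
                 cell_metadata = cell_metadata),
            class = "umi_matrix")
}

#' @export
print.umi_matrix <- function(x, ...) {
  cat(sprintf("<umi_matrix> %d cells x %d genes (%.2f%% non-zero, %d mito genes)\n",
              nrow(x$counts), ncol(x$counts),
              100 * length(x$counts@x) / prod(dim(x$counts)), sum(x$mito)))
  invisible(x)
}

#' @export
dim.umi_matrix <- function(x) dim(x$counts)

#' Read a MatrixMarket UMI triplet (MTX + barcodes + features)
#'
#' The 10x-style trio: an MTX file with genes as rows and cells as columns,
#' one barcode per line, one feature per line (first tab-separated field used
#' as the gene symbol). The matrix is transposed to the cells x genes
#' orientation used throughout.
#'
#' @param mtx,barcodes,features file paths.
#' @param mito_prefix gene-symbol prefix flagging mitochondrial genes.
#' @return A [umi_matrix()].
#' @export
read_umi_mtx <- function(mtx, barcodes, features, mito_prefix = "mt-") {
  m <- Matrix::readMM(mtx)
  bc <- readLines(barcodes)
  ft <- vapply(strsplit(readLines(features), "\t", fixed = TRUE), `[[`, "", 1L)
  if (nrow(m) != length(ft) || ncol(m) != length(bc)) {
    stop_cd8(sprintf("MTX is %d x %d but %d features / %d barcodes supplied",
                     nrow(m), ncol(m), length(ft), length(bc)), "bad_format")
  }
  m <- Matrix::t(m)
  dimnames(m) <- list(bc, ft)
  umi_matrix(m, mito_genes = mito_prefix)
}

#' Write a UMI matrix as MTX + barcodes + features
#'
#' @param x a [umi_matrix()].
#' @param mtx,barcodes,features output paths.
#' @return `mtx`, invisibly.
#' @export
write_umi_mtx <- function(x, mtx, barcodes, features) {
  Matrix::writeMM(Matrix::t(x$counts), mtx)
  writeLines(rownames(x$counts), barcodes)
  writeLines(colnames(x$counts), features)
  invisible(mtx)
}

#' Sequential single-cell quality-control filtering
#'
#' Applies the four QC filters in their documented order, each on the matrix
#' as it stands after the previous step:
#' 1. remove cells detecting fewer than `min_genes` genes;
#' 2. remove genes detected in fewer than `min_cells` cells;
#' 3. remove cells detecting more than `max_genes` genes;
#' 4. remove cells whose mitochondrial UMI fraction exceeds `max_mito`.
#'
#' The mitochondrial fraction is computed per cell on the input matrix,
#' before any filtering. Removal counts are order-dependent; the report
#' records the tally per step so the accounting is exact.
#'
#' @param x a [umi_matrix()].
#' @param min_genes,min_cells,max_genes,max_mito thresholds (defaults 200, 3,
#'   6100 and 0.07 — the study's printed values). All must be positive.
#' @return A list: `umi` (filtered [umi_matrix()]) and `report`, a
#'   `qc_report` tibble with one row per step (`step`, `axis`, `removed`,
#'   `cells_after`, `genes_after`).
#' @export
qc_filter <- function(x, min_genes = 200, min_cells = 3,
                      max_genes = 6100, max_mito = 0.07) {
  stopifnot(inherits(x, "umi_matrix"))
  if (any(c(min_genes, min_cells, max_genes, max_mito) <= 0)) {
    stop_cd8("QC thresholds must be positive", "bad_argument")
  }
  m <- x$counts
  mito_frac <- if (any(x$mito)) {
    as.numeric(Matrix::rowSums(m[, x$mito, drop = FALSE]) / pmax(Matrix::rowSums(m), 1))
  } else {
    numeric(nrow(m))
  }
  names(mito_frac) <- rownames(m)
  steps <- list()
  note <- function(step, axis, removed) {
    steps[[length(steps) + 1L]] <<- tibble(
      step = step, axis = axis, removed = removed,
      cells_after = nrow(m), genes_after = ncol(m))
  }

  genes_per_cell <- Matrix::rowSums(m > 0)
  drop <- genes_per_cell < min_genes
  m <- m[!drop, , drop = FALSE]
  note("cells_min_genes", "cells", sum(drop))

  cells_per_gene <- Matrix::colSums(m > 0)
  dropg <- cells_per_gene < min_cells
  m <- m[, !dropg, drop = FALSE]
  note("genes_min_cells", "genes", sum(dropg))

  genes_per_cell <- Matrix::rowSums(m > 0)
  drop <- genes_per_cell > max_genes
  m <- m[!drop, , drop = FALSE]
  note("cells_max_genes", "cells", sum(drop))

  drop <- mito_frac[rownames(m)] > max_mito
  m <- m[!drop, , drop = FALSE]
  note("cells_max_mito", "cells", sum(drop))

  report <- bind_rows(steps)
  attr(report, "before") <- dim(x$counts)
  attr(report, "after") <- dim(m)
  class(report) <- c("qc_report", class(report))
  meta <- x$cell_metadata
  if (!is.null(meta)) meta <- meta[match(rownames(m), rownames(x$counts)), , drop = FALSE]
  list(umi = umi_matrix(m, mito_genes = unname(x$mito[colnames(m)]),
                        cell_metadata = meta),
       report = report)
}

#' Counts-per-10k normalization with log1p
#'
#' Scales each cell to `scale_factor` total counts then applies `log1p`; the
#' standard pre-processing ahead of HVG selection and regression.
#'
#' @param x a [umi_matrix()].
#' @param scale_factor per-cell target total (default 1e4).
#' @param log1p apply `log1p` after scaling?
#' @return A dense matrix, cells x genes.
#' @export
normalize_per_cell <- function(x, scale_factor = 1e4, log1p = TRUE) {
  stopifnot(inherits(x, "umi_matrix"))
  totals <- Matrix::rowSums(x$counts)
  if (any(totals == 0)) {
    stop_cd8(paste0("cell(s) with zero counts: ",
                    paste(utils::head(rownames(x$counts)[totals == 0], 5L),
                          collapse = ", ")), "bad_argument")
  }
  out <- as.matrix(x$counts / totals * scale_factor)
  if (log1p) out <- log1p(out)
  out
}
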