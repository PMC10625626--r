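#' Protein intensity matrix with group labels
#'
#' Container for a label-free quantification matrix: proteins (rows) by
#' samples (columns), with an explicit missing-value mask (`NA` entries) and a
#' control/knockout group label per sample. Missing values are carried, never
#' imputed: downstream analyses decide how to treat them.
#'
#' @param values numeric matrix, proteins x samples, non-negative; `NA` marks
#'   a missing (not-quantified) entry. Row names are feature identifiers,
#'   column names are sample identifiers.
#' @param groups named character vector mapping every sample to its group
#'   (conventionally `"control"` / `"knockout"`, but any two labels work).
#' @param annotations optional tibble with columns `feature` and any of
#'   `molecular_weight` (g/mol), `is_histone` (logical), `gene_symbol`.
#'
#' @return An `intensity_matrix` object.
#' @export
intensity_matrix <- function(values, groups, annotations = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_cd8("`values` must be a numeric matrix", "bad_argument")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_cd8("`values` must carry feature row names and sample column names",
             "bad_argument")
  }
  if (anyDuplicated(rownames(values))) {
    dups <- unique(rownames(values)[duplicated(rownames(values))])
    stop_cd8(paste0("duplicate feature ids: ", paste(dups, collapse = ", ")),
             "duplicate_features")
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop_cd8("intensities must be non-negative", "bad_argument")
  }
  groups <- groups[colnames(values)]
  if (anyNA(names(groups)) || anyNA(groups)) {
    stop_cd8("every sample needs exactly one group label", "bad_argument")
  }
  structure(
    list(values = values, groups = groups, annotations = annotations),
    class = "intensity_matrix"
  )
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("<intensity_matrix> %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$groups)
  cat("  groups: ", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  missing: %.1f%%\n", 100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' Read a tab-delimited intensity table
#'
#' First column is the feature identifier, remaining columns are samples
#' (header row carries sample ids). Cells equal to `missing_marker` become
#' masked (`NA`) entries — they are not zeros. Feature order is preserved.
#'
#' @param path file path or connection.
#' @param groups named character vector of group labels per sample.
#' @param missing_marker string marking a missing cell (default `"NA"`).
#' @param annotations optional annotation tibble (see [intensity_matrix()]).
#' @return An [intensity_matrix()].
#' @export
read_intensity_table <- function(path, groups, missing_marker = "NA",
                                 annotations = NULL) {
  raw <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  if (ncol(raw) < 2L) stop_cd8("need a feature column plus >= 1 sample", "bad_format")
  ids <- raw[[1L]]
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    stop_cd8(paste0("duplicate feature ids: ", paste(dups, collapse = ", ")),
             "duplicate_features")
  }
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  is_missing <- cells == missing_marker
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num) & !is_missing, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop_cd8(sprintf(
      "non-numeric cell '%s' at row %d (feature %s), column %s",
      cells[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L], ids[bad[1L, 1L]],
      colnames(cells)[bad[1L, 2L]]), "bad_cell")
  }
  num[is_missing] <- NA_real_
  dimnames(num) <- list(ids, colnames(cells))
  intensity_matrix(num, groups = groups, annotations = annotations)
}

#' Write an intensity matrix as a tab-delimited table
#'
#' Inverse of [read_intensity_table()]: full-precision values (17 significant
#' digits), missing entries written as `missing_marker`.
#'
#' @param x an [intensity_matrix()].
#' @param path output path.
#' @param missing_marker string to write for masked entries.
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(x, path, missing_marker = "NA") {
  stopifnot(inherits(x, "intensity_matrix"))
  chr <- matrix(sprintf("%.17g", x$values), nrow = nrow(x$values))
  chr[is.na(x$values)] <- missing_marker
  lines <- c(
    paste(c("feature", colnames(x$values)), collapse = "\t"),
    paste(rownames(x$values), apply(chr, 1L, paste, collapse = "\t"), sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Equalize per-sample medians on the log2 scale
#'
#' Cross-run normalization: each sample column is scaled multiplicatively so
#' that the median of its present (non-missing, positive) values equals the
#' geometric mean of the per-sample medians — on the log2 scale, each sample's
#' median log intensity is shifted to the common value. The missing mask is
#' unchanged. This stands in for vendor-side cross-run normalization and can
#' be skipped by simply not calling it.
#'
#' @param x an [intensity_matrix()].
#' @return A normalized [intensity_matrix()].
#' @export
median_normalize <- function(x) {
  stopifnot(inherits(x, "intensity_matrix"))
  v <- x$values
  pos <- v
  pos[pos == 0] <- NA_real_  # zeros are non-detections, excluded from the median
  all_missing <- colSums(!is.na(pos)) == 0L
  if (any(all_missing)) {
    stop_cd8(paste0("sample(s) with no present values: ",
                    paste(colnames(v)[all_missing], collapse = ", ")),
             "all_missing_sample")
  }
  med <- apply(pos, 2L, stats::median, na.rm = TRUE)
  target <- 2^mean(log2(med))  # geometric mean keeps the factor scale-free
  out <- sweep(v, 2L, target / med, `*`)  # multiplicative: mask and zeros unchanged
  intensity_matrix(out, groups = x$groups, annotations = x$annotations)
}
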