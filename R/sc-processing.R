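#' Highly variable gene selection by binned dispersion
#'
#' Per-gene dispersion = variance / mean on the normalized, log1p-transformed
#' matrix. Genes are binned by mean expression (`n_bins` equal-occupancy
#' bins) and the dispersion is standardized within each bin
#' (`(dispersion - bin mean) / bin sd`), so a gene is "highly variable"
#' relative to genes of comparable expression. Bins with fewer than two genes
#' keep the raw dispersion. Selection is deterministic: ties break by gene
#' identifier.
#'
#' @param norm_matrix dense cells x genes matrix from [normalize_per_cell()].
#' @param n_top number of genes to return (ranked by standardized
#'   dispersion), or `NULL` to use `min_dispersion`.
#' @param min_dispersion standardized-dispersion cutoff when `n_top` is NULL.
#' @param n_bins number of mean-expression bins.
#' @return Character vector of selected gene names, with attribute `stats`
#'   (tibble: gene, mean, dispersion, dispersion_norm).
#' @export
select_hvg <- function(norm_matrix, n_top = NULL, min_dispersion = 1,
                       n_bins = 20) {
  mu <- colMeans(norm_matrix)
  v <- apply(norm_matrix, 2L, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  if (!is.null(n_top) && n_top > ncol(norm_matrix)) {
    stop_cd8(sprintf("asked for %d genes but only %d available",
                     n_top, ncol(norm_matrix)), "bad_argument")
  }
  bins <- cut(rank(mu, ties.method = "first"),
              breaks = max(1L, min(n_bins, ncol(norm_matrix))),
              labels = FALSE)
  disp_norm <- disp
  for (b in unique(bins)) {
    i <- bins == b
    if (sum(i) >= 2L && stats::sd(disp[i]) > 0) {
      disp_norm[i] <- (disp[i] - mean(disp[i])) / stats::sd(disp[i])
    }
  }
  stats_tbl <- tibble(gene = colnames(norm_matrix), mean = unname(mu),
                      dispersion = unname(disp),
                      dispersion_norm = unname(disp_norm)) |>
    arrange(desc(.data$dispersion_norm), .data$gene)
  selected <- if (is.null(n_top)) {
    stats_tbl$gene[stats_tbl$dispersion_norm >= min_dispersion &
                     stats_tbl$dispersion > 0]
  } else {
    utils::head(stats_tbl$gene[stats_tbl$dispersion > 0], n_top)
  }
  attr(selected, "stats") <- stats_tbl
  selected
}

#' Regress technical covariates out of an expression matrix
#'
#' Ordinary least squares of every gene on the supplied per-cell covariates
#' (with intercept); residuals are returned. Residuals have zero sample
#' correlation with each covariate. Constant covariates are dropped with a
#' warning.
#'
#' @param matrix dense cells x genes expression matrix.
#' @param covariates data frame / tibble of per-cell covariates, e.g. total
#'   counts and mitochondrial fraction.
#' @return Residual matrix, same shape and dimnames.
#' @export
regress_out <- function(matrix, covariates) {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != nrow(matrix)) {
    stop_cd8("one covariate row per cell required", "bad_argument")
  }
  constant <- vapply(covariates, function(v) stats::var(v) == 0, TRUE)
  if (any(constant)) {
    rlang::warn(paste0("dropping constant covariate(s): ",
                       paste(names(covariates)[constant], collapse = ", ")))
    covariates <- covariates[, !constant, drop = FALSE]
  }
  X <- cbind(intercept = 1, as.matrix(covariates))
  # residual-maker applied to all genes at once
  beta <- solve(crossprod(X), crossprod(X, matrix))
  res <- matrix - X %*% beta
  dimnames(res) <- dimnames(matrix)
  res
}

#' Scale genes to unit variance and clip extremes
#'
#' Each gene (column) is centered and scaled to unit variance, then values
#' beyond `max_sd` standard deviations are clipped to `[-max_sd, max_sd]`
#' (set `clip_lower = FALSE` for the upper-only clipping some toolchains
#' apply). Zero-variance genes are left at zero and flagged in the
#' `zero_variance` attribute.
#'
#' @param matrix dense cells x genes matrix (typically residuals from
#'   [regress_out()]).
#' @param max_sd clipping bound in standard deviations (default 10).
#' @param clip_lower clip the negative tail too (default TRUE, symmetric).
#' @return Scaled matrix with attribute `zero_variance` (gene names).
#' @export
scale_clip <- function(matrix, max_sd = 10, clip_lower = TRUE) {
  mu <- colMeans(matrix)
  sdv <- apply(matrix, 2L, stats::sd)
  zero <- sdv == 0
  sdv[zero] <- 1
  out <- sweep(sweep(matrix, 2L, mu, `-`), 2L, sdv, `/`)
  out[, zero] <- 0
  out[out > max_sd] <- max_sd
  if (clip_lower) out[out < -max_sd] <- -max_sd
  attr(out, "zero_variance") <- colnames(matrix)[zero]
  out
}

#' PCA with explained-variance ratios (scree data)
#'
#' Singular value decomposition of the (column-centered) matrix; returns the
#' top components and each component's share of the total variance, which is
#' what a scree plot displays. Ratios are non-increasing and sum to at most 1.
#'
#' @param matrix dense cells x genes matrix (typically from [scale_clip()]).
#' @param n_components number of components, at most `min(dim(matrix))`.
#' @return A list: `scores` (cells x components), `loadings`
#'   (genes x components), `variance_ratio` (length `n_components`),
#'   `singular_values`.
#' @export
pca_scree <- function(matrix, n_components = 50) {
  if (n_components > min(dim(matrix))) {
    stop_cd8(sprintf("n_components = %d exceeds min(dim) = %d",
                     n_components, min(dim(matrix))), "bad_argument")
  }
  centered <- sweep(matrix, 2L, colMeans(matrix), `-`)
  sv <- svd(centered, nu = n_components, nv = n_components)
  total_var <- sum(centered^2) / (nrow(matrix) - 1L)
  var_comp <- sv$d[seq_len(n_components)]^2 / (nrow(matrix) - 1L)
  list(scores = sv$u %*% diag(sv$d[seq_len(n_components)], n_components),
       loadings = sv$v,
       variance_ratio = var_comp / total_var,
       singular_values = sv$d[seq_len(n_components)])
}

#' Per-10k expression inclusion mask
#'
#' A cell is included for a gene's violin/temporal display iff it carries at
#' least one transcript of that gene per 10,000 total counts, i.e.
#' `count_gene / total_counts >= 1e-4`.
#'
#' @param x a [umi_matrix()].
#' @param gene gene name.
#' @return Named logical vector over cells.
#' @export
per10k_mask <- function(x, gene) {
  stopifnot(inherits(x, "umi_matrix"))
  if (!gene %in% colnames(x$counts)) {
    stop_cd8(sprintf("gene '%s' absent", gene), "missing_gene")
  }
  totals <- Matrix::rowSums(x$counts)
  if (any(totals == 0)) stop_cd8("cell(s) with zero total counts", "bad_argument")
  mask <- as.numeric(x$counts[, gene]) / totals >= 1e-4
  stats::setNames(mask, rownames(x$counts))
}

#' Classify memory subsets from marker expression
#'
#' Deterministic two-marker gating on normalized expression of CD62L (Sell)
#' and IL-7R alpha (Il7r):
#' \itemize{
#'   \item Sell-lo, Il7r-lo: long-lived effector (`LLE`)
#'   \item Sell-lo, Il7r-hi: effector memory (`TEM`)
#'   \item Sell-hi, Il7r-hi: central memory (`TCM`)
#'   \item Sell-hi, Il7r-lo: `unassigned` (no subset defined for this gate)
#' }
#' "hi" means normalized expression at or above the marker's threshold. The
#' default threshold of 1 on a counts-per-10k scale mirrors the per-10k
#' inclusion rule; pass your own thresholds for other normalizations.
#'
#' @param norm_matrix cells x genes normalized expression (e.g.
#'   [normalize_per_cell()] with `log1p = FALSE`).
#' @param markers named character vector mapping roles to gene names,
#'   `c(sell = ..., il7r = ...)`.
#' @param thresholds named numeric vector of hi/lo cutoffs per role.
#' @return A `subset_labels` tibble: `cell`, `sell`, `il7r` (marker levels),
#'   `label` (factor `LLE`/`TEM`/`TCM`/`unassigned`).
#' @export
classify_subsets <- function(norm_matrix,
                             markers = c(sell = "Sell", il7r = "Il7r"),
                             thresholds = c(sell = 1, il7r = 1)) {
  missing_m <- setdiff(unname(markers), colnames(norm_matrix))
  if (length(missing_m) > 0L) {
    stop_cd8(paste0("marker gene(s) absent: ", paste(missing_m, collapse = ", ")),
             "missing_gene")
  }
  sell <- norm_matrix[, markers[["sell"]]]
  il7r <- norm_matrix[, markers[["il7r"]]]
  sell_hi <- sell >= thresholds[["sell"]]
  il7r_hi <- il7r >= thresholds[["il7r"]]
  label <- rep("unassigned", nrow(norm_matrix))
  label[!sell_hi & !il7r_hi] <- "LLE"
  label[!sell_hi & il7r_hi] <- "TEM"
  label[sell_hi & il7r_hi] <- "TCM"
  out <- tibble(cell = rownames(norm_matrix) %||% as.character(seq_along(label)),
                sell = unname(sell), il7r = unname(il7r),
                label = factor(label, levels = c("LLE", "TEM", "TCM", "unassigned")))
  structure(out, class = c("subset_labels", class(out)),
            markers = markers, thresholds = thresholds)
}
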