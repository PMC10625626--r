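#' Transcripts per million from raw counts
#'
#' RPK = count / (gene length in kb); per-sample scaling factor =
#' sum(RPK) / 1e6; TPM = RPK / factor. Every non-degenerate sample column
#' therefore sums to exactly one million. Genes with zero or missing length
#' are excluded and reported in the `excluded_genes` attribute.
#'
#' @param counts numeric matrix, genes x samples, with dimnames.
#' @param gene_lengths named numeric vector of gene lengths in base pairs
#'   (names matching the count rows).
#' @return A TPM matrix (genes x samples) with attribute `excluded_genes`.
#' @export
tpm <- function(counts, gene_lengths) {
  if (is.null(rownames(counts))) stop_cd8("counts need gene row names", "bad_argument")
  len <- gene_lengths[rownames(counts)]
  excluded <- rownames(counts)[is.na(len) | len <= 0]
  keep <- !(rownames(counts) %in% excluded)
  counts <- counts[keep, , drop = FALSE]
  len <- len[keep]
  rpk <- counts / (len / 1000)
  factor <- colSums(rpk) / 1e6
  zero <- factor == 0
  if (any(zero)) {
    stop_cd8(paste0("all-zero sample(s): ",
                    paste(colnames(counts)[zero], collapse = ", ")),
             "all_zero_sample")
  }
  out <- sweep(rpk, 2L, factor, `/`)
  attr(out, "excluded_genes") <- excluded
  out
}

#' Call differentially expressed genes on TPM with study presets
#'
#' Per-gene two-sided Student's t on `log2(TPM + 1)` between the two groups,
#' gated by the preset thresholds:
#' \describe{
#'   \item{`myc`}{DEG iff `|log2FC| > 2` and `p < 0.001`.}
#'   \item{`cul4b`}{DEG iff `log2FC > 0.20` and `p < 0.05` (upper gate only as
#'     printed — downregulation is never called).}
#' }
#' `log2FC` is knockout over control on the `log2(TPM + 1)` scale.
#'
#' @param tpm_matrix genes x samples TPM matrix (see [tpm()]).
#' @param groups named group vector per sample (two groups).
#' @param preset `"myc"` or `"cul4b"`.
#' @param control,knockout optional explicit group labels.
#' @return A `differential_table` tibble (see [differential_test()]).
#' @export
call_degs <- function(tpm_matrix, groups, preset = c("myc", "cul4b"),
                      control = NULL, knockout = NULL) {
  preset <- match.arg(preset)
  thresholds <- de_preset(if (preset == "myc") "myc-rna" else "cul4b-rna")
  differential_test(log2(tpm_matrix + 1), groups = groups,
                    alpha = thresholds$alpha,
                    log2fc_lo = thresholds$log2fc_lo,
                    log2fc_hi = thresholds$log2fc_hi,
                    control = control, knockout = knockout,
                    log_transform = FALSE)
}
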