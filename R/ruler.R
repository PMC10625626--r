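#' Absolute protein copy numbers via the proteomic ruler
#'
#' The proteomic ruler scales mass-spectrometric intensity into absolute
#' copies per cell using the total histone signal as an internal standard for
#' cellular DNA mass:
#'
#' \deqn{copies_p = \frac{I_p \; N_A \; m_{DNA}}{MW_p \; \sum_{h \in histones} I_h}}
#'
#' where \eqn{I_p} is the protein's intensity, \eqn{MW_p} its molecular weight
#' (g/mol), \eqn{N_A} Avogadro's number and \eqn{m_{DNA}} the DNA mass per
#' cell (g). Copies are computed per sample and averaged within each group.
#' The estimate is invariant to uniform rescaling of all intensities in a
#' sample and scales linearly with `dna_mass_per_cell`.
#'
#' @param x an [intensity_matrix()]; annotations (either embedded or passed
#'   via `annotations`) must provide `molecular_weight` (g/mol) and
#'   `is_histone` per feature. Proteins lacking a molecular weight are
#'   reported unscored (`scored = FALSE`, `copies_per_cell = NA`).
#' @param annotations optional annotation tibble overriding `x$annotations`.
#' @param dna_mass_per_cell DNA mass per cell in grams. Default
#'   `5.89e-12` g, the diploid mouse genome (2 x 2.73 Gbp x 650 g/mol/bp /
#'   N_A); pass your own for other genomes or ploidies. Supplying `NULL` is an
#'   error — the constant is biology, not a fudge factor, so it must be
#'   explicit or the documented default.
#'
#' @return A tibble: `feature`, `molecular_weight`, `is_histone`, `group`,
#'   `mean_intensity`, `copies_per_cell`, `scored`.
#' @export
proteomic_ruler <- function(x, annotations = NULL,
                            dna_mass_per_cell = .DEFAULT_DNA_PG) {
  stopifnot(inherits(x, "intensity_matrix"))
  if (is.null(dna_mass_per_cell) || !is.numeric(dna_mass_per_cell) ||
      length(dna_mass_per_cell) != 1L || dna_mass_per_cell <= 0) {
    stop_cd8("`dna_mass_per_cell` must be a single positive mass in grams",
             "bad_argument")
  }
  ann <- annotations %||% x$annotations
  if (is.null(ann) || !all(c("feature", "molecular_weight", "is_histone") %in% names(ann))) {
    stop_cd8("annotations with `feature`, `molecular_weight`, `is_histone` required",
             "bad_argument")
  }
  idx <- match(rownames(x$values), ann$feature)
  mw <- ann$molecular_weight[idx]
  is_h <- ann$is_histone[idx]
  is_h[is.na(is_h)] <- FALSE
  if (!any(is_h)) stop_cd8("no histone features annotated", "no_histones")

  v <- x$values
  hist_total <- colSums(v[is_h, , drop = FALSE], na.rm = TRUE)
  if (any(hist_total <= 0)) {
    stop_cd8(paste0("zero total histone intensity in sample(s): ",
                    paste(colnames(v)[hist_total <= 0], collapse = ", ")),
             "zero_histone")
  }
  # copies per sample: I * N_A * m_DNA / (MW * total histone intensity)
  copies <- sweep(v, 2L, .AVOGADRO * dna_mass_per_cell / hist_total, `*`) / mw

  per_group <- function(mat) {
    cols <- lapply(split(seq_along(x$groups), x$groups),
                   function(j) rowMeans(mat[, j, drop = FALSE], na.rm = TRUE))
    do.call(cbind, cols)
  }
  grp_copies <- per_group(copies)
  grp_int <- per_group(v)

  out <- tibble(
    feature = rep(rownames(v), times = ncol(grp_copies)),
    molecular_weight = rep(mw, times = ncol(grp_copies)),
    is_histone = rep(is_h, times = ncol(grp_copies)),
    group = rep(colnames(grp_copies), each = nrow(v)),
    mean_intensity = as.vector(grp_int),
    copies_per_cell = as.vector(grp_copies)
  ) |>
    mutate(scored = !is.na(.data$molecular_weight),
           copies_per_cell = ifelse(.data$scored, .data$copies_per_cell, NA_real_))
  structure(out, class = c("copy_number_table", class(out)),
            dna_mass_per_cell = dna_mass_per_cell)
}
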