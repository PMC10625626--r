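#' Over-representation analysis with direction z-scores
#'
#' For each gene set, tests whether differentially expressed features overlap
#' the set more than chance by Fisher's exact test on the 2x2 table
#' (in set / not in set) x (DE / not DE) over the declared universe. Term
#' members are intersected with the universe before testing. Terms with zero
#' DE overlap are retained with `p_value = 1` (they carry no enrichment
#' signal). Each term also receives the GOplot-style direction z-score
#'
#' \deqn{z = (up - down) / \sqrt{up + down}}
#'
#' over its DE members: positive when more of the term's DE members are
#' upregulated than downregulated. Undefined (NA) when the overlap is empty.
#'
#' @param de_table a `differential_table` (from [differential_test()] or
#'   [call_degs()]); any tibble with `feature` and `direction` columns works.
#' @param gene_sets named list of member vectors (see [read_gmt()]).
#' @param universe feature universe; default all features in `de_table` —
#'   i.e. everything detected in the experiment, the proteomics convention.
#'   Must contain the DE set.
#' @param adjust_method `"bonferroni"` (the GO-term screen of the study) or
#'   `"BH"`.
#' @param alternative `"two.sided"` Fisher (default, matching the study's
#'   legends) or `"greater"` for the classical enrichment-only upper tail
#'   (then identical to a hypergeometric upper-tail test).
#'
#' @return An `ora_result` tibble: `term`, `overlap` (k), `term_size` (K, in
#'   universe), `de_size` (n), `universe_size` (N), `p_value`, `p_adjusted`,
#'   `up_count`, `down_count`, `z_score`, sorted by `p_value`.
#' @export
fisher_ora <- function(de_table, gene_sets, universe = NULL,
                       adjust_method = c("bonferroni", "BH"),
                       alternative = c("two.sided", "greater")) {
  adjust_method <- match.arg(adjust_method)
  alternative <- match.arg(alternative)
  universe <- unique(universe %||% de_table$feature)
  if (length(universe) == 0L) stop_cd8("empty universe", "bad_argument")
  de <- de_table$feature[de_table$direction %in% c("up", "down")]
  offenders <- setdiff(de, universe)
  if (length(offenders) > 0L) {
    stop_cd8(paste0("DE features outside the universe: ",
                    paste(utils::head(offenders, 5L), collapse = ", ")),
             "bad_universe")
  }
  dir_map <- stats::setNames(de_table$direction, de_table$feature)
  N <- length(universe); n <- length(de)

  rows <- imap(gene_sets, function(members, term) {
    in_univ <- intersect(members, universe)
    K <- length(in_univ)
    hits <- intersect(in_univ, de)
    k <- length(hits)
    if (k == 0L) {
      p <- 1
    } else if (alternative == "greater") {
      p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    } else {
      tab <- matrix(c(k, K - k, n - k, N - K - n + k), nrow = 2L)
      p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
    }
    up <- sum(dir_map[hits] == "up")
    down <- sum(dir_map[hits] == "down")
    tibble(term = term, overlap = k, term_size = K, de_size = n,
           universe_size = N, p_value = min(p, 1),
           up_count = up, down_count = down,
           z_score = if (k > 0L) (up - down) / sqrt(up + down) else NA_real_)
  })
  out <- bind_rows(rows) |>
    mutate(p_adjusted = stats::p.adjust(
      .data$p_value, method = if (adjust_method == "BH") "BH" else "bonferroni")) |>
    relocate("p_adjusted", .after = "p_value") |>
    arrange(.data$p_value, .data$term)
  structure(out, class = c("ora_result", class(out)),
            adjust_method = adjust_method, alternative = alternative)
}

#' GOplot-style direction z-score for one term
#'
#' `z = (up - down) / sqrt(up + down)` over the term's differentially
#' expressed members. Positive z: the term's DE members are mostly
#' upregulated.
#'
#' @param members identifiers of the term's DE overlap.
#' @param de_table a differential table carrying `feature` and `direction`.
#' @return A single number; `NA` for an empty overlap.
#' @export
goplot_zscore <- function(members, de_table) {
  if (length(members) == 0L) return(NA_real_)
  dir <- de_table$direction[match(members, de_table$feature)]
  if (anyNA(dir)) {
    stop_cd8(paste0("members without a direction: ",
                    paste(members[is.na(dir)], collapse = ", ")),
             "missing_direction")
  }
  up <- sum(dir == "up"); down <- sum(dir == "down")
  if (up + down == 0L) return(NA_real_)
  (up - down) / sqrt(up + down)
}

#' Bubble-plot view of an ORA result
#'
#' x: direction z-score; y: -log10 adjusted p; point area: overlap size.
#'
#' @param object an `ora_result`.
#' @param alpha significance line on the adjusted p scale.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot ora_result
#' @export
autoplot.ora_result <- function(object, alpha = 0.05, ...) {
  df <- as_tibble(object)[object$overlap > 0L, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z_score,
                                   y = -log10(.data$p_adjusted),
                                   size = .data$overlap)) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7, colour = "#34495e") +
    ggplot2::scale_size_area(max_size = 10) +
    ggplot2::labs(x = "z-score (up vs down)", y = expression(-log[10] ~ p[adj]),
                  size = "DE overlap") +
    ggplot2::theme_minimal()
}

#' Export bubble-plot data for external plotting
#'
#' @param object an `ora_result`.
#' @return A tibble: `term`, `neg_log10_p_adjusted`, `z_score`, `size`.
#' @export
ora_bubble_data <- function(object) {
  as_tibble(object) |>
    transmute(.data$term,
              neg_log10_p_adjusted = -log10(.data$p_adjusted),
              .data$z_score, size = .data$overlap)
}
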