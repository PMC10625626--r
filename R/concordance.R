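#' Cross-dataset log2 fold-change concordance
#'
#' Joins two differential tables on feature identifier (uppercased, so mixed
#' human/mouse symbol conventions join), selects a comparison set, and
#' summarizes agreement by an ordinary least-squares fit of `log2fc_b` on
#' `log2fc_a` and the Pearson correlation on the same set.
#'
#' Comparison-set policies:
#' \describe{
#'   \item{`de_in_both`}{features significant in both tables (the
#'     cross-dataset scatter convention of the study).}
#'   \item{`de_in_a`}{features significant in table A (e.g. an externally
#'     defined DE list applied to a new dataset).}
#'   \item{`all_common`}{every feature present in both tables.}
#' }
#'
#' @param table_a,table_b differential tables (`feature`, `log2fc`,
#'   `direction` columns required).
#' @param policy comparison-set policy (see above).
#' @return A `concordance_report` list: `glance`-able summary (`n_common`,
#'   `n_de_a`, `n_de_b`, `n_de_both`, `pearson_r`, `slope`, `intercept`,
#'   `policy`) plus a per-feature tibble `features` (`feature`, `log2fc_a`,
#'   `log2fc_b`, `de_a`, `de_b`, `in_comparison`) for scatter export.
#' @export
concordance <- function(table_a, table_b,
                        policy = c("de_in_both", "de_in_a", "all_common")) {
  policy <- match.arg(policy)
  a <- as_tibble(table_a); b <- as_tibble(table_b)
  a$key <- toupper(a$feature); b$key <- toupper(b$feature)
  joined <- inner_join(
    a |> select("key", feature = "feature", log2fc_a = "log2fc", dir_a = "direction"),
    b |> select("key", log2fc_b = "log2fc", dir_b = "direction"),
    by = "key") |>
    mutate(de_a = .data$dir_a %in% c("up", "down"),
           de_b = .data$dir_b %in% c("up", "down"))
  joined <- joined[!is.na(joined$log2fc_a) & !is.na(joined$log2fc_b), ]
  in_cmp <- switch(policy,
    de_in_both = joined$de_a & joined$de_b,
    de_in_a = joined$de_a,
    all_common = rep(TRUE, nrow(joined)))
  cmp <- joined[in_cmp, ]
  if (nrow(cmp) < 3L) {
    stop_cd8(sprintf("comparison set has %d feature(s); need >= 3 for a fit",
                     nrow(cmp)), "too_few")
  }
  fit <- stats::lm(log2fc_b ~ log2fc_a, data = cmp)
  r <- stats::cor(cmp$log2fc_a, cmp$log2fc_b)
  structure(
    list(
      summary = tibble(
        n_common = nrow(joined),
        n_de_a = sum(joined$de_a), n_de_b = sum(joined$de_b),
        n_de_both = sum(joined$de_a & joined$de_b),
        n_comparison = nrow(cmp),
        pearson_r = r,
        slope = unname(stats::coef(fit)[2L]),
        intercept = unname(stats::coef(fit)[1L]),
        policy = policy),
      features = joined |>
        mutate(in_comparison = in_cmp) |>
        select("feature", "log2fc_a", "log2fc_b", "de_a", "de_b", "in_comparison")),
    class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<concordance_report> policy=%s\n", s$policy))
  cat(sprintf("  common features: %d (DE in A: %d, DE in B: %d, both: %d)\n",
              s$n_common, s$n_de_a, s$n_de_b, s$n_de_both))
  cat(sprintf("  on %d compared features: r = %.4f, slope = %.4f, intercept = %.4f\n",
              s$n_comparison, s$pearson_r, s$slope, s$intercept))
  invisible(x)
}

#' @method glance concordance_report
#' @export
glance.concordance_report <- function(x, ...) x$summary

#' @method tidy concordance_report
#' @export
tidy.concordance_report <- function(x, ...) x$features

#' Scatter plot of a concordance report
#'
#' Grey: unchanged in both; orange/green: DE in one dataset only; blue: DE in
#' both, with the least-squares line fitted on the comparison set.
#'
#' @param object a `concordance_report`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot concordance_report
#' @export
autoplot.concordance_report <- function(object, ...) {
  df <- object$features |>
    mutate(class = case_when(
      .data$de_a & .data$de_b ~ "DE in both",
      .data$de_a ~ "DE in A only",
      .data$de_b ~ "DE in B only",
      TRUE ~ "unchanged"))
  s <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc_a, y = .data$log2fc_b,
                                   colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::geom_abline(slope = s$slope, intercept = s$intercept,
                         colour = "#2c3e50") +
    ggplot2::scale_colour_manual(values = c(
      "DE in both" = "#2980b9", "DE in A only" = "#e67e22",
      "DE in B only" = "#27ae60", "unchanged" = "grey70")) +
    ggplot2::labs(x = "log2FC (dataset A)", y = "log2FC (dataset B)",
                  colour = NULL,
                  subtitle = sprintf("r = %.3f on %d features (%s)",
                                     s$pearson_r, s$n_comparison, s$policy)) +
    ggplot2::theme_minimal()
}
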