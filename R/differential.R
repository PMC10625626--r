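#' Differential expression presets
#'
#' Threshold profiles used across the study's datasets:
#' \describe{
#'   \item{`proteome`}{two-sided t, `alpha = 0.05`, no fold-change gate.}
#'   \item{`myc-rna`}{`alpha = 0.001` and `|log2FC| > 2`.}
#'   \item{`cul4b-rna`}{`alpha = 0.05` and `log2FC > 0.20` — upper gate only,
#'     so only upregulation can be called significant.}
#' }
#'
#' @param preset preset name.
#' @return A list with `alpha`, `log2fc_lo`, `log2fc_hi`.
#' @export
de_preset <- function(preset = c("proteome", "myc-rna", "cul4b-rna")) {
  preset <- match.arg(preset)
  switch(preset,
    "proteome"  = list(alpha = 0.05,  log2fc_lo = 0,    log2fc_hi = 0),
    "myc-rna"   = list(alpha = 0.001, log2fc_lo = -2,   log2fc_hi = 2),
    "cul4b-rna" = list(alpha = 0.05,  log2fc_lo = -Inf, log2fc_hi = 0.20)
  )
}

#' Two-group differential expression on an intensity matrix
#'
#' Per-feature two-sided two-sample t-test on log2 intensities (classic
#' Student pooled-variance by default; Welch behind `var_equal = FALSE`).
#' Zeros are treated as missing before the log transform. `log2fc` is
#' mean(log2 knockout) - mean(log2 control). A feature is significant when
#' `p < alpha` AND (`log2fc > log2fc_hi` OR `log2fc < log2fc_lo`); its
#' `direction` is then `up`/`down` by the sign of `log2fc`. Features with
#' fewer than two present values in either group are reported untested
#' (`tested = FALSE`, statistics `NA`), never significant.
#'
#' Degenerate zero-variance features: both groups constant and equal gives
#' `p = 1`; constant and unequal gives the smallest representable positive p,
#' flagged in `degenerate` — the t statistic is undefined but the ranking is
#' preserved.
#'
#' @param x an [intensity_matrix()], or a plain numeric matrix together with
#'   `groups`.
#' @param control,knockout group labels naming the reference and test group;
#'   by default the labels `"control"` and `"knockout"`, falling back to the
#'   first and second label in sort order when those are absent.
#' @param alpha significance level in (0, 1).
#' @param log2fc_lo,log2fc_hi fold-change gates (see above). `(-Inf, 0)` etc.
#'   are allowed; the default `(0, 0)` means any nonzero fold change passes.
#' @param adjust_method `"BH"` (Benjamini-Hochberg) or `"bonferroni"`.
#' @param groups named group vector when `x` is a plain matrix.
#' @param var_equal pooled-variance Student t (`TRUE`, default) or Welch.
#' @param log_transform set `FALSE` when `x` already holds log2 values.
#'
#' @return A `differential_table` tibble: `feature`, `log2fc`, `t_statistic`,
#'   `p_value`, `p_adjusted`, `direction` (`up`/`down`/`unchanged`),
#'   `n_control`, `n_knockout`, `tested`, `degenerate`. Thresholds are stored
#'   as attributes and surfaced by [glance()].
#' @export
differential_test <- function(x, alpha = 0.05, log2fc_lo = 0, log2fc_hi = 0,
                              adjust_method = c("BH", "bonferroni"),
                              control = NULL, knockout = NULL, groups = NULL,
                              var_equal = TRUE, log_transform = TRUE) {
  assert_prob(alpha, "alpha")
  adjust_method <- match.arg(adjust_method)
  if (inherits(x, "intensity_matrix")) {
    values <- x$values
    groups <- x$groups
  } else {
    values <- x
    if (is.null(groups)) stop_cd8("`groups` required for a plain matrix", "bad_argument")
    groups <- groups[colnames(values)]
  }
  labs <- sort(unique(groups))
  if (length(labs) != 2L) stop_cd8("exactly two groups required", "bad_argument")
  control <- control %||% (if ("control" %in% labs) "control" else labs[1L])
  knockout <- knockout %||% (if ("knockout" %in% labs) "knockout" else setdiff(labs, control)[1L])
  ctl <- values[, groups == control, drop = FALSE]
  ko <- values[, groups == knockout, drop = FALSE]
  if (ncol(ctl) < 2L || ncol(ko) < 2L) {
    stop_cd8("each group needs at least 2 samples", "bad_argument")
  }
  if (log_transform) {
    ctl[ctl == 0] <- NA_real_; ko[ko == 0] <- NA_real_
    ctl <- log2(ctl); ko <- log2(ko)
  }

  stats_tbl <- row_t_stats(ctl, ko, var_equal = var_equal)
  log2fc <- stats_tbl$m2 - stats_tbl$m1
  tested <- stats_tbl$n1 >= 2L & stats_tbl$n2 >= 2L
  p <- rep(NA_real_, nrow(values))
  tstat <- rep(NA_real_, nrow(values))
  degenerate <- rep(FALSE, nrow(values))
  ok <- tested & stats_tbl$se > 0
  p[ok] <- 2 * stats::pt(abs(stats_tbl$t[ok]), df = stats_tbl$df[ok], lower.tail = FALSE)
  tstat[ok] <- stats_tbl$t[ok]
  zero_var <- tested & stats_tbl$se == 0
  eq <- zero_var & log2fc == 0
  ne <- zero_var & log2fc != 0
  p[eq] <- 1; tstat[eq] <- 0
  p[ne] <- .Machine$double.xmin
  degenerate[zero_var] <- TRUE

  p_adj <- rep(NA_real_, length(p))
  p_adj[tested] <- stats::p.adjust(p[tested], method = if (adjust_method == "BH") "BH" else "bonferroni")
  log2fc[!tested] <- NA_real_
  sig <- tested & !is.na(p) & p < alpha & (log2fc > log2fc_hi | log2fc < log2fc_lo)
  sig[is.na(sig)] <- FALSE
  direction <- rep("unchanged", length(sig))
  direction[sig & log2fc > 0] <- "up"
  direction[sig & log2fc < 0] <- "down"

  out <- tibble(
    feature = rownames(values),
    log2fc = unname(log2fc),
    t_statistic = unname(tstat),
    p_value = unname(p),
    p_adjusted = unname(p_adj),
    direction = unname(direction),
    n_control = unname(stats_tbl$n1),
    n_knockout = unname(stats_tbl$n2),
    tested = unname(tested),
    degenerate = unname(degenerate)
  )
  structure(out,
            class = c("differential_table", class(out)),
            alpha = alpha, log2fc_lo = log2fc_lo, log2fc_hi = log2fc_hi,
            adjust_method = adjust_method,
            control = control, knockout = knockout, var_equal = var_equal)
}

# vectorised per-row two-sample t; NA-aware
row_t_stats <- function(a, b, var_equal = TRUE) {
  n1 <- rowSums(!is.na(a)); n2 <- rowSums(!is.na(b))
  m1 <- rowMeans(a, na.rm = TRUE); m2 <- rowMeans(b, na.rm = TRUE)
  ss1 <- rowSums((a - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((b - m2)^2, na.rm = TRUE)
  if (var_equal) {
    df <- n1 + n2 - 2
    sp2 <- ifelse(df > 0, (ss1 + ss2) / df, NA_real_)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    v1 <- ss1 / pmax(n1 - 1, 1); v2 <- ss2 / pmax(n2 - 1, 1)
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      (v1^2 / (n1^2 * pmax(n1 - 1, 1)) + v2^2 / (n2^2 * pmax(n2 - 1, 1)))
  }
  list(t = (m2 - m1) / se, df = df, se = se, n1 = n1, n2 = n2, m1 = m1, m2 = m2)
}

#' @method glance differential_table
#' @export
glance.differential_table <- function(x, ...) {
  tibble(
    n_features = nrow(x),
    n_tested = sum(x$tested),
    n_up = sum(x$direction == "up"),
    n_down = sum(x$direction == "down"),
    alpha = attr(x, "alpha"),
    log2fc_lo = attr(x, "log2fc_lo"),
    log2fc_hi = attr(x, "log2fc_hi"),
    adjust_method = attr(x, "adjust_method"),
    control = attr(x, "control"),
    knockout = attr(x, "knockout")
  )
}

#' Volcano plot of a differential table
#'
#' @param object a `differential_table`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot differential_table
#' @export
autoplot.differential_table <- function(object, ...) {
  df <- as_tibble(object)[object$tested, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(.data$p_value),
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2980b9",
                                            unchanged = "grey60")) +
    ggplot2::labs(x = "log2 fold change (knockout / control)",
                  y = expression(-log[10] ~ p), colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
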