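#' Rank features for GSEA
#'
#' Orders tested features by a ranking metric, descending. Ties are broken by
#' feature identifier (lexicographic), so the ranking is deterministic.
#'
#' @param de_table a differential table.
#' @param metric `"t_statistic"` or `"signed_log2fc"` (the signed log2 fold
#'   change itself).
#' @return A tibble `feature`, `score`, in ranked order.
#' @export
rank_features <- function(de_table, metric = c("t_statistic", "signed_log2fc")) {
  metric <- match.arg(metric)
  df <- as_tibble(de_table)
  if ("tested" %in% names(df)) df <- df[df$tested, ]
  score <- switch(metric, t_statistic = df$t_statistic, signed_log2fc = df$log2fc)
  bad <- is.na(score) | is.nan(score)
  if (any(bad)) {
    stop_cd8(paste0("non-finite ranking scores for: ",
                    paste(utils::head(df$feature[bad], 5L), collapse = ", ")),
             "bad_score")
  }
  ord <- order(-score, df$feature)
  tibble(feature = df$feature[ord], score = score[ord])
}

# running-sum enrichment score on a ranked list.
# scores: ranking scores in list order; hit: logical, membership.
# hits increment by |score|^weight (normalised to sum 1, equal weights if the
# hit scores are all zero); misses decrement by 1/(N-K).
# ES is the running-sum value of maximal |.|; exact ties resolve positive.
running_sum_es <- function(scores, hit, weight) {
  N <- length(scores); K <- sum(hit)
  w <- abs(scores)^weight
  w[!hit] <- 0
  if (sum(w) == 0) w[hit] <- 1
  inc <- w / sum(w)
  step <- ifelse(hit, inc, -1 / (N - K))
  running <- cumsum(step)
  mx <- max(running); mn <- min(running)
  positive <- mx + mn >= -1e-12  # exact |max| = |min| ties resolve positive
  list(es = if (positive) mx else mn, running = running,
       peak = if (positive) which.max(running) else which.min(running))
}

#' Gene-set enrichment analysis for a single set
#'
#' Weighted Kolmogorov-Smirnov-like running-sum statistic over a ranked list:
#' walking down the ranking, the sum rises by the hit's normalized
#' `|score|^weight` at set members and falls by `1/(N-K)` elsewhere; the
#' enrichment score (ES) is the signed maximum deviation. A positive ES means
#' the set concentrates at the top of the ranking, negative at the bottom.
#' The null is built by gene-label permutation (random sets of the same size,
#' appropriate for the small group sizes of this study); the normalized
#' enrichment score is
#' `NES = ES / mean(|permuted ES| of the same sign)` and the nominal p-value
#' is the fraction of same-sign permuted ES at least as extreme as the
#' observed one.
#'
#' @param ranked tibble from [rank_features()] (or a named numeric vector of
#'   scores, descending).
#' @param gene_set character vector of member identifiers.
#' @param weight hit-weighting exponent (0 = classic unweighted KS; 1 =
#'   standard weighted GSEA, the default).
#' @param n_permutations number of gene-label permutations (default 1000).
#'   Below 100 the result is flagged `low_permutations` in its metadata.
#' @param seed RNG seed for the permutations; recorded in the result.
#' @param keep_permutations keep the vector of permuted ES in the metadata
#'   (used by [run_gsea()] for pooled FDR).
#' @return A `gsea_result` list: `es`, `nes`, `nominal_p`, `leading_edge`,
#'   `size` (overlap used), `running` tibble (position, running sum, hit) for
#'   plotting, and `metadata` (weight, n_permutations, seed, low_permutations).
#' @export
gsea <- function(ranked, gene_set, weight = 1, n_permutations = 1000, seed,
                 keep_permutations = FALSE) {
  if (missing(seed)) stop_cd8("`seed` is required for the permutation null", "bad_argument")
  if (is.numeric(ranked) && !is.null(names(ranked))) {
    ranked <- tibble(feature = names(ranked), score = unname(ranked))
  }
  stopifnot(all(c("feature", "score") %in% names(ranked)))
  N <- nrow(ranked)
  hit <- ranked$feature %in% gene_set
  K <- sum(hit)
  if (K == 0L) stop_cd8("gene set does not intersect the ranked list", "empty_overlap")
  if (K == N) stop_cd8("gene set covers the whole ranked list", "full_coverage")

  obs <- running_sum_es(ranked$score, hit, weight)
  perm_es <- permuted_es(ranked$score, K, weight, n_permutations, seed)
  same_sign <- if (obs$es >= 0) perm_es[perm_es >= 0] else perm_es[perm_es <= 0]
  nes <- if (length(same_sign) > 0) obs$es / mean(abs(same_sign)) else NA_real_
  nominal_p <- if (length(same_sign) == 0) NA_real_
    else if (obs$es >= 0) mean(same_sign >= obs$es) else mean(same_sign <= obs$es)

  le <- if (obs$es >= 0) ranked$feature[hit & seq_len(N) <= obs$peak]
        else ranked$feature[hit & seq_len(N) >= obs$peak]
  structure(
    list(es = obs$es, nes = nes, nominal_p = nominal_p,
         leading_edge = le, size = K,
         running = tibble(position = seq_len(N), running_sum = obs$running, hit = hit),
         metadata = c(
           list(weight = weight, n_permutations = n_permutations,
                seed = seed, low_permutations = n_permutations < 100),
           if (keep_permutations) list(permuted_es = perm_es))),
    class = "gsea_result")
}

permuted_es <- function(scores, K, weight, n_permutations, seed) {
  N <- length(scores)
  withr::with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      hit <- logical(N)
      hit[sample.int(N, K)] <- TRUE
      running_sum_es(scores, hit, weight)$es
    }, 0)
  })
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("<gsea_result> size=%d  ES=%.4f  NES=%.4f  p=%.4g\n",
              x$size, x$es, x$nes, x$nominal_p))
  cat(sprintf("  leading edge: %d member(s); %d permutations, seed %s\n",
              length(x$leading_edge), x$metadata$n_permutations,
              format(x$metadata$seed)))
  invisible(x)
}

#' @method tidy gsea_result
#' @export
tidy.gsea_result <- function(x, ...) {
  tibble(es = x$es, nes = x$nes, nominal_p = x$nominal_p, size = x$size,
         n_leading_edge = length(x$leading_edge))
}

#' Enrichment-plot (running sum) for a GSEA result
#'
#' @param object a `gsea_result`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot gsea_result
#' @export
autoplot.gsea_result <- function(object, ...) {
  df <- object$running
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$running_sum)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line(colour = "#27ae60") +
    ggplot2::geom_rug(data = df[df$hit, ], sides = "b", colour = "#2c3e50",
                      length = ggplot2::unit(0.03, "npc")) +
    ggplot2::labs(x = "rank", y = "running enrichment score",
                  subtitle = sprintf("ES = %.3f, NES = %.3f, p = %.3g",
                                     object$es, object$nes, object$nominal_p)) +
    ggplot2::theme_minimal()
}

#' GSEA across a gene-set collection with pooled FDR
#'
#' Runs [gsea()] for every set in a collection against one ranking, then
#' computes FDR q-values by the canonical NES-pooling procedure: permuted ES
#' are NES-normalized per term (by the same-sign permutation mean as the
#' observed ES), pooled across terms, and for each observed NES the ratio of
#' the null tail fraction to the observed tail fraction (same sign) is taken,
#' clipped to `[0, 1]`.
#'
#' @inheritParams gsea
#' @param gene_sets named list of member vectors.
#' @param min_size,max_size overlap-size bounds; sets outside are skipped.
#' @return A `gsea_collection` tibble: `term`, `size`, `es`, `nes`,
#'   `nominal_p`, `fdr_q`, `leading_edge` (list-column), sorted by
#'   `nominal_p`; run metadata in attributes.
#' @export
run_gsea <- function(ranked, gene_sets, weight = 1, n_permutations = 1000,
                     seed, min_size = 2, max_size = Inf) {
  if (missing(seed)) stop_cd8("`seed` is required for the permutation null", "bad_argument")
  if (is.numeric(ranked) && !is.null(names(ranked))) {
    ranked <- tibble(feature = names(ranked), score = unname(ranked))
  }
  sizes <- vapply(gene_sets, function(m) sum(ranked$feature %in% m), 0L)
  keep <- sizes >= min_size & sizes <= pmin(max_size, nrow(ranked) - 1L)
  gene_sets <- gene_sets[keep]
  if (length(gene_sets) == 0L) stop_cd8("no gene set passes the size bounds", "bad_argument")

  res <- imap(gene_sets, function(members, term) {
    g <- gsea(ranked, members, weight = weight,
              n_permutations = n_permutations,
              seed = seed + match(term, names(gene_sets)),
              keep_permutations = TRUE)
    list(row = tibble(term = term, size = g$size, es = g$es, nes = g$nes,
                      nominal_p = g$nominal_p,
                      leading_edge = list(g$leading_edge)),
         perm = g$metadata$permuted_es)
  })
  tab <- bind_rows(map(res, "row"))

  # per-term NES-normalise the permutation ES, then pool
  perm_nes <- unlist(map(res, function(r) {
    pe <- r$perm
    pos_mean <- mean(pe[pe >= 0]); neg_mean <- mean(abs(pe[pe <= 0]))
    out <- ifelse(pe >= 0, pe / pos_mean, pe / neg_mean)
    out[is.finite(out)]
  }))
  obs_nes <- tab$nes
  fdr_q <- vapply(obs_nes, function(nes) {
    if (is.na(nes)) return(NA_real_)
    if (nes >= 0) {
      null_frac <- mean(perm_nes[perm_nes >= 0] >= nes)
      obs_frac <- mean(obs_nes[obs_nes >= 0] >= nes)
    } else {
      null_frac <- mean(perm_nes[perm_nes <= 0] <= nes)
      obs_frac <- mean(obs_nes[obs_nes <= 0] <= nes)
    }
    min(1, null_frac / max(obs_frac, .Machine$double.eps))
  }, 0)
  tab$fdr_q <- fdr_q
  out <- tab |> relocate("leading_edge", .after = "fdr_q") |>
    arrange(.data$nominal_p, .data$term)
  structure(out, class = c("gsea_collection", class(out)),
            weight = weight, n_permutations = n_permutations, seed = seed,
            low_permutations = n_permutations < 100)
}
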