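#' Read a STRING protein.links file
#'
#' Parses the space-delimited `protein1 protein2 combined_score` dialect
#' (one header line; integer scores 0-999, i.e. combined score x 1000).
#' Scores are divided by 1000, rows below `min_score` are dropped, and the two
#' directed rows STRING emits per association are collapsed into one
#' undirected edge. If reciprocal rows disagree on the score the maximum is
#' kept with a warning.
#'
#' @param path file path or connection.
#' @param min_score minimum combined score in `[0, 1]` (the study threshold is
#'   0.750); rows with `score/1000 < min_score` are dropped.
#' @param taxon_prefix NCBI taxon prefix (e.g. `"10090"` for mouse). When
#'   `strip_taxon = TRUE` the leading `"<taxon_prefix>."` is removed from
#'   identifiers.
#' @param strip_taxon strip the taxon prefix from identifiers?
#' @return A `scored_edges` tibble with columns `protein1`, `protein2`,
#'   `combined_score` (in `[0,1]`), one row per undirected edge, with
#'   `protein1 < protein2` lexicographically, sorted. Attribute
#'   `taxon_prefix` records the declared prefix.
#' @export
read_string_links <- function(path, min_score = 0, taxon_prefix = "10090",
                              strip_taxon = FALSE) {
  if (min_score < 0 || min_score > 1) {
    stop_cd8("`min_score` must be in [0, 1]", "bad_argument")
  }
  lines <- readLines(path)
  if (length(lines) == 0L) stop_cd8("empty links file", "bad_format")
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    return(scored_edges(tibble(protein1 = character(), protein2 = character(),
                               combined_score = double()),
                        taxon_prefix = taxon_prefix))
  }
  fields <- strsplit(body, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 3L)) {
    stop_cd8(sprintf("malformed row at line %d: expected 3 fields, got %d",
                     which(nf != 3L)[1L] + 1L, nf[nf != 3L][1L]), "bad_format")
  }
  m <- matrix(unlist(fields), ncol = 3L, byrow = TRUE)
  suppressWarnings(raw_score <- as.numeric(m[, 3L]))
  bad <- is.na(raw_score) | raw_score != floor(raw_score) |
    raw_score < 0 | raw_score > 999
  if (any(bad)) {
    stop_cd8(sprintf("score outside 0-999 ('%s') at line %d",
                     m[which(bad)[1L], 3L], which(bad)[1L] + 1L), "bad_score")
  }
  a <- m[, 1L]; b <- m[, 2L]
  if (any(a == b)) {
    stop_cd8(sprintf("self-edge at line %d", which(a == b)[1L] + 1L), "bad_format")
  }
  score <- raw_score / 1000
  keep <- score >= min_score
  a <- a[keep]; b <- b[keep]; score <- score[keep]
  if (strip_taxon) {
    pref <- paste0(taxon_prefix, ".")
    a <- sub(pref, "", a, fixed = TRUE)
    b <- sub(pref, "", b, fixed = TRUE)
  }
  if (length(a) == 0L) {
    return(scored_edges(tibble(protein1 = character(), protein2 = character(),
                               combined_score = double()),
                        taxon_prefix = taxon_prefix))
  }
  # collapse reciprocal duplicates: canonical order within the pair
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  agg <- tapply(score, key, max)
  n_distinct_scores <- tapply(score, key, function(s) length(unique(s)))
  if (any(n_distinct_scores > 1L)) {
    rlang::warn(sprintf(
      "%d edge(s) had disagreeing reciprocal scores; kept the maximum",
      sum(n_distinct_scores > 1L)))
  }
  pairs <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  out <- tibble(protein1 = pairs[, 1L], protein2 = pairs[, 2L],
                combined_score = as.numeric(agg)) |>
    arrange(.data$protein1, .data$protein2)
  scored_edges(out, taxon_prefix = taxon_prefix)
}

scored_edges <- function(tbl, taxon_prefix = NULL) {
  structure(tbl, taxon_prefix = taxon_prefix,
            class = c("scored_edges", class(tibble())))
}

#' Write edges in the STRING protein.links dialect
#'
#' Emits both directed rows per undirected edge (as STRING files do), integer
#' scores (combined score x 1000), one header line. Together with
#' [read_string_links()] this round-trips an edge set exactly.
#'
#' @param edges a `scored_edges` tibble (or any tibble with `protein1`,
#'   `protein2`, `combined_score` columns).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_string_links <- function(edges, path) {
  sc <- as.integer(round(edges$combined_score * 1000))
  lines <- c("protein1 protein2 combined_score",
             paste(edges$protein1, edges$protein2, sc),
             paste(edges$protein2, edges$protein1, sc))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column symbol map
#'
#' Tab-delimited, header `identifier<TAB>symbol`. Used to join gene symbols in
#' differential tables to external (e.g. STRING) identifiers.
#'
#' @param path file path.
#' @return A tibble with columns `identifier`, `symbol`.
#' @export
read_symbol_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          check.names = FALSE)
  if (ncol(df) < 2L) stop_cd8("symbol map needs two columns", "bad_format")
  tibble(identifier = df[[1L]], symbol = df[[2L]])
}

#' Map gene symbols to external identifiers
#'
#' Input order is preserved; unmapped symbols are reported, never silently
#' dropped. A symbol with several candidate identifiers is resolved
#' deterministically to the lexicographically smallest identifier and flagged
#' ambiguous.
#'
#' @param symbols non-empty character vector of gene symbols.
#' @param symbol_map tibble with columns `identifier`, `symbol` (see
#'   [read_symbol_map()]).
#' @return A list: `mapped` tibble (`symbol`, `identifier`, `ambiguous`) in
#'   input order covering mappable symbols only; `unmapped` character vector.
#' @export
map_symbols <- function(symbols, symbol_map) {
  if (length(symbols) == 0L) stop_cd8("empty symbol list", "bad_argument")
  resolved <- symbol_map |>
    group_by(.data$symbol) |>
    summarise(ambiguous = n_distinct(.data$identifier) > 1L,
              identifier = min(.data$identifier),
              .groups = "drop")
  idx <- match(symbols, resolved$symbol)
  unmapped <- symbols[is.na(idx)]
  hit <- !is.na(idx)
  list(
    mapped = tibble(symbol = symbols[hit],
                    identifier = resolved$identifier[idx[hit]],
                    ambiguous = resolved$ambiguous[idx[hit]]),
    unmapped = unmapped
  )
}
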