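#' Serialize a scored interaction graph
#'
#' Deterministic export of an igraph network (node and edge order sorted by
#' identifier). Three formats:
#' \describe{
#'   \item{`graphml`}{full fidelity — node attributes and edge scores survive a
#'     round trip through [read_graph_file()].}
#'   \item{`sif`}{Cytoscape simple-interaction format,
#'     `node1<TAB>pp<TAB>node2`; scores are not carried.}
#'   \item{`edge-tsv`}{`protein1<TAB>protein2<TAB>combined_score` with header.}
#' }
#'
#' @param graph an igraph object; edge attribute `combined_score` expected for
#'   score-carrying formats.
#' @param path output path.
#' @param format one of `"graphml"`, `"sif"`, `"edge-tsv"`.
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(graph, path, format = c("graphml", "sif", "edge-tsv")) {
  if (!format[1L] %in% c("graphml", "sif", "edge-tsv")) {
    stop_cd8(sprintf(
      "unknown format '%s'; supported: graphml, sif, edge-tsv", format[1L]),
      "bad_format")
  }
  format <- format[1L]
  graph <- sort_graph(graph)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
    return(invisible(path))
  }
  el <- igraph::as_edgelist(graph)
  lo <- pmin(el[, 1L], el[, 2L]); hi <- pmax(el[, 1L], el[, 2L])
  ord <- order(lo, hi)
  if (format == "sif") {
    body <- paste(lo[ord], "pp", hi[ord], sep = "\t")
    # SIF must still list isolated nodes so the node set survives
    deg0 <- igraph::V(graph)$name[igraph::degree(graph) == 0L]
    writeLines(c(body, deg0), path)
  } else {
    score <- igraph::E(graph)$combined_score %||% rep(NA_real_, nrow(el))
    writeLines(c("protein1\tprotein2\tcombined_score",
                 paste(lo[ord], hi[ord], sprintf("%.17g", score[ord]), sep = "\t")),
               path)
  }
  invisible(path)
}

sort_graph <- function(graph) {
  perm <- match(igraph::V(graph)$name, sort(igraph::V(graph)$name))
  igraph::permute(graph, perm)
}

#' Read a graph written by [write_graph_file()]
#'
#' @param path input path.
#' @param format one of `"graphml"`, `"sif"`, `"edge-tsv"`.
#' @return An igraph object.
#' @export
read_graph_file <- function(path, format = c("graphml", "sif", "edge-tsv")) {
  format <- format[1L]
  if (format == "graphml") {
    return(igraph::read_graph(path, format = "graphml"))
  }
  lines <- readLines(path)
  if (format == "sif") {
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    edges <- fields[lengths(fields) == 3L]
    singletons <- unlist(fields[lengths(fields) == 1L])
    el <- do.call(rbind, lapply(edges, function(f) f[c(1L, 3L)]))
    g <- igraph::make_empty_graph(directed = FALSE)
    verts <- sort(unique(c(as.vector(el), singletons)))
    g <- igraph::add_vertices(g, length(verts), name = verts)
    if (!is.null(el)) g <- igraph::add_edges(g, t(matrix(match(el, verts), ncol = 2L)))
    return(g)
  }
  df <- utils::read.delim(text = lines, header = TRUE, colClasses = "character")
  g <- igraph::graph_from_data_frame(df[, 1:2], directed = FALSE)
  igraph::E(g)$combined_score <- as.numeric(df[[3L]])
  g
}
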