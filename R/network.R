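#' Build a score-thresholded seed subnetwork
#'
#' Takes the induced subgraph on `seeds` plus `anchors` over the edges of
#' `edge_list` with `combined_score >= min_score`, then removes isolated
#' nodes (nodes with no interaction inside the network — anchors included,
#' they get no special treatment). Seeds absent from the edge list's
#' identifier namespace are reported in the `unmatched` attribute.
#'
#' @param edge_list a `scored_edges` tibble (see [read_string_links()]) or any
#'   tibble with `protein1`, `protein2`, `combined_score`.
#' @param seeds character vector of seed identifiers (e.g. the differentially
#'   expressed proteins overlapping the pathway categories of interest).
#' @param anchors identifiers added on top of the seeds (e.g. the regulators
#'   whose neighborhoods are being probed); may be empty.
#' @param min_score combined-score threshold in `[0, 1]` (the study uses
#'   0.750).
#' @return An igraph with vertex attributes `seed`, `anchor` and edge
#'   attribute `combined_score`; graph attributes `isolated_removed`
#'   (count) and `unmatched` (identifiers never seen in the edge list).
#' @export
build_seed_network <- function(edge_list, seeds, anchors = character(),
                               min_score = 0.750) {
  if (length(seeds) == 0L) stop_cd8("empty seed list", "bad_argument")
  if (min_score < 0 || min_score > 1) stop_cd8("`min_score` must be in [0, 1]", "bad_argument")
  wanted <- unique(c(seeds, anchors))
  known <- unique(c(edge_list$protein1, edge_list$protein2))
  unmatched <- setdiff(wanted, known)

  el <- edge_list[edge_list$combined_score >= min_score &
                    edge_list$protein1 %in% wanted &
                    edge_list$protein2 %in% wanted, , drop = FALSE]
  # every requested node enters the induced graph; ones without a qualifying
  # edge (including identifiers absent from the edge list) fall to the
  # isolation rule below
  nodes <- sort(wanted)
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (nrow(el) > 0L) {
    g <- igraph::add_edges(g, rbind(match(el$protein1, nodes),
                                    match(el$protein2, nodes)))
    igraph::E(g)$combined_score <- el$combined_score
  }
  g <- igraph::simplify(g, edge.attr.comb = list(combined_score = "max"))
  iso <- igraph::degree(g) == 0L
  n_removed <- sum(iso)
  g <- igraph::delete_vertices(g, which(iso))
  igraph::V(g)$seed <- igraph::V(g)$name %in% seeds
  igraph::V(g)$anchor <- igraph::V(g)$name %in% anchors
  g <- igraph::set_graph_attr(g, "isolated_removed", n_removed)
  g <- igraph::set_graph_attr(g, "unmatched", unmatched)
  g
}

#' Exact-distance neighbor sets around an anchor
#'
#' Breadth-first shortest-path (hop) distances within the given graph; edge
#' scores do not weight the distance. `set_d` holds the nodes at distance
#' exactly `d` from the anchor, so the sets are disjoint by construction.
#'
#' @param graph an igraph.
#' @param anchor anchor node name.
#' @param k_max largest distance reported.
#' @return A named list `set_1` ... `set_<k_max>` of character vectors, with
#'   attribute `distances` (named numeric vector, `Inf` if unreachable).
#' @export
khop_sets <- function(graph, anchor, k_max = 2) {
  if (!anchor %in% igraph::V(graph)$name) {
    stop_cd8(sprintf("anchor '%s' not in graph", anchor), "missing_anchor")
  }
  d <- igraph::distances(graph, v = anchor, weights = NA)[1L, ]
  sets <- lapply(seq_len(k_max), function(k) sort(names(d)[d == k]))
  names(sets) <- paste0("set_", seq_len(k_max))
  attr(sets, "distances") <- d
  sets
}

#' Partition nodes by proximity to two anchors
#'
#' Classifies every non-anchor node by whether it lies within `k` hops of
#' anchor A, anchor B, or both: `mutual` is the intersection of the two
#' within-`k` neighborhoods, `unique_a`/`unique_b` are the remainders. The
#' anchors themselves are excluded from all sets. Exact-distance sets per
#' anchor are also reported so per-distance counts can be tabulated either
#' inclusively or exclusively.
#'
#' @param graph an igraph.
#' @param anchor_a,anchor_b distinct anchor node names.
#' @param k neighborhood radius in hops (default 2, the "within 2 degrees of
#'   interaction" reading).
#' @return A `neighborhood_partition` list: `anchor_a`, `anchor_b`,
#'   `unique_a`, `unique_b`, `mutual` (sorted character vectors), `exact_a`,
#'   `exact_b` (lists of exact-distance sets), and `distances` tibble
#'   (`node`, `d_a`, `d_b`, `partition`).
#' @export
partition_interactors <- function(graph, anchor_a, anchor_b, k = 2) {
  if (identical(anchor_a, anchor_b)) stop_cd8("anchors must differ", "bad_argument")
  sets_a <- khop_sets(graph, anchor_a, k_max = k)
  sets_b <- khop_sets(graph, anchor_b, k_max = k)
  d_a <- attr(sets_a, "distances"); d_b <- attr(sets_b, "distances")
  anchors <- c(anchor_a, anchor_b)
  nodes <- setdiff(igraph::V(graph)$name, anchors)
  within_a <- nodes[d_a[nodes] <= k]
  within_b <- nodes[d_b[nodes] <= k]
  mutual <- sort(intersect(within_a, within_b))
  unique_a <- sort(setdiff(within_a, mutual))
  unique_b <- sort(setdiff(within_b, mutual))
  partition <- rep("outside", length(nodes))
  partition[nodes %in% unique_a] <- "unique_a"
  partition[nodes %in% unique_b] <- "unique_b"
  partition[nodes %in% mutual] <- "mutual"
  structure(
    list(anchor_a = anchor_a, anchor_b = anchor_b,
         unique_a = unique_a, unique_b = unique_b, mutual = mutual,
         exact_a = lapply(sets_a, function(s) setdiff(s, anchors)),
         exact_b = lapply(sets_b, function(s) setdiff(s, anchors)),
         k = k,
         distances = tibble(node = nodes,
                            d_a = unname(d_a[nodes]), d_b = unname(d_b[nodes]),
                            partition = partition)),
    class = "neighborhood_partition")
}

#' @export
print.neighborhood_partition <- function(x, ...) {
  cat(sprintf("<neighborhood_partition> within %d hops of %s / %s\n",
              x$k, x$anchor_a, x$anchor_b))
  cat(sprintf("  unique to %s: %d   unique to %s: %d   mutual: %d\n",
              x$anchor_a, length(x$unique_a),
              x$anchor_b, length(x$unique_b), length(x$mutual)))
  for (d in seq_len(x$k)) {
    cat(sprintf("  exact distance %d: %s %d, %s %d\n", d,
                x$anchor_a, length(x$exact_a[[d]]),
                x$anchor_b, length(x$exact_b[[d]])))
  }
  invisible(x)
}

#' @method tidy neighborhood_partition
#' @export
tidy.neighborhood_partition <- function(x, ...) x$distances

#' Basic counts for a constructed network
#'
#' @param graph an igraph, typically from [build_seed_network()].
#' @return A one-row tibble: `nodes`, `edges`, `components`,
#'   `isolated_removed` (0 when the graph does not carry the attribute).
#' @export
network_summary <- function(graph) {
  tibble(
    nodes = igraph::vcount(graph),
    edges = igraph::ecount(graph),
    components = igraph::components(graph)$no,
    isolated_removed = igraph::graph_attr(graph, "isolated_removed") %||% 0L
  )
}

#' Node-attribute table for a partitioned network
#'
#' Joins a [partition_interactors()] result back onto the graph's node set
#' for export next to the GraphML (distances and partition label per node).
#'
#' @param graph the igraph the partition was computed on.
#' @param partition a `neighborhood_partition`.
#' @return A tibble: `node`, `seed`, `anchor`, `d_a`, `d_b`, `partition`.
#' @export
node_attribute_table <- function(graph, partition) {
  base <- tibble(node = igraph::V(graph)$name,
                 seed = igraph::V(graph)$seed %||% NA,
                 anchor = igraph::V(graph)$anchor %||% NA)
  left_join(base, partition$distances, by = "node") |>
    mutate(partition = ifelse(.data$node %in% c(partition$anchor_a, partition$anchor_b),
                              "anchor", .data$partition)) |>
    arrange(.data$node)
}
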