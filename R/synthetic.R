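#' Synthetic label-free proteome with planted effects
#'
#' Generates an intensity matrix from a copy-number model so the proteomic
#' ruler is exactly invertible: every protein gets a true copy number
#' (log-uniform over `copies_range`), a molecular weight, and per-sample
#' intensity `copies * MW * sample_scale`, perturbed by log-normal noise.
#' Histone copy numbers are drawn so that their summed protein mass equals the
#' cellular DNA mass (`sum(copies_h * MW_h) = N_A * dna_mass_per_cell`), which
#' is the identity the ruler rests on. A `de_fraction` of non-histone features
#' is shifted by `effect_log2` (random sign) in the knockout group.
#' Missingness is intensity-dependent (logistic in standardized log
#' intensity, emulating left-censoring); histones are never masked.
#'
#' @param n_features total features.
#' @param n_per_group samples per group (groups `control`, `knockout`).
#' @param de_fraction fraction of non-histone features with a planted shift,
#'   in `[0, 1)`.
#' @param effect_log2 absolute planted shift on the log2 scale.
#' @param missing_rate target overall missingness (0 disables masking).
#' @param n_histones number of histone features.
#' @param noise_sd log2-scale measurement noise (0 gives exact intensities).
#' @param copies_range range of true copies per cell (log-uniform draw).
#' @param dna_mass_per_cell DNA mass per cell in grams.
#' @param seed RNG seed (mandatory; the generator is a pure function of its
#'   arguments).
#' @return A list: `matrix` (an [intensity_matrix()] with annotations) and
#'   `truth` (list: `copies` named vector of control-group true copies,
#'   `planted_de` tibble of shifted features with signed effects, `histones`,
#'   `sample_scales`, `params`).
#' @export
gen_intensity_matrix <- function(n_features = 2000, n_per_group = 4,
                                 de_fraction = 0.1, effect_log2 = 2,
                                 missing_rate = 0.1, n_histones = 4,
                                 noise_sd = 0.25,
                                 copies_range = c(1e2, 1e7),
                                 dna_mass_per_cell = .DEFAULT_DNA_PG,
                                 seed) {
  if (missing(seed)) stop_cd8("`seed` is required", "bad_argument")
  if (de_fraction < 0 || de_fraction >= 1) {
    stop_cd8("`de_fraction` must be in [0, 1)", "bad_argument")
  }
  stopifnot(n_histones >= 1, n_features > n_histones)
  withr::with_seed(seed, {
    n_samples <- 2L * n_per_group
    features <- sprintf("prot%04d", seq_len(n_features))
    histones <- sprintf("hist%02d", seq_len(n_histones))
    features[seq_len(n_histones)] <- histones
    samples <- c(sprintf("ctl%d", seq_len(n_per_group)),
                 sprintf("ko%d", seq_len(n_per_group)))
    groups <- stats::setNames(rep(c("control", "knockout"), each = n_per_group),
                              samples)

    mw <- stats::rlnorm(n_features, meanlog = log(5e4), sdlog = 0.5)
    is_h <- features %in% histones
    # histone copies: random proportions of the DNA-mass-equivalent protein mass
    w <- stats::runif(n_histones); w <- w / sum(w)
    copies <- 10^stats::runif(n_features, log10(copies_range[1L]), log10(copies_range[2L]))
    copies[is_h] <- w * .AVOGADRO * dna_mass_per_cell / mw[is_h]

    # plant effects among quantifiable features: the bottom of the abundance
    # range is mostly left-censored and carries no testable signal
    candidates <- features[!is_h & copies >= stats::quantile(copies[!is_h], 0.2)]
    n_de <- round(de_fraction * sum(!is_h))
    de_features <- sort(sample(candidates, n_de))
    signs <- sample(c(-1, 1), n_de, replace = TRUE)
    effect <- stats::setNames(rep(0, n_features), features)
    effect[de_features] <- signs * effect_log2

    sample_scales <- 2^stats::rnorm(n_samples, 0, 0.3)
    base <- copies * mw  # intensity units per unit sample scale
    values <- matrix(0, n_features, n_samples, dimnames = list(features, samples))
    for (j in seq_len(n_samples)) {
      shift <- if (groups[j] == "knockout") effect else rep(0, n_features)
      noise <- if (noise_sd > 0) stats::rnorm(n_features, 0, noise_sd) else rep(0, n_features)
      noise[is_h] <- 0  # histones stay exact so the ruler is invertible
      values[, j] <- base * 2^(shift + noise) * sample_scales[j]
    }

    if (missing_rate > 0) {
      z <- scale(log2(as.vector(values)))[, 1L]
      p_miss <- stats::plogis(stats::qlogis(missing_rate) - z)
      mask <- matrix(stats::runif(length(values)) < p_miss,
                     n_features, n_samples)
      mask[is_h, ] <- FALSE
      values[mask] <- NA_real_
    }

    ann <- tibble(feature = features, molecular_weight = mw,
                  is_histone = is_h, gene_symbol = features)
    list(
      matrix = intensity_matrix(values, groups = groups, annotations = ann),
      truth = list(
        copies = stats::setNames(copies, features),
        planted_de = tibble(feature = de_features, effect_log2 = signs * effect_log2),
        histones = histones,
        sample_scales = stats::setNames(sample_scales, samples),
        params = list(n_features = n_features, n_per_group = n_per_group,
                      de_fraction = de_fraction, effect_log2 = effect_log2,
                      missing_rate = missing_rate, noise_sd = noise_sd,
                      dna_mass_per_cell = dna_mass_per_cell, seed = seed)))
  })
}

#' Synthetic scored interaction graph with planted anchor neighborhoods
#'
#' Constructively realizes an exact two-anchor neighborhood specification:
#' per anchor, the number of nodes at shortest-path distance exactly 1 and
#' exactly 2, and the number of `mutual` nodes lying within 2 hops of both
#' anchors. Mutual nodes are placed at distance exactly 2 from each anchor
#' through one gateway neighbor per anchor, so they count toward both
#' anchors' distance-2 sets; layered construction adds no other edges between
#' layers, so no shortcut can change a distance. Planted edges carry combined
#' scores at or above `threshold`; decoy nodes/edges score strictly below it
#' and disappear when the network is built at `min_score = threshold`.
#'
#' @param anchor_spec list with `a = list(d1, d2)`, `b = list(d1, d2)` and
#'   `mutual` (counts). Feasibility requires `mutual <= min(a$d2, b$d2)` and,
#'   when `mutual > 0` or `d2 > 0`, `d1 >= 1` for the affected anchor.
#' @param anchor_names names for the two anchors.
#' @param n_decoy_nodes,n_decoy_edges decoy graph size (edges sampled among
#'   decoy and planted nodes, scores below threshold).
#' @param threshold combined-score threshold separating planted from decoy
#'   edges (default 0.750).
#' @param taxon_prefix STRING-style taxon prefix used when writing the links
#'   file.
#' @param seed RNG seed (mandatory).
#' @return A list: `edges` (a `scored_edges` tibble, planted + decoy),
#'   `truth` (anchor names, per-anchor exact-distance member sets, `mutual`
#'   members, `nodes` = all planted node names, `threshold`, `params`).
#' @export
gen_scored_graph <- function(anchor_spec = list(a = list(d1 = 11, d2 = 42),
                                                b = list(d1 = 10, d2 = 28),
                                                mutual = 17),
                             anchor_names = c("Myc", "Cul4b"),
                             n_decoy_nodes = 20, n_decoy_edges = 40,
                             threshold = 0.750, taxon_prefix = "10090",
                             seed) {
  if (missing(seed)) stop_cd8("`seed` is required", "bad_argument")
  d1a <- anchor_spec$a$d1; d2a <- anchor_spec$a$d2
  d1b <- anchor_spec$b$d1; d2b <- anchor_spec$b$d2
  mutual_n <- anchor_spec$mutual %||% 0L
  if (mutual_n > min(d2a, d2b)) {
    stop_cd8(sprintf(
      "infeasible spec: mutual (%d) exceeds a distance-2 count (a: %d, b: %d) — mutual nodes are placed at distance 2 from both anchors",
      mutual_n, d2a, d2b), "infeasible_spec")
  }
  for (side in c("a", "b")) {
    d1 <- anchor_spec[[side]]$d1; d2 <- anchor_spec[[side]]$d2
    if ((d2 > 0 || mutual_n > 0) && d1 < 1) {
      stop_cd8(sprintf(
        "infeasible spec: anchor %s needs d1 >= 1 to support distance-2 nodes",
        side), "infeasible_spec")
    }
  }
  withr::with_seed(seed, {
    A <- anchor_names[1L]; B <- anchor_names[2L]
    d1a_nodes <- if (d1a > 0) sprintf("a1_%02d", seq_len(d1a)) else character()
    d1b_nodes <- if (d1b > 0) sprintf("b1_%02d", seq_len(d1b)) else character()
    mutual_nodes <- if (mutual_n > 0) sprintf("mut_%02d", seq_len(mutual_n)) else character()
    u2a <- if (d2a - mutual_n > 0) sprintf("a2_%02d", seq_len(d2a - mutual_n)) else character()
    u2b <- if (d2b - mutual_n > 0) sprintf("b2_%02d", seq_len(d2b - mutual_n)) else character()

    edges <- list()
    add <- function(x, y) edges[[length(edges) + 1L]] <<- c(x, y)
    for (v in d1a_nodes) add(A, v)
    for (v in d1b_nodes) add(B, v)
    if (mutual_n > 0) {
      for (v in mutual_nodes) { add(d1a_nodes[1L], v); add(d1b_nodes[1L], v) }
    }
    # spread unique distance-2 nodes round-robin over the distance-1 layer
    for (i in seq_along(u2a)) add(d1a_nodes[(i - 1L) %% d1a + 1L], u2a[i])
    for (i in seq_along(u2b)) add(d1b_nodes[(i - 1L) %% d1b + 1L], u2b[i])

    el <- do.call(rbind, edges)
    planted <- if (is.null(el)) {
      tibble(protein1 = character(), protein2 = character(),
             combined_score = double())
    } else {
      tibble(protein1 = el[, 1L], protein2 = el[, 2L],
             combined_score = sample(seq(round(threshold * 1000), 999L),
                                     nrow(el), replace = TRUE) / 1000)
    }

    planted_nodes <- c(A, B, d1a_nodes, d1b_nodes, mutual_nodes, u2a, u2b)
    decoy_nodes <- if (n_decoy_nodes > 0) sprintf("decoy_%02d", seq_len(n_decoy_nodes)) else character()
    decoys <- NULL
    if (n_decoy_edges > 0 && length(decoy_nodes) > 0) {
      pool <- c(decoy_nodes, planted_nodes)
      p1 <- sample(decoy_nodes, n_decoy_edges, replace = TRUE)
      p2 <- sample(pool, n_decoy_edges, replace = TRUE)
      keep <- p1 != p2
      decoys <- tibble(
        protein1 = pmin(p1[keep], p2[keep]), protein2 = pmax(p1[keep], p2[keep]),
        combined_score = sample(seq_len(round(threshold * 1000) - 1L),
                                sum(keep), replace = TRUE) / 1000) |>
        distinct(.data$protein1, .data$protein2, .keep_all = TRUE)
    }
    all_edges <- bind_rows(planted, decoys) |>
      arrange(.data$protein1, .data$protein2)
    list(
      edges = scored_edges(all_edges, taxon_prefix = taxon_prefix),
      truth = list(
        anchor_a = A, anchor_b = B,
        exact_a = list(set_1 = sort(d1a_nodes), set_2 = sort(c(u2a, mutual_nodes))),
        exact_b = list(set_1 = sort(d1b_nodes), set_2 = sort(c(u2b, mutual_nodes))),
        mutual = sort(mutual_nodes),
        nodes = planted_nodes, decoy_nodes = decoy_nodes,
        threshold = threshold,
        params = list(anchor_spec = anchor_spec, seed = seed)))
  })
}

#' Synthetic gene-set collection with planted enrichment
#'
#' Planted terms draw a declared number of members from the DE set (so their
#' hypergeometric enrichment is known by construction); decoy terms are drawn
#' uniformly from the universe.
#'
#' @param universe feature universe.
#' @param de_features the DE subset of the universe.
#' @param n_planted,planted_size,planted_overlap planted terms: how many, the
#'   term size and how many members come from the DE set (`overlap <= size`).
#' @param n_decoys,decoy_size decoy terms drawn uniformly from the universe.
#' @param seed RNG seed (mandatory).
#' @return A list: `sets` (named list, GMT-compatible) and `truth`
#'   (`planted_terms`, `params`).
#' @export
gen_gene_sets <- function(universe, de_features, n_planted = 3,
                          planted_size = 20, planted_overlap = 15,
                          n_decoys = 20, decoy_size = 20, seed) {
  if (missing(seed)) stop_cd8("`seed` is required", "bad_argument")
  if (planted_overlap > planted_size) {
    stop_cd8("planted overlap exceeds term size", "bad_argument")
  }
  if (planted_overlap > length(de_features)) {
    stop_cd8("planted overlap exceeds the DE set", "bad_argument")
  }
  withr::with_seed(seed, {
    non_de <- setdiff(universe, de_features)
    planted <- lapply(seq_len(n_planted), function(i) {
      c(sample(de_features, planted_overlap),
        sample(non_de, planted_size - planted_overlap))
    })
    names(planted) <- sprintf("PLANTED_%02d", seq_len(n_planted))
    decoys <- lapply(seq_len(n_decoys), function(i) sample(universe, decoy_size))
    names(decoys) <- sprintf("DECOY_%02d", seq_len(n_decoys))
    sets <- c(planted, decoys)
    list(sets = sets,
         truth = list(planted_terms = names(planted),
                      params = list(n_planted = n_planted,
                                    planted_size = planted_size,
                                    planted_overlap = planted_overlap,
                                    n_decoys = n_decoys, decoy_size = decoy_size,
                                    seed = seed)))
  })
}

#' Synthetic bulk RNA-seq counts with planted DEGs
#'
#' Negative-binomial counts with a gene-length covariate (longer genes draw
#' proportionally more reads, as in read-count data) and a planted
#' `effect_log2` fold change (random sign unless `one_sided_up = TRUE`) for a
#' fraction of genes in the knockout group.
#'
#' @param n_genes,n_per_group matrix size (groups `control`, `knockout`).
#' @param deg_fraction fraction of genes with a planted effect, in `[0, 1)`.
#' @param effect_log2 absolute planted log2 fold change.
#' @param dispersion NB dispersion (`size = 1/dispersion`).
#' @param one_sided_up plant only upregulation.
#' @param seed RNG seed (mandatory).
#' @return A list: `counts` (integer matrix), `gene_lengths` (named, bp),
#'   `groups`, `truth` (`planted` tibble with signed effects, `params`).
#' @export
gen_bulk_counts <- function(n_genes = 5000, n_per_group = 4,
                            deg_fraction = 0.02, effect_log2 = 3,
                            dispersion = 0.01, one_sided_up = FALSE, seed) {
  if (missing(seed)) stop_cd8("`seed` is required", "bad_argument")
  if (deg_fraction < 0 || deg_fraction >= 1) {
    stop_cd8("`deg_fraction` must be in [0, 1)", "bad_argument")
  }
  withr::with_seed(seed, {
    genes <- sprintf("gene%05d", seq_len(n_genes))
    samples <- c(sprintf("ctl%d", seq_len(n_per_group)),
                 sprintf("ko%d", seq_len(n_per_group)))
    groups <- stats::setNames(rep(c("control", "knockout"), each = n_per_group),
                              samples)
    lengths_bp <- stats::setNames(round(stats::runif(n_genes, 500, 5000)), genes)
    base_expr <- stats::rlnorm(n_genes, meanlog = log(20), sdlog = 1.2)
    mu <- base_expr * lengths_bp / 1000  # reads scale with length

    n_deg <- round(deg_fraction * n_genes)
    # plant among expressed genes (expected count >= 20, the usual
    # filter-by-expression floor); shot noise drowns an effect at a handful
    # of reads, which is a detectability limit, not a property of the test
    expressed <- genes[mu >= 20]
    planted_genes <- sort(sample(expressed, n_deg))
    signs <- if (one_sided_up) rep(1, n_deg) else sample(c(-1, 1), n_deg, replace = TRUE)
    effect <- stats::setNames(rep(0, n_genes), genes)
    effect[planted_genes] <- signs * effect_log2

    counts <- matrix(0L, n_genes, length(samples), dimnames = list(genes, samples))
    for (j in seq_along(samples)) {
      mu_j <- if (groups[j] == "knockout") mu * 2^effect else mu
      counts[, j] <- stats::rnbinom(n_genes, mu = mu_j, size = 1 / dispersion)
    }
    list(counts = counts, gene_lengths = lengths_bp, groups = groups,
         truth = list(planted = tibble(gene = planted_genes,
                                       effect_log2 = signs * effect_log2),
                      params = list(n_genes = n_genes, n_per_group = n_per_group,
                                    deg_fraction = deg_fraction,
                                    effect_log2 = effect_log2,
                                    dispersion = dispersion, seed = seed)))
  })
}

#' Synthetic UMI matrix with planted QC violators and subsets
#'
#' Builds a sparse cells x genes matrix in which a declared number of cells or
#' genes violates exactly one QC filter each (classes constructed
#' non-overlapping, so per-filter removal counts are unambiguous under the
#' sequential filter order), and passing cells carry planted Sell/Il7r
#' hi-lo marker classes.
#'
#' The structure is deterministic given the spec (which cell detects which
#' genes); only the counts are random. Filler genes are assigned to passing
#' cells round-robin so every retained gene comfortably exceeds `min_cells`.
#'
#' @param n_pass number of passing (base) cells.
#' @param qc_spec planted violator counts:
#'   `list(cells_min_genes =, genes_min_cells =, cells_max_genes =, cells_max_mito =)`.
#' @param subset_spec named integer vector of planted subset sizes among the
#'   passing cells, e.g. `c(LLE = 40, TEM = 30, TCM = 30)`; remaining passing
#'   cells get the `unassigned` gate (Sell-hi/Il7r-lo). Must sum to at most
#'   `n_pass`.
#' @param thresholds the QC thresholds the violators are planted against
#'   (defaults mirror [qc_filter()]).
#' @param genes_per_cell detected filler genes per passing cell; must lie
#'   strictly between `min_genes` and `max_genes`.
#' @param n_filler size of the filler gene pool; with violators the total gene
#'   count is `n_filler + n_mito + 2 markers + genes_min_cells`.
#' @param n_mito number of mitochondrial genes (`mt-*`).
#' @param seed RNG seed (mandatory).
#' @return A list: `umi` (a [umi_matrix()]) and `truth` (`qc` tibble of
#'   planted removal counts per step, `subsets` tibble of planted labels,
#'   `params`).
#' @export
gen_umi_matrix <- function(n_pass = 120,
                           qc_spec = list(cells_min_genes = 12,
                                          genes_min_cells = 15,
                                          cells_max_genes = 6,
                                          cells_max_mito = 9),
                           subset_spec = c(LLE = 40, TEM = 30, TCM = 30),
                           thresholds = list(min_genes = 200, min_cells = 3,
                                             max_genes = 6100, max_mito = 0.07),
                           genes_per_cell = 400, n_filler = 6300,
                           n_mito = 10, seed) {
  if (missing(seed)) stop_cd8("`seed` is required", "bad_argument")
  if (sum(subset_spec) > n_pass) {
    stop_cd8("subset spec exceeds the number of passing cells", "bad_argument")
  }
  if (genes_per_cell <= thresholds$min_genes || genes_per_cell >= thresholds$max_genes) {
    stop_cd8("`genes_per_cell` must lie strictly between min_genes and max_genes",
             "bad_argument")
  }
  if (n_filler <= thresholds$max_genes) {
    stop_cd8("`n_filler` must exceed `max_genes` so over-detection is plantable",
             "bad_argument")
  }
  # round-robin coverage per filler gene must clear the gene filter
  min_coverage <- floor(n_pass * genes_per_cell / n_filler)
  if (min_coverage < thresholds$min_cells + 2) {
    stop_cd8(sprintf(
      "filler coverage %d too thin for min_cells = %d; raise n_pass or genes_per_cell",
      min_coverage, thresholds$min_cells), "infeasible_spec")
  }
  withr::with_seed(seed, {
    filler <- sprintf("gene%05d", seq_len(n_filler))
    mito <- sprintf("mt-g%02d", seq_len(n_mito))
    markers <- c("Sell", "Il7r")
    rare <- if (qc_spec$genes_min_cells > 0)
      sprintf("rare%03d", seq_len(qc_spec$genes_min_cells)) else character()
    genes <- c(filler, mito, markers, rare)

    cells <- list(
      pass = sprintf("pass_%03d", seq_len(n_pass)),
      lowg = if (qc_spec$cells_min_genes > 0)
        sprintf("lowgene_%03d", seq_len(qc_spec$cells_min_genes)) else character(),
      highg = if (qc_spec$cells_max_genes > 0)
        sprintf("highgene_%03d", seq_len(qc_spec$cells_max_genes)) else character(),
      mito = if (qc_spec$cells_max_mito > 0)
        sprintf("himito_%03d", seq_len(qc_spec$cells_max_mito)) else character())
    barcodes <- unlist(cells, use.names = FALSE)

    ii <- integer(0); jj <- integer(0); xx <- integer(0)
    put <- function(cell_idx, gene_names, counts) {
      ii <<- c(ii, rep(cell_idx, length(gene_names)))
      jj <<- c(jj, match(gene_names, genes))
      xx <<- c(xx, counts)
    }
    cell_index <- stats::setNames(seq_along(barcodes), barcodes)

    # planted subset labels over passing cells (trailing ones unassigned)
    labels <- rep("unassigned", n_pass)
    if (sum(subset_spec) > 0) {
      labels[seq_len(sum(subset_spec))] <- rep(names(subset_spec), subset_spec)
    }

    for (i in seq_len(n_pass)) {
      cell <- cells$pass[i]
      start <- ((i - 1L) * genes_per_cell) %% n_filler
      idx <- (start + seq_len(genes_per_cell) - 1L) %% n_filler + 1L
      fill_counts <- stats::rpois(genes_per_cell, 1) + 1L
      put(cell_index[cell], filler[idx], fill_counts)
      total <- sum(fill_counts)
      # ~1.5% mitochondrial signal, comfortably below the threshold;
      # rotate the mito pair so every mito gene clears the gene filter
      mito_pair <- mito[c((i - 1L) %% n_mito, i %% n_mito) + 1L]
      put(cell_index[cell], mito_pair,
          pmax(1L, round(c(0.01, 0.005) * total)))
      lab <- labels[i]
      sell_hi <- lab %in% c("TCM", "unassigned")
      il7r_hi <- lab %in% c("TEM", "TCM")
      if (sell_hi) put(cell_index[cell], "Sell", 2L + stats::rpois(1, 2))
      if (il7r_hi) put(cell_index[cell], "Il7r", 2L + stats::rpois(1, 2))
    }
    # under-detection violators: far below min_genes, removed at step 1
    for (cell in cells$lowg) {
      k <- max(1L, thresholds$min_genes %/% 2L)
      put(cell_index[cell], filler[seq_len(k)], rep(1L, k))
    }
    # rare genes: in exactly (min_cells - 1) passing cells, removed at step 2
    host <- cells$pass[seq_len(thresholds$min_cells - 1L)]
    for (g in rare) {
      for (h in host) put(cell_index[[h]], g, 1L)
    }
    # over-detection violators: above max_genes, removed at step 3
    for (cell in cells$highg) {
      k <- min(n_filler, thresholds$max_genes + 100L)
      put(cell_index[cell], filler[seq_len(k)], rep(1L, k))
      put(cell_index[cell], mito[1L], max(1L, round(0.01 * k)))
    }
    # mito violators: normal detection, ~2x the mito threshold, removed at step 4
    for (cell in cells$mito) {
      fill_counts <- stats::rpois(genes_per_cell, 1) + 1L
      put(cell_index[cell], filler[seq_len(genes_per_cell)], fill_counts)
      total <- sum(fill_counts)
      frac <- min(0.45, 2 * thresholds$max_mito)
      put(cell_index[cell], mito[1L], ceiling(frac / (1 - frac) * total))
    }

    m <- Matrix::sparseMatrix(i = ii, j = jj, x = as.numeric(xx),
                              dims = c(length(barcodes), length(genes)),
                              dimnames = list(barcodes, genes))
    umi <- umi_matrix(m, mito_genes = "mt-")
    list(
      umi = umi,
      truth = list(
        qc = tibble(
          step = c("cells_min_genes", "genes_min_cells",
                   "cells_max_genes", "cells_max_mito"),
          planted_removed = c(qc_spec$cells_min_genes, qc_spec$genes_min_cells,
                              qc_spec$cells_max_genes, qc_spec$cells_max_mito)),
        subsets = tibble(cell = cells$pass, label = labels),
        params = list(n_pass = n_pass, qc_spec = qc_spec,
                      subset_spec = subset_spec, thresholds = thresholds,
                      genes_per_cell = genes_per_cell, n_filler = n_filler,
                      seed = seed)))
  })
}
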