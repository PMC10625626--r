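test_that("TPM follows the RPK / per-million-factor definition", {
  # one gene: normalization forces 1e6 regardless of count
  m1 <- matrix(c(7, 900), nrow = 1, dimnames = list("g1", c("s1", "s2")))
  expect_equal(as.vector(tpm(m1, c(g1 = 1500))), c(1e6, 1e6))

  # worked example: counts (10, 30), lengths (1 kb, 2 kb)
  m2 <- matrix(c(10, 30), ncol = 1, dimnames = list(c("g1", "g2"), "s1"))
  out <- tpm(m2, c(g1 = 1000, g2 = 2000))
  expect_equal(as.vector(out), c(4e5, 6e5))

  # random matrices: every column sums to one million
  withr::with_seed(6, {
    m3 <- matrix(rpois(400, 50), nrow = 100,
                 dimnames = list(sprintf("g%03d", 1:100), sprintf("s%d", 1:4)))
    len <- setNames(round(runif(100, 300, 8000)), rownames(m3))
  })
  expect_equal(unname(colSums(tpm(m3, len))), rep(1e6, 4), tolerance = 1e-9)

  # zero-length genes are excluded with a report; all-zero samples error
  len2 <- len; len2["g001"] <- 0
  out2 <- tpm(m3, len2)
  expect_equal(attr(out2, "excluded_genes"), "g001")
  expect_equal(nrow(out2), 99)
  m4 <- m3; m4[, 2] <- 0
  expect_error(tpm(m4, len), class = "cd8omics_all_zero_sample")
})

test_that("DEG presets gate fold change and p-value as printed", {
  # construct TPM with controlled log2 shifts and tiny within-group noise
  withr::with_seed(10, {
    n <- c(4, 4)
    base <- matrix(2^rnorm(50 * 8, 8, 0.05), nrow = 50,
                   dimnames = list(sprintf("g%02d", 1:50),
                                   c(sprintf("c%d", 1:4), sprintf("k%d", 1:4))))
  })
  groups <- setNames(rep(c("control", "knockout"), each = 4), colnames(base))
  # g01: strong shift but |log2FC| = 1.5 < 2 -> myc preset must reject
  base["g01", 5:8] <- base["g01", 5:8] * 2^1.5
  # g02: modest shift 0.25 -> cul4b preset must accept (p will be tiny)
  base["g02", 5:8] <- base["g02", 5:8] * 2^0.25
  # g03: clear 8-fold shift -> myc preset must accept
  base["g03", 5:8] <- base["g03", 5:8] * 2^3
  # g04: downshift -0.5: significant for myc? no (gate); for cul4b? no (upper gate only)
  base["g04", 5:8] <- base["g04", 5:8] * 2^-0.5

  myc <- call_degs(base, groups, preset = "myc")
  expect_equal(myc$direction[myc$feature == "g01"], "unchanged")
  expect_equal(myc$direction[myc$feature == "g03"], "up")
  cul <- call_degs(base, groups, preset = "cul4b")
  expect_equal(cul$direction[cul$feature == "g02"], "up")
  expect_equal(cul$direction[cul$feature == "g04"], "unchanged")  # no lower gate
  expect_error(call_degs(base, groups, preset = "other"))
})

test_that("QC filters run sequentially with exact per-step accounting", {
  u <- gen_umi_matrix(seed = 11)
  res <- qc_filter(u$umi)
  expect_equal(res$report$removed, u$truth$qc$planted_removed)
  expect_equal(res$report$step, u$truth$qc$step)
  # accounting identity per axis
  before <- attr(res$report, "before"); after <- attr(res$report, "after")
  cells_removed <- sum(res$report$removed[res$report$axis == "cells"])
  genes_removed <- sum(res$report$removed[res$report$axis == "genes"])
  expect_equal(before[1] - cells_removed, after[1])
  expect_equal(before[2] - genes_removed, after[2])
  # survivors are exactly the planted passing cells
  expect_setequal(rownames(res$umi$counts), u$truth$subsets$cell)
})

test_that("a matrix that passes every filter is returned unchanged", {
  u <- gen_umi_matrix(qc_spec = list(cells_min_genes = 0, genes_min_cells = 0,
                                     cells_max_genes = 0, cells_max_mito = 0),
                      subset_spec = c(LLE = 10, TEM = 10, TCM = 10),
                      thresholds = list(min_genes = 100, min_cells = 3,
                                        max_genes = 700, max_mito = 0.07),
                      n_pass = 60, genes_per_cell = 300, n_filler = 800, seed = 3)
  res <- qc_filter(u$umi)
  expect_equal(sum(res$report$removed), 0L)
  expect_equal(dim(res$umi$counts), dim(u$umi$counts))
  expect_error(qc_filter(u$umi, min_genes = 0), class = "cd8omics_bad_argument")
})

test_that("a cell under the minimum gene count is removed at step one", {
  withr::with_seed(4, {
    m <- Matrix::Matrix(rpois(30 * 20, 2), nrow = 30, sparse = TRUE)
  })
  dimnames(m) <- list(sprintf("cell%02d", 1:30), sprintf("gene%02d", 1:20))
  m[1, ] <- 0; m[1, 1:5] <- 1  # 5 detected genes
  u <- umi_matrix(m)
  res <- qc_filter(u, min_genes = 10, min_cells = 1, max_genes = 19, max_mito = 0.5)
  expect_false("cell01" %in% rownames(res$umi$counts))
  expect_equal(res$report$removed[res$report$step == "cells_min_genes"], 1L)
})

test_that("filter order matters: the documented order differs from gene-first", {
  # cell c1 detects only g1; g1 is detected in c1 and c2; g3 only in c3.
  m <- Matrix::sparseMatrix(
    i = c(1, 2, 2, 3, 3),
    j = c(1, 1, 2, 2, 3),
    x = 1,
    dims = c(3, 3), dimnames = list(c("c1", "c2", "c3"), c("g1", "g2", "g3")))
  u <- umi_matrix(m)
  res <- qc_filter(u, min_genes = 2, min_cells = 2, max_genes = 100, max_mito = 0.5)
  # documented order: c1 removed first (1 gene), then g1 (now 1 cell) and g3 drop
  expect_equal(res$report$removed[1:2], c(1L, 2L))
  # gene-first order instead removes only g3, then cells c1 and c3 fall under
  genes_first_gene_removed <- sum(Matrix::colSums(m > 0) < 2)      # g3 only
  m2 <- m[, Matrix::colSums(m > 0) >= 2, drop = FALSE]
  genes_first_cells_removed <- sum(Matrix::rowSums(m2 > 0) < 2)    # c1 and c3
  expect_equal(genes_first_gene_removed, 1L)
  expect_equal(genes_first_cells_removed, 2L)
  # totals differ between the two orders on the same matrix
  expect_false(identical(c(1L, 2L),
                         c(genes_first_cells_removed, genes_first_gene_removed)))
})

test_that("HVG selection is driven by dispersion at matched mean", {
  withr::with_seed(19, {
    n_cells <- 80
    flat <- matrix(rep(seq(0.5, 3, length.out = 30), each = n_cells) +
                     rnorm(80 * 30, 0, 0.2),
                   nrow = n_cells,
                   dimnames = list(NULL, sprintf("g%02d", 1:30)))
    # one gene with ~10x the variance of its mean-matched peers
    flat[, "g15"] <- mean(flat[, "g15"]) + rnorm(n_cells, 0, sqrt(10) * 0.2)
    constant <- matrix(1, n_cells, 1, dimnames = list(NULL, "const"))
    mat <- cbind(flat, constant)
  })
  hv <- select_hvg(mat, n_top = 5, n_bins = 5)
  expect_equal(hv[1], "g15")
  expect_false("const" %in% select_hvg(mat, n_top = 30, n_bins = 5))  # zero dispersion
  # invariant to cell order
  hv2 <- select_hvg(mat[sample(nrow(mat)), ], n_top = 5, n_bins = 5)
  expect_equal(hv, hv2)
  expect_error(select_hvg(mat, n_top = 100), class = "cd8omics_bad_argument")
})

test_that("covariate regression leaves orthogonal residuals", {
  withr::with_seed(25, {
    n <- 60
    total <- runif(n, 500, 5000)
    mito <- runif(n, 0, 0.1)
    y_lin <- 2 + 0.003 * total                 # exactly linear in a covariate
    y_other <- rnorm(n)
    mat <- cbind(lin = y_lin, other = y_other,
                 noisy = 0.001 * total - 5 * mito + rnorm(n))
  })
  covs <- data.frame(total = total, mito = mito)
  res <- regress_out(mat, covs)
  expect_equal(max(abs(res[, "lin"])), 0, tolerance = 1e-9)
  for (g in colnames(mat)) {
    # covariance for all genes; correlation only where residuals are non-null
    expect_lt(abs(cov(res[, g], total)) / (sd(total) * max(sd(mat[, g]), 1)), 1e-8)
    expect_lt(abs(cov(res[, g], mito)) / (sd(mito) * max(sd(mat[, g]), 1)), 1e-8)
    if (sd(res[, g]) > 1e-8) {
      expect_lt(abs(cor(res[, g], total)), 1e-8)
      expect_lt(abs(cor(res[, g], mito)), 1e-8)
    }
  }
  # an orthogonal gene comes back centered but otherwise intact
  expect_equal(sd(res[, "other"]), sd(y_other), tolerance = 0.15)
  expect_warning(regress_out(mat, data.frame(total = total, k = rep(1, n))),
                 "constant")
})

test_that("scaling yields unit variance with symmetric clipping", {
  withr::with_seed(30, {
    mat <- matrix(rnorm(200 * 10), 200, 10,
                  dimnames = list(NULL, sprintf("g%02d", 1:10)))
  })
  sc <- scale_clip(mat)
  expect_equal(unname(apply(sc, 2, sd)), rep(1, 10), tolerance = 1e-9)

  mat2 <- mat; mat2[1, 1] <- 50 * sd(mat[, 1]) + mean(mat[, 1])
  sc2 <- scale_clip(mat2, max_sd = 10)
  expect_equal(max(sc2[, 1]), 10)
  expect_true(all(abs(sc2) <= abs(scale(mat2)) + 1e-9))  # clipping never grows values

  mat3 <- cbind(mat, flat = rep(2, 200))
  sc3 <- scale_clip(mat3)
  expect_equal(unname(sc3[, "flat"]), rep(0, 200))
  expect_equal(attr(sc3, "zero_variance"), "flat")
})

test_that("PCA variance ratios match a dense eigendecomposition", {
  withr::with_seed(33, {
    # rank-1 dominant structure
    u <- rnorm(40); v <- rnorm(15)
    rank1 <- outer(u, v) + matrix(rnorm(600, 0, 1e-3), 40, 15)
  })
  p1 <- pca_scree(rank1, 3)
  expect_gt(p1$variance_ratio[1], 0.99)
  expect_true(all(diff(p1$variance_ratio) <= 1e-12))
  expect_lte(sum(p1$variance_ratio), 1 + 1e-9)

  withr::with_seed(34, mat <- matrix(rnorm(200), 20, 10))
  p <- pca_scree(mat, 10)
  centered <- scale(mat, scale = FALSE)
  ev <- eigen(cov(centered))$values
  expect_equal(p$variance_ratio, ev / sum(ev), tolerance = 1e-9)
  expect_error(pca_scree(mat, 11), class = "cd8omics_bad_argument")
})

test_that("per-10k inclusion implements the one-transcript rule", {
  m <- Matrix::sparseMatrix(i = c(1, 2, 3, 1, 2, 3), j = c(1, 1, 1, 2, 2, 2),
                            x = c(1, 0, 1, 9999, 20000, 19999),
                            dims = c(3, 2),
                            dimnames = list(c("a", "b", "c"), c("goi", "rest")))
  u <- umi_matrix(m)
  mask <- per10k_mask(u, "goi")
  expect_true(mask[["a"]])    # 1 / 10000 = exactly the rule
  expect_false(mask[["b"]])   # zero transcripts
  expect_false(mask[["c"]])   # 1 / 20000 < 1 per 10k
  expect_error(per10k_mask(u, "absent"), class = "cd8omics_missing_gene")
})

test_that("marker gating assigns subsets deterministically", {
  mat <- rbind(c(5, 5), c(0, 0), c(0, 5), c(5, 0))
  dimnames(mat) <- list(sprintf("cell%d", 1:4), c("Sell", "Il7r"))
  lab <- classify_subsets(mat)
  expect_equal(as.character(lab$label), c("TCM", "LLE", "TEM", "unassigned"))

  # invariant to cell order and to unrelated genes
  mat2 <- cbind(mat, junk = c(9, 9, 9, 9))[c(3, 1, 4, 2), ]
  lab2 <- classify_subsets(mat2)
  expect_equal(as.character(lab2$label[match(lab$cell, lab2$cell)]),
               as.character(lab$label))
  expect_error(classify_subsets(mat[, 1, drop = FALSE]),
               class = "cd8omics_missing_gene")
})

test_that("planted subsets are recovered through the full single-cell path", {
  u <- gen_umi_matrix(seed = 21)
  qc <- qc_filter(u$umi)
  norm <- normalize_per_cell(qc$umi, log1p = FALSE)
  lab <- classify_subsets(norm)
  truth <- u$truth$subsets$label[match(lab$cell, u$truth$subsets$cell)]
  expect_equal(as.character(lab$label), truth)
})

test_that("MTX trio round-trips a UMI matrix", {
  u <- gen_umi_matrix(n_pass = 40, genes_per_cell = 300, n_filler = 800,
                      qc_spec = list(cells_min_genes = 2, genes_min_cells = 2,
                                     cells_max_genes = 1, cells_max_mito = 1),
                      thresholds = list(min_genes = 100, min_cells = 3,
                                        max_genes = 700, max_mito = 0.07),
                      subset_spec = c(LLE = 10, TEM = 10, TCM = 10), seed = 8)
  d <- withr::local_tempdir()
  write_umi_mtx(u$umi, file.path(d, "m.mtx"), file.path(d, "barcodes.tsv"),
                file.path(d, "features.tsv"))
  back <- read_umi_mtx(file.path(d, "m.mtx"), file.path(d, "barcodes.tsv"),
                       file.path(d, "features.tsv"))
  expect_equal(dim(back$counts), dim(u$umi$counts))
  expect_equal(Matrix::norm(back$counts - u$umi$counts, "F"), 0)
  expect_equal(back$mito, u$umi$mito)
})
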