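make_de <- function(features, up = character(), down = character()) {
  tibble::tibble(
    feature = features,
    log2fc = ifelse(features %in% up, 1, ifelse(features %in% down, -1, 0)),
    t_statistic = ifelse(features %in% up, 3, ifelse(features %in% down, -3, 0)),
    p_value = 0.5, p_adjusted = 0.5,
    direction = ifelse(features %in% up, "up",
                       ifelse(features %in% down, "down", "unchanged")),
    tested = TRUE
  )
}

test_that("ORA reduces to the hypergeometric tail and handles empty DE sets", {
  universe <- sprintf("g%02d", 1:20)
  # all 5 DE genes inside a 5-member term: upper tail is 1 / choose(20, 5)
  de <- make_de(universe, up = universe[1:5])
  sets <- list(T1 = universe[1:5])
  res <- fisher_ora(de, sets, alternative = "greater")
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$overlap, 5L)

  # empty DE set: every term k = 0, p = 1
  de0 <- make_de(universe)
  res0 <- fisher_ora(de0, list(T1 = universe[1:5], T2 = universe[6:9]))
  expect_equal(res0$p_value, c(1, 1))
  expect_equal(res0$overlap, c(0L, 0L))

  expect_error(fisher_ora(de, sets, universe = universe[1:3]),
               class = "cd8omics_bad_universe")
})

test_that("ORA one-tailed p equals direct hypergeometric summation (N <= 50)", {
  withr::with_seed(21, {
    for (rep in 1:20) {
      N <- sample(10:50, 1)
      universe <- sprintf("u%03d", seq_len(N))
      n <- sample(2:(N - 2), 1)
      K <- sample(2:(N - 2), 1)
      de_set <- sample(universe, n)
      term <- sample(universe, K)
      de <- make_de(universe, up = de_set)
      res <- fisher_ora(de, list(T = term), alternative = "greater")
      k <- length(intersect(term, de_set))
      expected <- if (k == 0) 1 else hyper_upper_tail(k, K, n, N)
      expect_equal(res$p_value, expected, tolerance = 1e-12)
    }
  })
})

test_that("two-sided Fisher ORA matches fisher.test and is conservative under the null", {
  universe <- sprintf("g%02d", 1:40)
  de <- make_de(universe, up = universe[1:6], down = universe[7:10])
  term <- universe[c(1:4, 20:25)]
  res <- fisher_ora(de, list(T = term), alternative = "two.sided")
  ref <- fisher.test(matrix(c(4, 6, 6, 24), nrow = 2))$p.value
  expect_equal(res$p_value, ref, tolerance = 1e-12)

  # permuted-label null: p-values stochastically >= uniform
  withr::with_seed(8, {
    pvals <- replicate(150, {
      de_r <- make_de(universe, up = sample(universe, 8))
      term_r <- sample(universe, 10)
      fisher_ora(de_r, list(T = term_r))$p_value
    })
  })
  expect_gte(mean(pvals > 0.5), 0.45)       # at least uniform-like mass up top
  expect_lte(mean(pvals < 0.05), 0.08)      # no anti-conservative bulge
})

test_that("direction z-scores follow (up - down) / sqrt(up + down)", {
  feats <- sprintf("g%d", 1:20)
  de <- make_de(feats, up = feats[1:9], down = feats[10])
  expect_equal(goplot_zscore(feats[c(1:3, 10)], de), (3 - 1) / sqrt(4))  # = 1
  de2 <- make_de(feats, up = feats[1:2], down = feats[3:4])
  expect_equal(goplot_zscore(feats[1:4], de2), 0)
  expect_equal(goplot_zscore(feats[1:9], de), (9 - 0) / sqrt(9))          # = 3
  expect_error(goplot_zscore(c("g1", "nope"), de),
               class = "cd8omics_missing_direction")
  # fisher_ora carries the same z per term
  res <- fisher_ora(de, list(T = feats[c(1:3, 10)]))
  expect_equal(res$z_score, 1)
})

test_that("feature ranking is descending with deterministic ties", {
  de <- tibble::tibble(feature = c("b", "c", "a"),
                       log2fc = c(1, -0.5, 2), t_statistic = c(2, -1, 3),
                       p_value = 0.1, tested = TRUE)
  rk <- rank_features(de, "t_statistic")
  expect_equal(rk$score, c(3, 2, -1))
  de_tie <- tibble::tibble(feature = c("zeta", "alpha"), log2fc = c(1, 1),
                           t_statistic = c(2, 2), tested = TRUE)
  expect_equal(rank_features(de_tie, "t_statistic")$feature, c("alpha", "zeta"))
  de_bad <- tibble::tibble(feature = "x", log2fc = NaN, t_statistic = NaN,
                           tested = TRUE)
  expect_error(rank_features(de_bad), class = "cd8omics_bad_score")
})

test_that("GSEA running sum matches hand-computable cases", {
  # the single top-ranked gene at weight 0: ES hits 1.0 at position 1
  rk <- tibble::tibble(feature = c("a", "b", "c", "d"), score = c(4, 3, 2, 1))
  g <- gsea(rk, "a", weight = 0, n_permutations = 100, seed = 1)
  expect_equal(g$es, 1.0)
  expect_equal(g$running$running_sum[1], 1.0)
  expect_equal(g$leading_edge, "a")

  # a set at the bottom of the list has negative ES
  g2 <- gsea(rk, c("c", "d"), weight = 0, n_permutations = 100, seed = 1)
  expect_lt(g2$es, 0)

  # 5-gene list, 2-gene set, weight 1: exhaustive running-sum maximum
  rk5 <- tibble::tibble(feature = letters[1:5], score = c(5, 4, 3, -2, -6))
  hit <- rk5$feature %in% c("b", "e")
  g3 <- gsea(rk5, c("b", "e"), weight = 1, n_permutations = 100, seed = 2)
  expect_equal(g3$es, brute_force_es(rk5$score, hit, 1), tolerance = 1e-12)

  expect_error(gsea(rk, rk$feature, seed = 1), class = "cd8omics_full_coverage")
  expect_error(gsea(rk, "zz", seed = 1), class = "cd8omics_empty_overlap")
})

test_that("GSEA ES agrees with an independent implementation", {
  skip_if_not_installed("fgsea")
  withr::with_seed(31, {
    for (i in 1:10) {
      N <- sample(20:60, 1)
      scores <- sort(rnorm(N, 0, 2), decreasing = TRUE)
      feats <- sprintf("f%03d", seq_len(N))
      K <- sample(3:8, 1)
      members <- sample(feats, K)
      g <- gsea(tibble::tibble(feature = feats, score = scores), members,
                weight = 1, n_permutations = 100, seed = i)
      ref <- fgsea::calcGseaStat(stats = setNames(scores, feats),
                                 selectedStats = which(feats %in% members),
                                 gseaParam = 1)
      expect_equal(g$es, ref, tolerance = 1e-6)
    }
  })
})

test_that("GSEA ES properties: rescale invariance at weight 0, reversal negation", {
  withr::with_seed(17, {
    N <- 30
    scores <- sort(rnorm(N), decreasing = TRUE)
    feats <- sprintf("f%02d", seq_len(N))
    members <- sample(feats, 6)
    rk <- tibble::tibble(feature = feats, score = scores)
    g <- gsea(rk, members, weight = 0, n_permutations = 100, seed = 4)
    # monotone rescaling leaves the weight-0 ES unchanged
    rk2 <- tibble::tibble(feature = feats, score = scores * 7 + 100)
    g2 <- gsea(rk2, members, weight = 0, n_permutations = 100, seed = 4)
    expect_equal(g$es, g2$es, tolerance = 1e-12)
    # reversing the ranked list negates the ES (weight 1: continuous scores
    # keep the running-sum extrema off the tie lattice of the unweighted case)
    gw <- gsea(rk, members, weight = 1, n_permutations = 100, seed = 4)
    rk_rev <- rk[rev(seq_len(N)), ]
    g3 <- gsea(rk_rev, members, weight = 1, n_permutations = 100, seed = 4)
    expect_equal(g3$es, -gw$es, tolerance = 1e-12)
  })
})

test_that("permutation NES/p and pooled FDR behave on planted collections", {
  withr::with_seed(12, {
    N <- 200
    feats <- sprintf("f%03d", seq_len(N))
    scores <- sort(rnorm(N), decreasing = TRUE)
    rk <- tibble::tibble(feature = feats, score = scores)
    sets <- c(list(TOP = feats[1:15]),
              lapply(setNames(1:10, sprintf("RAND_%02d", 1:10)),
                     function(i) sample(feats, 15)))
  })
  res <- run_gsea(rk, sets, weight = 1, n_permutations = 300, seed = 9)
  expect_equal(sign(res$nes), sign(res$es))
  expect_true(all(res$nominal_p >= 0 & res$nominal_p <= 1))
  expect_true(all(res$fdr_q >= 0 & res$fdr_q <= 1))
  top <- res[res$term == "TOP", ]
  expect_gt(top$es, 0.8)            # the planted set sits at the very top
  expect_equal(top$nominal_p, 0)    # no permutation reaches it
  expect_lt(top$fdr_q, 0.05)
  expect_true(all(unlist(top$leading_edge) %in% sprintf("f%03d", 1:15)))

  low <- gsea(rk, sets$TOP, n_permutations = 50, seed = 2)
  expect_true(low$metadata$low_permutations)
})

test_that("GSEA nominal p is calibrated under a random-rank null", {
  withr::with_seed(41, {
    N <- 80
    feats <- sprintf("f%02d", seq_len(N))
    hits <- 0
    n_rep <- 60
    for (i in 1:n_rep) {
      scores <- sort(rnorm(N), decreasing = TRUE)
      rk <- tibble::tibble(feature = feats, score = scores)
      members <- sample(feats, 8)
      g <- gsea(rk, members, weight = 1, n_permutations = 200, seed = 1000 + i)
      if (!is.na(g$nominal_p) && g$nominal_p < 0.05) hits <- hits + 1
    }
  })
  # binomial(60, 0.05): mean 3, sd 1.7 — allow 4 sd
  expect_lte(hits, 10)
})
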