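test_that("exact Mann-Whitney matches enumeration, including ties", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)

  expect_equal(mann_whitney_u(c(5, 5), c(5, 5))$p_value, 1)

  set.seed(11)
  for (n in c(2, 4, 5)) {
    for (m in c(3, 5)) {
      x <- sample(1:4, n, replace = TRUE)   # ties likely
      y <- sample(1:4, m, replace = TRUE)
      got <- mann_whitney_u(x, y)
      orc <- mwu_enum_oracle(x, y)
      expect_equal(got$statistic, orc$u)
      expect_equal(got$p_value, orc$p)
    }
  }
  # tie-free exact case agrees with the base R exact test
  x <- c(1.2, 3.4, 2.2, 9.1); y <- c(5.5, 0.3, 7.7, 4.4, 6.6)
  expect_equal(mann_whitney_u(x, y)$p_value,
               stats::wilcox.test(x, y, exact = TRUE)$p.value)
})

test_that("approximate Mann-Whitney agrees with base R and holds its size", {
  set.seed(21)
  x <- rnorm(60); y <- rnorm(55, 0.4)
  got <- mann_whitney_u(x, y)
  ref <- stats::wilcox.test(x, y, correct = TRUE, exact = FALSE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")

  # type-I error at alpha = 0.05 for n = m = 50 null draws
  set.seed(31)
  rej <- mean(replicate(1000, {
    mann_whitney_u(rnorm(50), rnorm(50))$p_value < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)

  # directional alternatives are consistent
  expect_lt(mann_whitney_u(x + 2, y, alternative = "greater")$p_value, 0.01)
  expect_gt(mann_whitney_u(x + 2, y, alternative = "less")$p_value, 0.9)
})

test_that("Kruskal-Wallis reproduces the rank H formula and base R", {
  groups <- list(c(1, 2), c(3, 4), c(5, 6))
  # hand computation: ranks 1..6, no ties
  rbar <- c(1.5, 3.5, 5.5); N <- 6
  h_hand <- 12 / (N * (N + 1)) * sum(2 * (rbar - 3.5)^2)
  got <- kruskal_wallis(groups)
  expect_equal(got$statistic, h_hand)
  expect_equal(got$p_value,
               stats::kruskal.test(unlist(groups),
                                   rep(1:3, each = 2))$p.value)

  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2, 2)))$statistic, 0)
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2, 2)))$p_value, 1)
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")

  set.seed(41)
  for (i in 1:5) {
    g <- list(sample(1:6, 8, TRUE), sample(1:6, 5, TRUE), sample(1:6, 7, TRUE))
    ref <- stats::kruskal.test(unlist(g), rep(1:3, lengths(g)))
    got <- kruskal_wallis(g)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("two-group Kruskal-Wallis tracks the Mann-Whitney decision", {
  set.seed(51)
  agree <- mean(replicate(500, {
    x <- rnorm(30); y <- rnorm(30, sample(c(0, 0.6), 1))
    (kruskal_wallis(list(x, y))$p_value < 0.05) ==
      (mann_whitney_u(x, y, correct = FALSE)$p_value < 0.05)
  }))
  expect_gte(agree, 0.95)
})

test_that("Conover post hoc orders pairs by effect and caps ties at 1", {
  g <- list(a = c(1.1, 1.9, 1.4, 2.2), b = c(1.3, 2.1, 1.7, 1.2),
            c = c(8.5, 9.1, 8.8, 9.4))
  pm <- conover_posthoc(g, p_adjust = "none")
  expect_true(isSymmetric(pm))
  expect_lt(pm["a", "c"], pm["a", "b"])
  expect_lt(pm["b", "c"], pm["a", "b"])

  same <- list(rep(3, 4), rep(3, 5), rep(3, 4))
  expect_true(all(conover_posthoc(same) == 1))

  # Bonferroni multiplies by the number of pairs
  pm_raw <- conover_posthoc(g, p_adjust = "none")
  pm_bon <- conover_posthoc(g, p_adjust = "bonferroni")
  expect_equal(pm_bon["a", "b"], min(1, pm_raw["a", "b"] * 3))
})

test_that("two-group Conover p approximates a label-permutation test", {
  set.seed(61)
  x <- rnorm(8); y <- rnorm(8, 1.1)
  p_conover <- conover_posthoc(list(x, y), p_adjust = "none")[1, 2]
  r <- rank(c(x, y))
  obs <- abs(mean(r[1:8]) - mean(r[9:16]))
  perm <- replicate(1e4, {
    i <- sample(16, 8)
    abs(mean(r[i]) - mean(r[-i]))
  })
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(p_conover - p_perm) / p_perm, 0.25)
})

test_that("Benjamini-Hochberg follows the step-up definition", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(71)
  for (i in 1:5) {
    p <- runif(20)
    expect_equal(benjamini_hochberg(p), bh_stepup_oracle(p))
    # order invariance
    perm <- sample(20)
    expect_equal(benjamini_hochberg(p[perm]), benjamini_hochberg(p)[perm])
  }
})

test_that("hypergeometric over-representation matches combinatorial sums", {
  expect_equal(hypergeom_overrep(5, 5, 5, 10), 1 / 252)
  expect_equal(hypergeom_overrep(0, 5, 10, 100), 1)
  expect_equal(hypergeom_overrep(3, 5, 10, 100),
               hyper_sum_oracle(3, 5, 10, 100), tolerance = 1e-12)

  # monotone decreasing in overlap
  ps <- vapply(0:5, hypergeom_overrep, numeric(1),
               set_size = 8, query_size = 12, background = 60)
  expect_true(all(diff(ps) < 0))

  expect_error(hypergeom_overrep(6, 5, 10, 100), "overlap exceeds")
  expect_error(hypergeom_overrep(3, 5, 200, 100), "background")
})

test_that("gene ranking recovers planted markers and matches exact MWU", {
  # a gene expressed only in cluster A ranks first for A
  set.seed(81)
  vals <- matrix(rlnorm(200 * 30, 0, 0.1), 200, 30,
                 dimnames = list(NULL, sprintf("g%02d", 1:30)))
  labs <- rep(c("A", "B"), each = 100)
  vals[labs == "B", "g01"] <- 0
  ranked <- wilcoxon_rank_genes(vals, labs)
  expect_equal(ranked$gene[ranked$group == "A"][1], "g01")
  expect_true(all(ranked$adj_p >= ranked$p - 1e-15))

  # planted-marker recovery on the simulated fixture
  sim <- make_count_matrix(small_spec(seed = 3))
  flt <- filter_cells_genes(sim$cm)
  nm <- normalize_log(flt$cm)
  truth <- sim$truth$cell_type[match(flt$cm$cell_meta$cell_id,
                                     sim$cm$cell_meta$cell_id)]
  ranked <- wilcoxon_rank_genes(nm$values, truth)
  for (ty in names(sim$truth$marker_sets)) {
    top50 <- ranked$gene[ranked$group == ty][1:50]
    hits <- sum(sim$truth$marker_sets[[ty]] %in% top50)
    expect_gte(hits, 18)
  }

  # tiny clusters with exact = TRUE reproduce the exact MWU p
  tiny <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1,
                 dimnames = list(NULL, "gene1"))
  tiny <- cbind(tiny, gene2 = c(5, 1, 8, 2, 9, 3))
  lab <- rep(c("lo", "hi"), each = 3)
  r <- wilcoxon_rank_genes(tiny, lab, exact = TRUE)
  for (g in c("gene1", "gene2")) {
    row <- r[r$group == "hi" & r$gene == g, ]
    expect_equal(row$p, mann_whitney_u(tiny[4:6, g], tiny[1:3, g])$p_value)
  }

  # labels with < 2 cells are skipped with a warning
  expect_warning(
    wilcoxon_rank_genes(vals, c("solo", labs[-1])),
    "skipping")
})

test_that("ranked gene tables round-trip through TSV", {
  set.seed(91)
  vals <- matrix(rnorm(40 * 6, 5), 40, 6,
                 dimnames = list(NULL, sprintf("g%d", 1:6)))
  ranked <- wilcoxon_rank_genes(vals, rep(c("A", "B"), 20))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ranked_genes(ranked, path)
  back <- read_ranked_genes(path)
  expect_equal(back$gene, ranked$gene)
  expect_equal(back$statistic, ranked$statistic, tolerance = 1e-12)
})
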