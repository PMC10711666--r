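make_toy_cm <- function(counts, ...) {
  colnames(counts) <- colnames(counts) %||% sprintf("G%02d", seq_len(ncol(counts)))
  count_matrix(counts, ...)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("QC metrics equal a dense per-cell recomputation", {
  set.seed(1)
  counts <- matrix(rpois(50 * 20, 2), 50, 20)
  colnames(counts) <- c(sprintf("MT-%02d", 1:3), sprintf("RPS%02d", 1:3),
                        sprintf("GENE%02d", 1:14))
  counts[7, ] <- 0                      # an empty cell
  cm <- count_matrix(counts)
  qc <- compute_qc_metrics(cm)
  for (i in c(1, 7, 23, 50)) {
    tot <- sum(counts[i, ])
    expect_equal(qc$total_counts[i], tot)
    expect_equal(qc$n_genes[i], sum(counts[i, ] > 0))
    expect_equal(qc$mito_frac[i],
                 if (tot > 0) sum(counts[i, 1:3]) / tot else 0)
    expect_equal(qc$ribo_frac[i],
                 if (tot > 0) sum(counts[i, 4:6]) / tot else 0)
  }
  expect_equal(unlist(qc[7, c("n_genes", "total_counts", "mito_frac",
                              "ribo_frac")], use.names = FALSE),
               c(0, 0, 0, 0))
  # a cell whose counts sit only on mito genes
  counts2 <- counts; counts2[3, ] <- 0; counts2[3, 1:3] <- 5
  expect_equal(compute_qc_metrics(count_matrix(counts2))$mito_frac[3], 1)
})

test_that("cell filters precede the gene filter and the report reconciles", {
  sim <- make_count_matrix(small_spec(seed = 2))
  flt <- filter_cells_genes(sim$cm)
  rep <- flt$report
  expect_equal(rep$cells_after, nrow(flt$cm$counts))
  expect_equal(rep$genes_after, ncol(flt$cm$counts))
  expect_equal(sum(unlist(rep$per_sample_after)), rep$cells_after)

  # exhaustive post-check: every surviving cell satisfies every threshold
  cfg <- qc_config()
  qc <- compute_qc_metrics(flt$cm)
  expect_true(all(flt$cm$cell_meta$doublet_score < cfg$max_doublet_score))
  expect_true(all(qc$n_genes >= cfg$min_genes))
  expect_true(all(qc$mito_frac <= cfg$max_mito_frac))
  expect_true(all(qc$ribo_frac <= cfg$max_ribo_frac))
  expect_true(all(qc$total_counts >= cfg$min_counts))
  expect_true(all(qc$total_counts <= cfg$max_counts))
  expect_true(all(Matrix::colSums(flt$cm$counts > 0) >= cfg$min_cells_per_gene))

  # and every removed cell violates at least one cell-level threshold
  qc0 <- compute_qc_metrics(sim$cm)
  removed <- !(sim$cm$cell_meta$cell_id %in% flt$cm$cell_meta$cell_id)
  viol <- sim$cm$cell_meta$doublet_score >= cfg$max_doublet_score |
    qc0$n_genes < cfg$min_genes | qc0$mito_frac > cfg$max_mito_frac |
    qc0$ribo_frac > cfg$max_ribo_frac | qc0$total_counts < cfg$min_counts |
    qc0$total_counts > cfg$max_counts
  expect_identical(removed, unname(viol))

  # idempotence
  again <- filter_cells_genes(flt$cm)
  expect_equal(dim(again$cm$counts), dim(flt$cm$counts))

  # extreme thresholds are an identity filter
  loose <- qc_config(min_genes = 0, max_mito_frac = 1, max_ribo_frac = 1,
                     min_counts = 0, max_counts = Inf, min_cells_per_gene = 0,
                     max_doublet_score = Inf)
  ident <- filter_cells_genes(sim$cm, loose)
  expect_equal(dim(ident$cm$counts), dim(sim$cm$counts))

  # impossible thresholds raise with the report attached
  err <- tryCatch(
    filter_cells_genes(sim$cm, qc_config(min_genes = 10^6)),
    error = function(e) e)
  expect_s3_class(err, "lb_qc_error")
  expect_equal(err$report$cells_after, 0)
})

test_that("gene filter boundary sits exactly at 10 expressing cells", {
  set.seed(3)
  counts <- matrix(rpois(40 * 30, 5) + 1, 40, 30)  # all cells healthy
  colnames(counts) <- sprintf("G%02d", 1:30)
  counts[, 1] <- 0; counts[1:9, 1] <- 3     # expressed in 9 cells
  counts[, 2] <- 0; counts[1:10, 2] <- 3    # expressed in 10 cells
  cm <- count_matrix(counts)
  cfg <- qc_config(min_genes = 0, min_counts = 0)
  flt <- filter_cells_genes(cm, cfg)
  expect_false("G01" %in% flt$cm$gene_meta$symbol)
  expect_true("G02" %in% flt$cm$gene_meta$symbol)
})

test_that("normalization excludes top-decile genes and is scale invariant", {
  # uniform cells: size factors 1, values = log1p(counts)
  counts <- matrix(rep(c(5, 3, 2, 8, 1, 4, 7, 2, 3, 6), 4), 4, 10,
                   byrow = TRUE)
  colnames(counts) <- sprintf("G%02d", 1:10)
  nm <- normalize_log(count_matrix(counts))
  expect_equal(nm$size_factors, rep(1, 4))
  expect_equal(unname(nm$values), unname(log1p(counts)))

  # dominant gene: excluded from size factors, still normalized and logged
  counts2 <- matrix(c(100, 1, 2, 3,
                      200, 2, 4, 6,
                      100, 2, 1, 3), 3, 4, byrow = TRUE)
  colnames(counts2) <- c("BIG", "A", "B", "C")
  # hand computation: floor(0.1*4) = 0 genes excluded -> use 10 genes
  counts3 <- cbind(counts2, matrix(1, 3, 6,
                                   dimnames = list(NULL, sprintf("P%d", 1:6))))
  nm3 <- normalize_log(count_matrix(counts3))
  expect_true(nm3$highly_expressed[1])            # BIG flagged
  incl <- rowSums(counts3[, -1])
  sf_hand <- incl / stats::median(incl)
  expect_equal(nm3$size_factors, sf_hand)
  expect_equal(unname(nm3$values[, "BIG"]), log1p(counts3[, "BIG"] / sf_hand))

  # doubling one cell's counts leaves its normalized values unchanged
  # (constructed so the median included sum and the gene ranking cannot
  # move: ten identical cells pin the median, and the test cell shares
  # their expression pattern up to a scalar)
  pat <- c(5, 3, 2, 8, 1, 4, 7, 2, 3, 6, 9, 2, 4, 1, 5, 3, 2, 6, 4, 8)
  counts4 <- rbind(matrix(rep(pat, 10), 10, byrow = TRUE), 2 * pat)
  colnames(counts4) <- sprintf("G%02d", seq_along(pat))
  nmA <- normalize_log(count_matrix(counts4))
  counts4b <- counts4
  counts4b[11, ] <- counts4b[11, ] * 2
  nmB <- normalize_log(count_matrix(counts4b))
  expect_equal(nmB$values[11, ], nmA$values[11, ], tolerance = 1e-12)
})

test_that("HVG selection flags planted variable genes deterministically", {
  set.seed(5)
  vals <- matrix(rlnorm(300 * 50, 0, 0.05), 300, 50,
                 dimnames = list(NULL, sprintf("G%02d", 1:50)))
  vals[, "G07"] <- c(rep(0.05, 150), rep(4, 150))   # bimodal gene
  nm <- normalized_matrix(log1p(vals))
  sel <- select_hvg(nm, n_top = 5)
  expect_true(sel$hvg_mask[7])
  expect_equal(sum(sel$hvg_mask), 5)
  # determinism
  sel2 <- select_hvg(nm, n_top = 5)
  expect_identical(sel$hvg_mask, sel2$hvg_mask)
  # n_top >= n_genes flags everything
  expect_true(all(select_hvg(nm, n_top = 50)$hvg_mask))
  expect_warning(select_hvg(nm, n_top = 60), "exceeds")
})

test_that("scaling centers, clips at the maximum, and zeroes flat genes", {
  set.seed(6)
  vals <- cbind(flat = rep(2, 400), normal = rnorm(400),
                outlier = c(rnorm(399), 0))
  vals <- vals - min(vals) + 0.1   # keep the normalized-value contract (>= 0)
  vals[400, "outlier"] <- mean(vals[1:399, "outlier"]) +
    8 * stats::sd(vals[1:399, "outlier"])
  nm <- scale_clip(normalized_matrix(vals))
  expect_true(all(nm$scaled_values[, "flat"] == 0))
  expect_equal(mean(nm$scaled_values[, "normal"]), 0, tolerance = 1e-12)
  expect_equal(stats::sd(nm$scaled_values[, "normal"]), 1, tolerance = 1e-12)
  expect_equal(max(nm$scaled_values[, "outlier"]), 5)
})

test_that("cluster robustness metrics separate good and random labelings", {
  set.seed(7)
  blobs <- rbind(matrix(rnorm(100 * 2, 0, 0.2), ncol = 2),
                 matrix(rnorm(100 * 2, 5, 0.2), ncol = 2))
  good <- rep(c(1, 2), each = 100)
  bad <- sample(good)
  res <- cluster_robustness(blobs, list(good = good, bad = bad,
                                        same = good))
  m <- res$metrics
  expect_gt(m$silhouette[m$resolution == "good"], 0.8)
  expect_lt(abs(m$silhouette[m$resolution == "bad"]), 0.1)
  expect_equal(m[m$resolution == "good", -1], m[m$resolution == "same", -1],
               ignore_attr = TRUE)
  expect_equal(res$selected, "good")
  expect_lt(m$davies_bouldin[m$resolution == "good"],
            m$davies_bouldin[m$resolution == "bad"])
  expect_warning(cluster_robustness(blobs, list(one = rep(1, 200),
                                                good = good)),
                 "single cluster")
})
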