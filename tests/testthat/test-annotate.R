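test_that("planted cell types are recovered and adj_p matches the oracle", {
  sim <- make_count_matrix(small_spec(seed = 10))
  flt <- filter_cells_genes(sim$cm)
  nm <- normalize_log(flt$cm)
  truth <- sim$truth$cell_type[match(flt$cm$cell_meta$cell_id,
                                     sim$cm$cell_meta$cell_id)]
  ranked <- wilcoxon_rank_genes(nm$values, truth)
  db <- marker_db(sim$truth$marker_sets)
  dec <- annotate_clusters(ranked, db, background = ncol(nm$values))
  expect_equal(dec$label, dec$cluster_id)       # planted names match
  expect_true(all(dec$significant))
  expect_true(all(dec$matched_genes == lengths(sim$truth$marker_sets)))

  # oracle: recompute one cluster's adj_p with the explicit hypergeometric
  # sum and the step-up definition
  cl <- dec$cluster_id[1]
  top <- ranked$gene[ranked$group == cl][1:200]
  universe <- unique(ranked$gene)
  ps <- vapply(names(db$entries), function(ct) {
    set <- intersect(db$entries[[ct]], universe)
    ov <- length(intersect(top, set))
    if (ov == 0) return(1)
    hyper_sum_oracle(ov, length(set), length(top), ncol(nm$values))
  }, numeric(1))
  adj <- bh_stepup_oracle(ps)
  expect_equal(dec$adj_p[dec$cluster_id == cl],
               adj[names(ps) == dec$label[dec$cluster_id == cl]],
               tolerance = 1e-9)
})

test_that("the stem-cell gate blocks unexpressed pluripotency labels", {
  # cluster X's top genes overlap the ESC marker set, but no gate gene is
  # expressed in X: the ESC label must be skipped for the next candidate
  genes <- c(sprintf("E%02d", 1:10), sprintf("D%02d", 1:10),
             c("SOX2", "NANOG", "POU5F1", "KLF1"), sprintf("F%02d", 1:26))
  ranked <- list(X = c(sprintf("E%02d", 1:10), sprintf("D%02d", 1:6)))
  db <- marker_db(list(
    "Embryonic stem cells" = sprintf("E%02d", 1:10),
    "Ductal cells" = c(sprintf("E%02d", 1:2), sprintf("D%02d", 1:6))))
  expr <- matrix(1, 20, length(genes), dimnames = list(NULL, genes))
  expr[, c("SOX2", "NANOG", "POU5F1", "KLF1")] <- 0
  nm <- normalized_matrix(expr)
  labs <- rep("X", 20)

  gated <- annotate_clusters(ranked, db, background = length(genes),
                             universe = genes, top_n = 16,
                             expression = nm, cell_labels = labs)
  expect_equal(gated$label, "Ductal cells")
  expect_equal(gated$gate_failed_labels, "Embryonic stem cells")

  # with a gate gene expressed, the ESC label wins on overlap count
  expr2 <- expr; expr2[3, "NANOG"] <- 2
  open <- annotate_clusters(ranked, db, background = length(genes),
                            universe = genes, top_n = 16,
                            expression = normalized_matrix(expr2),
                            cell_labels = labs)
  expect_equal(open$label, "Embryonic stem cells")
})

test_that("disjoint databases fall back with adj_p 1", {
  ranked <- list(c1 = sprintf("A%02d", 1:30))
  db <- marker_db(list(OnlyType = sprintf("Z%02d", 1:10)))
  universe <- c(sprintf("A%02d", 1:30), sprintf("Z%02d", 1:10))
  dec <- annotate_clusters(ranked, db, background = 40, universe = universe,
                           top_n = 30)
  expect_true(dec$fallback_used)
  expect_false(dec$significant)
  expect_equal(dec$adj_p, 1)
  expect_equal(dec$matched_genes, 0L)
})

test_that("marker sets derive from pairwise fold changes with the HB1 rule", {
  toy <- data.frame(
    gene = c("gA", "gB", "gC", "gD"),
    stage = c("HB2", "HB2", "FH1", "FH1"),
    precursor = c("HB1", "HB1", "HB2", "HB2"),
    lfc = c(1, -1, 2, 0.5), stringsAsFactors = FALSE)
  db <- derive_marker_sets_from_pairwise_dge(toy)
  expect_equal(db$entries$HB2, "gA")
  expect_equal(db$entries$HB1, "gB")
  expect_equal(db$entries$FH1, c("gC", "gD"))
  expect_equal(db$source, "reference_dge")

  # all-zero fold changes leave nothing
  zero <- toy; zero$lfc <- 0
  expect_error(suppressWarnings(derive_marker_sets_from_pairwise_dge(zero)),
               "no marker sets")

  # truncation keeps exactly top_n genes ranked by lfc
  big <- data.frame(gene = sprintf("g%03d", 1:150), stage = "Zone1",
                    precursor = "Zone0", lfc = seq(150, 1),
                    stringsAsFactors = FALSE)
  db100 <- derive_marker_sets_from_pairwise_dge(big, top_n = 100,
                                                negative_lfc_stage = NULL)
  expect_length(db100$entries$Zone1, 100)
  expect_equal(db100$entries$Zone1[1], "g001")
})

test_that("clusters must represent every control replicate", {
  meta <- data.frame(
    condition = rep(c("control", "treated"), c(160, 40)),
    replicate = c(rep(1:8, each = 20), rep(1, 40)))
  labels <- rep("A", 200)
  # cluster B: 5 cells from each of control replicates 1-7 (absent from 8),
  # plus 3 treated cells; cluster A keeps cells in every control replicate
  b_cells <- unlist(lapply(1:7, function(r)
    which(meta$condition == "control" & meta$replicate == r)[1:5]))
  labels[c(b_cells, 188:190)] <- "B"
  res <- enforce_control_representation(labels, meta)
  expect_equal(res$kept, "A")
  expect_equal(res$excluded, "B")
  expect_equal(res$excluded_cells, 38)

  # all clusters everywhere: nothing excluded
  all_ok <- rep(c("A", "B"), each = 100)
  meta2 <- data.frame(condition = "control", replicate = rep(1:4, 50))
  res2 <- enforce_control_representation(all_ok, meta2)
  expect_equal(sort(res2$kept), c("A", "B"))
  expect_equal(res2$excluded_cells, 0)

  # engineered 37-cell orphan cluster
  labels3 <- rep("A", 200)
  labels3[meta$condition == "treated"][1:37] <- "orphan"
  expect_equal(enforce_control_representation(labels3, meta)$excluded_cells, 37)

  expect_error(enforce_control_representation(labels, data.frame(
    condition = "treated", replicate = 1)), "no control replicates")
})

test_that("non-significant clusters merge into the nearest annotated one", {
  decisions <- data.frame(
    cluster_id = c("c1", "c2", "c3"),
    label = c("Ductal", "Hepatocyte", "Stromal"),
    adj_p = c(1e-6, 1e-6, 0.2),
    matched_genes = c(10L, 10L, 2L),
    significant = c(TRUE, TRUE, FALSE),
    fallback_used = c(FALSE, FALSE, TRUE),
    gate_failed_labels = "", stringsAsFactors = FALSE)
  centroids <- rbind(c1 = c(0, 0), c2 = c(10, 10), c3 = c(1, 1))
  merged <- merge_nonsignificant_cluster(decisions, centroids)
  expect_equal(merged$label[3], "Ductal")
  expect_equal(merged$merged_into[3], "c1")

  # all significant: identity
  all_sig <- decisions; all_sig$significant <- TRUE
  expect_equal(merge_nonsignificant_cluster(all_sig, centroids)$label,
               decisions$label)

  # equidistant neighbors resolve to the lower cluster index
  cent_tie <- rbind(c1 = c(0, 0), c2 = c(2, 0), c3 = c(1, 0))
  tie <- merge_nonsignificant_cluster(decisions, cent_tie)
  expect_equal(tie$merged_into[3], "c1")

  none <- decisions; none$significant <- FALSE
  expect_warning(merge_nonsignificant_cluster(none, centroids),
                 "nothing to merge")
})

test_that("zonation scores look up the reference map exactly", {
  expect_equal(zonation_score("Pericentral-C3"), 5L)
  expect_equal(zonation_score("Periportal-C5"), 0L)
  cells <- c("Interzonal-C15", "Periportal-C14", "Pericentral-C1")
  expect_equal(zonation_score(cells), c(3L, 1L, 4L))

  # permuting map insertion order changes nothing
  zmap <- zonation_map_default()
  shuffled <- zmap[c(4, 2, 6, 1, 3, 5)]
  expect_equal(zonation_score(cells, shuffled), zonation_score(cells))

  # inverse lookup is the identity over the six reference labels
  inv <- stats::setNames(names(zmap), zmap)
  for (lab in names(zmap))
    expect_equal(inv[as.character(zonation_score(lab))], lab,
                 ignore_attr = TRUE)

  expect_error(zonation_score("Midlobular-C9"), "unknown zone")
  expect_error(zonation_score("Periportal-C5", c(A = 1L, B = 2L)),
               "consecutive")
})

test_that("early-cell selection maximizes under the expression gate", {
  vals <- cbind(AFP = c(5, 9, 7, 1), CEBPA = c(1, 0, 2, 3))
  nm <- normalized_matrix(vals,
                          cell_meta = data.frame(cell_id = paste0("c", 1:4)))
  # cell 2 has the global AFP maximum but no CEBPA: cell 3 wins
  sel <- select_early_cell(nm, "AFP", "CEBPA")
  expect_equal(unname(sel), 3L)
  expect_equal(names(sel), "c3")

  none <- normalized_matrix(cbind(AFP = 1:4, CEBPA = rep(0, 4)))
  expect_error(select_early_cell(none, "AFP", "CEBPA"), "no cell expresses")
  expect_error(select_early_cell(nm, "MISSING", "CEBPA"), "not in matrix")
})
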