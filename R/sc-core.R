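#' Cell-by-gene count matrix container
#'
#' Bundles an integer cells x genes count matrix with per-cell metadata
#' (sample, condition, replicate, doublet score) and per-gene metadata
#' (symbol, mitochondrial/ribosomal flags). Mitochondrial genes are
#' recognized by the "MT-" symbol prefix and ribosomal genes by "RPS"/"RPL"
#' (mitochondrial ribosomal "MRP*" symbols are deliberately not counted as
#' ribosomal); both rules are overridable by supplying `gene_meta`.
#'
#' @param counts Non-negative integer matrix (or `Matrix` sparse matrix),
#'   cells in rows, genes in columns, gene symbols as column names.
#' @param cell_meta Data.frame with one row per cell; columns `sample_id`,
#'   `condition`, `replicate`, `doublet_score` are expected by downstream
#'   stages (missing ones are filled with defaults).
#' @param gene_meta Optional data.frame with columns `symbol`, `is_mito`,
#'   `is_ribo`; derived from symbols when omitted.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, cell_meta = NULL, gene_meta = NULL) {
  if (is.null(colnames(counts))) stop("counts must carry gene symbols as column names")
  if (any(counts < 0)) stop("counts must be non-negative")
  n_cells <- nrow(counts); n_genes <- ncol(counts)
  if (is.null(cell_meta)) cell_meta <- data.frame(row.names = seq_len(n_cells))
  if (nrow(cell_meta) != n_cells) stop("cell_meta rows must match cells")
  for (col in c("sample_id", "condition", "replicate")) {
    if (is.null(cell_meta[[col]])) cell_meta[[col]] <- "sample1"
  }
  if (is.null(cell_meta$doublet_score)) cell_meta$doublet_score <- 0
  if (is.null(cell_meta$cell_id)) {
    cell_meta$cell_id <- if (!is.null(rownames(counts))) rownames(counts) else
      sprintf("cell%06d", seq_len(n_cells))
  }
  if (is.null(gene_meta)) {
    sym <- colnames(counts)
    gene_meta <- data.frame(symbol = sym,
                            is_mito = grepl("^MT-", sym),
                            is_ribo = grepl("^RP[SL]", sym),
                            stringsAsFactors = FALSE)
  }
  if (nrow(gene_meta) != n_genes) stop("gene_meta rows must match genes")
  structure(list(counts = counts, cell_meta = cell_meta, gene_meta = gene_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d cells x %d genes (%d mito, %d ribo genes)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$gene_meta$is_mito), sum(x$gene_meta$is_ribo)))
  cat("samples:", paste(unique(x$cell_meta$sample_id), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' QC thresholds for cell and gene filtering
#'
#' Defaults follow the organoid scRNA-seq recipe: at least 500 detected
#' genes per cell, mitochondrial fraction at most 20%, ribosomal fraction at
#' most 40%, between 500 and 30,000 total counts, doublet score below 0.5,
#' and genes kept when detected in at least 10 surviving cells.
#'
#' @param min_genes,max_mito_frac,max_ribo_frac,min_counts,max_counts
#'   Per-cell thresholds.
#' @param min_cells_per_gene Gene detection threshold.
#' @param max_doublet_score Cells at or above this score are removed.
#' @return A `qc_config` list.
#' @export
qc_config <- function(min_genes = 500, max_mito_frac = 0.20,
                      max_ribo_frac = 0.40, min_counts = 500,
                      max_counts = 30000, min_cells_per_gene = 10,
                      max_doublet_score = 0.5) {
  stopifnot(min_counts <= max_counts)
  structure(list(min_genes = min_genes, max_mito_frac = max_mito_frac,
                 max_ribo_frac = max_ribo_frac, min_counts = min_counts,
                 max_counts = max_counts, min_cells_per_gene = min_cells_per_gene,
                 max_doublet_score = max_doublet_score),
            class = "qc_config")
}

#' Per-cell QC metrics
#'
#' @param cm A [count_matrix()].
#' @return Data.frame with `n_genes`, `total_counts`, `mito_frac`,
#'   `ribo_frac` per cell; cells with zero counts get zero fractions.
#' @export
compute_qc_metrics <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  counts <- cm$counts
  total <- Matrix::rowSums(counts)
  n_genes <- Matrix::rowSums(counts > 0)
  mito <- Matrix::rowSums(counts[, cm$gene_meta$is_mito, drop = FALSE])
  ribo <- Matrix::rowSums(counts[, cm$gene_meta$is_ribo, drop = FALSE])
  data.frame(
    cell_id = cm$cell_meta$cell_id,
    n_genes = as.integer(n_genes),
    total_counts = as.numeric(total),
    mito_frac = ifelse(total > 0, mito / total, 0),
    ribo_frac = ifelse(total > 0, ribo / total, 0),
    stringsAsFactors = FALSE
  )
}

#' Filter cells then genes by QC thresholds
#'
#' Cell filters are applied first (doublet score, detected genes,
#' mitochondrial and ribosomal fractions, total-count window), then genes
#' are kept only when detected in at least `min_cells_per_gene` of the
#' surviving cells. The report records per-sample cell counts before/after,
#' gene counts before/after, and how many cells failed each criterion
#' (a cell can be counted under several reasons).
#'
#' @param cm A [count_matrix()].
#' @param cfg A [qc_config()].
#' @return List with elements `cm` (filtered [count_matrix()]) and `report`
#'   (class `qc_report`).
#' @export
filter_cells_genes <- function(cm, cfg = qc_config()) {
  stopifnot(inherits(cm, "count_matrix"), inherits(cfg, "qc_config"))
  qc <- compute_qc_metrics(cm)
  fail <- list(
    doublet    = cm$cell_meta$doublet_score >= cfg$max_doublet_score,
    low_genes  = qc$n_genes < cfg$min_genes,
    high_mito  = qc$mito_frac > cfg$max_mito_frac,
    high_ribo  = qc$ribo_frac > cfg$max_ribo_frac,
    low_counts = qc$total_counts < cfg$min_counts,
    high_counts = qc$total_counts > cfg$max_counts
  )
  keep_cell <- !Reduce(`|`, fail)
  reason_counts <- vapply(fail, sum, integer(1))

  per_sample_before <- table(cm$cell_meta$sample_id)
  if (!any(keep_cell)) {
    report <- structure(list(
      cells_before = nrow(cm$counts), cells_after = 0L,
      genes_before = ncol(cm$counts), genes_after = 0L,
      per_sample_before = as.list(per_sample_before),
      per_sample_after = as.list(per_sample_before * 0L),
      reason_counts = as.list(reason_counts)), class = "qc_report")
    stop(structure(class = c("lb_qc_error", "error", "condition"),
                   list(message = "all cells removed by QC", call = sys.call(),
                        report = report)))
  }
  sub <- cm$counts[keep_cell, , drop = FALSE]
  keep_gene <- Matrix::colSums(sub > 0) >= cfg$min_cells_per_gene
  out <- count_matrix(sub[, keep_gene, drop = FALSE],
                      cm$cell_meta[keep_cell, , drop = FALSE],
                      cm$gene_meta[keep_gene, , drop = FALSE])
  per_sample_after <- table(factor(out$cell_meta$sample_id,
                                   levels = names(per_sample_before)))
  report <- structure(list(
    cells_before = nrow(cm$counts), cells_after = nrow(out$counts),
    genes_before = ncol(cm$counts), genes_after = ncol(out$counts),
    per_sample_before = as.list(per_sample_before),
    per_sample_after = as.list(per_sample_after),
    reason_counts = as.list(reason_counts)), class = "qc_report")
  list(cm = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: cells %d -> %d, genes %d -> %d\n",
              x$cells_before, x$cells_after, x$genes_before, x$genes_after))
  rc <- unlist(x$reason_counts)
  cat("cells failing each criterion:\n")
  for (nm in names(rc)) cat(sprintf("  %-11s %d\n", nm, rc[[nm]]))
  invisible(x)
}

#' Total-count normalization and natural-log transform
#'
#' Genes are ranked by total counts over the joint dataset and the top
#' `highly_expressed_frac` share is excluded from each cell's size-factor
#' sum; every cell is then scaled so that its included-gene sum equals the
#' median of included-gene sums, and log(x + 1) (natural logarithm) is
#' applied to all genes.
#'
#' @param cm A filtered [count_matrix()].
#' @param highly_expressed_frac Fraction of genes (by total counts) treated
#'   as highly expressed and excluded from size factors (default 10%).
#' @return A `normalized_matrix` with `values` (cells x genes dense matrix),
#'   `size_factors`, `highly_expressed` mask, and the carried-over cell and
#'   gene metadata.
#' @export
normalize_log <- function(cm, highly_expressed_frac = 0.10) {
  stopifnot(inherits(cm, "count_matrix"))
  counts <- as.matrix(cm$counts)
  gene_tot <- colSums(counts)
  n_excl <- floor(highly_expressed_frac * ncol(counts))
  he <- rep(FALSE, ncol(counts))
  if (n_excl > 0) {
    ord <- order(-gene_tot, seq_along(gene_tot))
    he[ord[seq_len(n_excl)]] <- TRUE
  }
  incl_sum <- rowSums(counts[, !he, drop = FALSE])
  target <- stats::median(incl_sum)
  if (target <= 0) stop("median included-gene sum is zero; cannot normalize")
  sf <- incl_sum / target
  sf[sf == 0] <- 1  # cells expressing only highly-expressed genes are left unscaled
  values <- log1p(counts / sf)
  normalized_matrix(values, size_factors = sf, highly_expressed = he,
                    cell_meta = cm$cell_meta, gene_meta = cm$gene_meta)
}

#' Construct a normalized expression container
#'
#' Holds natural-log normalized values plus optional size factors, HVG mask
#' and scaled values; used by the scoring, annotation and trajectory-seed
#' stages. Exposed so that tests and simulations can construct normalized
#' data directly.
#'
#' @param values Numeric cells x genes matrix with gene names as columns.
#' @param size_factors,highly_expressed,hvg_mask,scaled_values Optional slots.
#' @param cell_meta,gene_meta Optional metadata data.frames.
#' @return Object of class `normalized_matrix`.
#' @export
normalized_matrix <- function(values, size_factors = NULL,
                              highly_expressed = NULL, hvg_mask = NULL,
                              scaled_values = NULL, cell_meta = NULL,
                              gene_meta = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("values must carry gene names")
  structure(list(values = values, size_factors = size_factors,
                 highly_expressed = highly_expressed, hvg_mask = hvg_mask,
                 scaled_values = scaled_values, cell_meta = cell_meta,
                 gene_meta = gene_meta),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d cells x %d genes%s%s\n",
              nrow(x$values), ncol(x$values),
              if (!is.null(x$hvg_mask)) sprintf(", %d HVGs", sum(x$hvg_mask)) else "",
              if (!is.null(x$scaled_values)) ", scaled" else ""))
  invisible(x)
}

#' Select highly variable genes
#'
#' Dispersion (variance / mean of expm1 values) is z-scored within
#' `n_bins` equal-occupancy mean-expression bins (genes binned by the rank
#' of their mean, so no bin degenerates to a single gene) and the top
#' `n_top` genes by normalized dispersion are flagged. Ties at the cutoff
#' are broken by gene index ascending, making the mask deterministic.
#'
#' @param nm A `normalized_matrix`.
#' @param n_top Number of genes to flag (default 5000).
#' @param n_bins Number of mean-expression bins (default 20).
#' @return The `normalized_matrix` with `hvg_mask` filled in.
#' @export
select_hvg <- function(nm, n_top = 5000, n_bins = 20) {
  stopifnot(inherits(nm, "normalized_matrix"))
  n_genes <- ncol(nm$values)
  if (n_top >= n_genes) {
    if (n_top > n_genes) warning("n_top exceeds the number of genes; flagging all")
    nm$hvg_mask <- rep(TRUE, n_genes)
    return(nm)
  }
  expd <- expm1(nm$values)
  mu <- colMeans(expd)
  v <- apply(expd, 2, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  bins <- ceiling(rank(mu, ties.method = "first") / (n_genes / n_bins))
  z <- disp
  for (b in unique(bins)) {
    idx <- which(bins == b)
    s <- stats::sd(disp[idx])
    m <- mean(disp[idx])
    z[idx] <- if (is.na(s) || s == 0) 0 else (disp[idx] - m) / s
  }
  ord <- order(-z, seq_len(n_genes))
  mask <- rep(FALSE, n_genes)
  mask[ord[seq_len(n_top)]] <- TRUE
  nm$hvg_mask <- mask
  nm
}

#' Scale genes to unit variance and clip
#'
#' Each gene is mean-centered and divided by its standard deviation;
#' zero-variance genes map to 0 and values above `max_value` are clipped to
#' `max_value`.
#'
#' @param nm A `normalized_matrix`.
#' @param max_value Upper clip (default 5).
#' @return The `normalized_matrix` with `scaled_values` filled in.
#' @export
scale_clip <- function(nm, max_value = 5) {
  stopifnot(inherits(nm, "normalized_matrix"))
  mu <- colMeans(nm$values)
  sd <- apply(nm$values, 2, stats::sd)
  sc <- sweep(nm$values, 2, mu, "-")
  sd_safe <- ifelse(sd > 0, sd, 1)
  sc <- sweep(sc, 2, sd_safe, "/")
  sc[, sd == 0] <- 0
  sc[sc > max_value] <- max_value
  nm$scaled_values <- sc
  nm
}

#' Cluster-robustness metrics over candidate labelings
#'
#' Computes the mean silhouette width (via \pkg{cluster}) and the
#' Davies-Bouldin index (euclidean, centroid-based) for each candidate
#' labeling of the same embedding, and selects the labeling that maximizes
#' the silhouette, breaking ties by the lower Davies-Bouldin index.
#' Labelings with fewer than two distinct labels are skipped with a warning.
#'
#' @param embedding Numeric cells x d matrix.
#' @param labelings Named list of label vectors (e.g. one per clustering
#'   resolution).
#' @return List with `metrics` (data.frame resolution/silhouette/
#'   davies_bouldin) and `selected` (name of the chosen labeling).
#' @export
cluster_robustness <- function(embedding, labelings) {
  embedding <- as.matrix(embedding)
  if (!is.list(labelings) || is.null(names(labelings)))
    stop("labelings must be a named list")
  d <- stats::dist(embedding)
  rows <- list()
  for (nm in names(labelings)) {
    lab <- as.integer(factor(labelings[[nm]]))
    if (length(lab) != nrow(embedding)) stop("labeling length mismatch for ", nm)
    if (length(unique(lab)) < 2L) {
      warning("labeling '", nm, "' has a single cluster; skipped")
      next
    }
    sil <- mean(cluster::silhouette(lab, d)[, "sil_width"])
    rows[[nm]] <- data.frame(resolution = nm, silhouette = sil,
                             davies_bouldin = davies_bouldin(embedding, lab),
                             stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no valid labelings")
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  ord <- order(-metrics$silhouette, metrics$davies_bouldin)
  list(metrics = metrics, selected = metrics$resolution[ord[1]])
}

# Davies-Bouldin index: mean over clusters of the worst (largest) ratio of
# summed within-cluster scatters to centroid separation.
davies_bouldin <- function(embedding, labels) {
  labs <- sort(unique(labels))
  cent <- t(vapply(labs, function(l) colMeans(embedding[labels == l, , drop = FALSE]),
                   numeric(ncol(embedding))))
  s <- vapply(seq_along(labs), function(i) {
    pts <- embedding[labels == labs[i], , drop = FALSE]
    mean(sqrt(rowSums((pts - rep(cent[i, ], each = nrow(pts)))^2)))
  }, numeric(1))
  k <- length(labs)
  r <- numeric(k)
  for (i in seq_len(k)) {
    ratios <- vapply(setdiff(seq_len(k), i), function(j) {
      m <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      if (m == 0) Inf else (s[i] + s[j]) / m
    }, numeric(1))
    r[i] <- max(ratios)
  }
  mean(r)
}

#' Read a 10x-style Matrix Market directory
#'
#' Expects `matrix.mtx` (genes stored on either axis; cells are inferred
#' from `barcodes.tsv`), `features.tsv` (gene symbols, one per line, first
#' column used) and `barcodes.tsv`, plus an optional `cell_meta.tsv` with
#' per-cell sample/condition/replicate/doublet-score columns.
#'
#' @param dir Directory containing the triplet files.
#' @return A [count_matrix()].
#' @export
read_counts_10x <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  feats <- utils::read.delim(file.path(dir, "features.tsv"), header = FALSE,
                             stringsAsFactors = FALSE)
  bcs <- utils::read.delim(file.path(dir, "barcodes.tsv"), header = FALSE,
                           stringsAsFactors = FALSE)[[1]]
  if (nrow(m) == nrow(feats) && ncol(m) == length(bcs)) m <- Matrix::t(m)
  if (nrow(m) != length(bcs) || ncol(m) != nrow(feats))
    stop("matrix dimensions do not match barcodes/features")
  m <- as(m, "CsparseMatrix")
  dimnames(m) <- list(bcs, feats[[1]])
  meta_path <- file.path(dir, "cell_meta.tsv")
  cell_meta <- if (file.exists(meta_path))
    utils::read.delim(meta_path, stringsAsFactors = FALSE) else NULL
  count_matrix(m, cell_meta)
}

#' Write a [count_matrix()] as a 10x-style Matrix Market directory
#'
#' Emits `matrix.mtx` (genes x cells, the 10x convention), `features.tsv`,
#' `barcodes.tsv` and `cell_meta.tsv`.
#'
#' @param cm A [count_matrix()].
#' @param dir Output directory (created if needed).
#' @export
write_counts_10x <- function(cm, dir) {
  stopifnot(inherits(cm, "count_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::t(as(as(cm$counts, "dMatrix"), "CsparseMatrix"))
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(cm$gene_meta$symbol, file.path(dir, "features.tsv"))
  writeLines(cm$cell_meta$cell_id, file.path(dir, "barcodes.tsv"))
  utils::write.table(cm$cell_meta, file.path(dir, "cell_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write a QC report as JSON
#' @param report A `qc_report`.
#' @param path Output path.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
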