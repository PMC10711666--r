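#' Gene signature definition
#'
#' A named gene list for control-matched scoring. Genes are de-duplicated;
#' the number of control genes defaults to the signature size (after
#' de-duplication), matching the convention of setting the control pool to
#' the input list size.
#'
#' @param name Signature name.
#' @param genes Character vector of gene symbols.
#' @param n_bins Number of mean-expression bins for control matching (25).
#' @param n_ctrl Control genes sampled per bin; defaults to the signature
#'   size.
#' @return A `gene_signature` object.
#' @export
gene_signature <- function(name, genes, n_bins = 25, n_ctrl = NULL) {
  genes <- unique(as.character(genes))
  if (!length(genes)) stop("signature must contain at least one gene")
  if (is.null(n_ctrl)) n_ctrl <- length(genes)
  if (n_ctrl < 1) stop("n_ctrl must be >= 1")
  structure(list(name = name, genes = genes, n_bins = n_bins, n_ctrl = n_ctrl),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature '%s': %d genes, %d bins, %d control genes/bin\n",
              x$name, length(x$genes), x$n_bins, x$n_ctrl))
  invisible(x)
}

#' Read signatures from a two-column TSV (signature, gene)
#' @param path TSV path.
#' @param n_bins,n_ctrl Passed to [gene_signature()].
#' @return Named list of [gene_signature()] objects.
#' @export
read_signatures <- function(path, n_bins = 25, n_ctrl = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("signature", "gene") %in% colnames(df)))
    stop("signature TSV needs columns signature, gene")
  sets <- split(df$gene, df$signature)
  stats::setNames(lapply(names(sets), function(nm)
    gene_signature(nm, sets[[nm]], n_bins = n_bins, n_ctrl = n_ctrl)),
    names(sets))
}

#' Score cells for a gene signature with expression-matched controls
#'
#' Control-bin scoring: all genes are binned by the rank of their mean
#' expression into `sig$n_bins` bins; for every bin containing signature
#' genes, `sig$n_ctrl` control genes are sampled uniformly without
#' replacement from that bin (signature genes excluded; the whole bin is
#' used when it is smaller). The per-cell score is the mean expression of
#' the signature genes minus the mean expression of the pooled control
#' genes. Signature genes absent from the matrix are dropped before
#' scoring; an empty post-filter signature is an error.
#'
#' @param nm A [normalized_matrix()].
#' @param sig A [gene_signature()].
#' @param seed Integer seed for the control-gene sampling.
#' @return Numeric score per cell, with the control genes used in the
#'   `"control_genes"` attribute.
#' @export
score_gene_set <- function(nm, sig, seed = 1L) {
  stopifnot(inherits(nm, "normalized_matrix"), inherits(sig, "gene_signature"))
  genes <- colnames(nm$values)
  sig_genes <- intersect(sig$genes, genes)
  if (!length(sig_genes)) stop("no signature gene present in the matrix")
  mu <- colMeans(nm$values)
  # rank-based binning: equal-occupancy bins over the mean-expression order
  n_bins <- min(sig$n_bins, length(genes))
  bin <- ceiling(rank(mu, ties.method = "first") / (length(genes) / n_bins))
  names(bin) <- genes
  ctrl <- with_seed(seed, {
    out <- character(0)
    for (b in sort(unique(bin[sig_genes]))) {
      pool <- setdiff(genes[bin == b], sig$genes)
      if (!length(pool)) next
      k <- min(sig$n_ctrl, length(pool))
      out <- c(out, pool[sample.int(length(pool), k)])
    }
    unique(out)
  })
  sig_mean <- rowMeans(nm$values[, sig_genes, drop = FALSE])
  ctrl_mean <- if (length(ctrl))
    rowMeans(nm$values[, ctrl, drop = FALSE]) else 0
  score <- sig_mean - ctrl_mean
  attr(score, "control_genes") <- ctrl
  attr(score, "retained_genes") <- sig_genes
  score
}

#' Assign cell-cycle phase from S and G2M scores
#'
#' G1 when neither score is positive; otherwise the phase of the larger
#' score. An exact positive tie is called G1 (documented tie rule).
#'
#' @param s_score,g2m_score Numeric vectors of per-cell scores.
#' @return Character vector with values `"S"`, `"G2M"`, `"G1"`.
#' @export
cell_cycle_phase <- function(s_score, g2m_score) {
  stopifnot(length(s_score) == length(g2m_score))
  phase <- rep("G1", length(s_score))
  phase[s_score > 0 & s_score > g2m_score] <- "S"
  phase[g2m_score > 0 & g2m_score > s_score] <- "G2M"
  phase
}

#' Score a battery of gene signatures
#'
#' Applies [score_gene_set()] per signature; signatures entirely absent
#' from the matrix are skipped with a warning. Retained-gene counts are
#' recorded in the `"retained"` attribute.
#'
#' @param nm A [normalized_matrix()].
#' @param signatures List of [gene_signature()] objects.
#' @param seed Integer seed (one stream per signature, offset by index).
#' @return Data.frame of per-cell scores (one column per signature), with
#'   `condition`/`cell_type` columns carried over from `nm$cell_meta` when
#'   present.
#' @export
go_score_battery <- function(nm, signatures, seed = 1L) {
  stopifnot(inherits(nm, "normalized_matrix"))
  cols <- list()
  retained <- integer(0)
  for (i in seq_along(signatures)) {
    sig <- signatures[[i]]
    if (!length(intersect(sig$genes, colnames(nm$values)))) {
      warning("signature '", sig$name, "' absent from the matrix; skipped")
      next
    }
    sc <- score_gene_set(nm, sig, seed = seed + i - 1L)
    cols[[sig$name]] <- as.numeric(sc)
    retained[sig$name] <- length(attr(sc, "retained_genes"))
  }
  if (!length(cols)) stop("no signature could be scored")
  out <- as.data.frame(cols, check.names = FALSE)
  for (cc in c("condition", "cell_type")) {
    if (!is.null(nm$cell_meta[[cc]])) out[[cc]] <- nm$cell_meta[[cc]]
  }
  attr(out, "retained") <- retained
  out
}

# Significance stars at the 0.05 / 0.01 / 0.001 thresholds.
p_stars <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "")))
}

#' Severity ratios of signature scores, treatment vs matched control
#'
#' For every signature column and every treatment condition, computes the
#' ratio of mean scores (treatment / matched control) and a two-sided
#' Mann-Whitney U p-value over all cells, overall and optionally per cell
#' type. A zero control mean leaves the ratio undefined (NA) with the
#' `undefined` flag set.
#'
#' @param scores Data.frame from [go_score_battery()] (signature columns
#'   plus `condition` and, for per-cell-type mode, `cell_type`).
#' @param design Named character vector: treatment condition -> matched
#'   control condition.
#' @param by_cell_type Also emit one row per cell type (default FALSE).
#' @param bonferroni Multiply p-values by the number of emitted comparisons
#'   (default FALSE, matching raw reporting).
#' @return Data.frame with `signature`, `treatment`, `cell_type` ("all" for
#'   the pooled rows), `ratio_of_means`, `U`, `p`, `stars`, `n_treat`,
#'   `n_ctrl_cells`, `undefined`.
#' @export
severity_ratios <- function(scores, design, by_cell_type = FALSE,
                            bonferroni = FALSE) {
  if (is.null(scores$condition)) stop("scores needs a condition column")
  sig_cols <- setdiff(colnames(scores), c("condition", "cell_type"))
  rows <- list()
  emit <- function(sig, treat, ctrl, subset_label, sel_t, sel_c) {
    x <- scores[[sig]][sel_t]; y <- scores[[sig]][sel_c]
    if (length(x) < 2 || length(y) < 2)
      stop("treatment and matched control need >= 2 cells each (",
           sig, ", ", treat, ", ", subset_label, ")")
    mt <- mean(x); mc <- mean(y)
    undef <- mc == 0
    tst <- mann_whitney_u(x, y)
    data.frame(signature = sig, treatment = treat, cell_type = subset_label,
               ratio_of_means = if (undef) NA_real_ else mt / mc,
               U = tst$statistic, p = tst$p_value,
               n_treat = length(x), n_ctrl_cells = length(y),
               undefined = undef, stringsAsFactors = FALSE)
  }
  for (sig in sig_cols) {
    for (treat in names(design)) {
      ctrl <- design[[treat]]
      sel_t <- scores$condition == treat
      sel_c <- scores$condition == ctrl
      rows[[length(rows) + 1L]] <- emit(sig, treat, ctrl, "all", sel_t, sel_c)
      if (by_cell_type && !is.null(scores$cell_type)) {
        for (ct in sort(unique(scores$cell_type))) {
          st <- sel_t & scores$cell_type == ct
          sc <- sel_c & scores$cell_type == ct
          if (sum(st) >= 2 && sum(sc) >= 2)
            rows[[length(rows) + 1L]] <- emit(sig, treat, ctrl, ct, st, sc)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (bonferroni) out$p <- pmin(1, out$p * nrow(out))
  out$stars <- p_stars(out$p)
  rownames(out) <- NULL
  out
}
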