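#' Rank genes between clusters by the Wilcoxon rank-sum z statistic
#'
#' For each group of cells, every gene is tested with a tie-corrected
#' rank-sum z statistic (normal approximation, no continuity correction, as
#' is standard for per-gene marker screens), two-sided p-values are
#' Benjamini-Hochberg adjusted within the group, and genes are returned
#' sorted by the statistic in decreasing order.
#'
#' In `one_vs_rest` mode each label is compared against all remaining cells.
#' In `pairwise` mode each non-reference label is compared against the cells
#' carrying the reference label (`ref`); mitochondrial and ribosomal genes
#' are expected to have been removed by the caller for treatment-vs-control
#' contrasts.
#'
#' @param values Numeric cells x genes matrix of normalized expression
#'   (dense or `Matrix` sparse), with gene names as column names.
#' @param labels Factor or character vector, one label per cell (row).
#' @param mode `"one_vs_rest"` or `"pairwise"`.
#' @param ref Reference label for `pairwise` mode.
#' @param exact Route per-gene p-values through [mann_whitney_u()] (exact
#'   enumeration where feasible) instead of the z approximation; intended
#'   for small contrasts.
#' @param lfc_eps Pseudocount used in the log2 fold-change of expm1 means.
#' @return A data.frame with columns `group`, `gene`, `statistic`, `p`,
#'   `adj_p`, `lfc`, sorted by statistic within group. Labels with fewer
#'   than 2 cells are skipped; the skipped labels are recorded in the
#'   `"skipped"` attribute and announced with a warning.
#' @export
wilcoxon_rank_genes <- function(values, labels,
                                mode = c("one_vs_rest", "pairwise"),
                                ref = NULL, exact = FALSE, lfc_eps = 1e-9) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if (is.null(colnames(values))) colnames(values) <- paste0("g", seq_len(ncol(values)))
  labels <- as.character(labels)
  if (length(labels) != nrow(values)) stop("one label per cell (row) required")
  if (length(unique(labels)) < 2L) stop("need >= 2 distinct labels")
  if (mode == "pairwise") {
    if (is.null(ref) || !ref %in% labels) stop("pairwise mode needs a reference label present in `labels`")
    targets <- setdiff(unique(labels), ref)
  } else {
    targets <- unique(labels)
  }
  targets <- sort(targets)

  counts <- table(labels)
  skipped <- names(counts)[counts < 2L]
  if (length(skipped)) {
    warning("skipping labels with < 2 cells: ", paste(skipped, collapse = ", "))
    targets <- setdiff(targets, skipped)
  }

  # Midranks and tie terms per gene over the cells entering a contrast.
  rank_parts <- function(mat) {
    list(rk = apply(mat, 2, rank),
         tie = vapply(seq_len(ncol(mat)), function(j) {
           t <- rle(sort.int(mat[, j]))$lengths
           sum(t^3 - t)
         }, numeric(1)))
  }
  rank_z <- function(parts, in_group) {
    n1 <- sum(in_group); n2 <- sum(!in_group); N <- n1 + n2
    rsum <- colSums(parts$rk[in_group, , drop = FALSE])
    mu <- n1 * (N + 1) / 2
    sigma2 <- n1 * n2 / 12 * ((N + 1) - parts$tie / (N * (N - 1)))
    ifelse(sigma2 > 0, (rsum - mu) / sqrt(sigma2), 0)
  }
  shared_parts <- if (mode == "one_vs_rest") rank_parts(values) else NULL

  res <- lapply(targets, function(gr) {
    if (mode == "one_vs_rest") {
      sub <- values
      in_group <- labels == gr
      parts <- shared_parts
    } else {
      keep <- labels %in% c(gr, ref)
      sub <- values[keep, , drop = FALSE]
      in_group <- labels[keep] == gr
      parts <- rank_parts(sub)
    }
    z <- rank_z(parts, in_group)
    p <- if (exact) {
      vapply(seq_len(ncol(sub)), function(j)
        mann_whitney_u(sub[in_group, j], sub[!in_group, j])$p_value, numeric(1))
    } else {
      2 * stats::pnorm(abs(z), lower.tail = FALSE)
    }
    adj <- benjamini_hochberg(p)
    m1 <- colMeans(expm1(sub[in_group, , drop = FALSE]))
    m0 <- colMeans(expm1(sub[!in_group, , drop = FALSE]))
    lfc <- log2((m1 + lfc_eps) / (m0 + lfc_eps))
    out <- data.frame(group = gr, gene = colnames(values),
                      statistic = z, p = p, adj_p = adj, lfc = lfc,
                      row.names = NULL, stringsAsFactors = FALSE)
    out[order(-out$statistic, out$gene), , drop = FALSE]
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Write a ranked gene table to TSV
#'
#' Serializes the output of [wilcoxon_rank_genes()] with columns
#' `group, gene, statistic, p, adj_p, lfc`.
#'
#' @param ranked Data.frame from [wilcoxon_rank_genes()].
#' @param path Output file path.
#' @export
write_ranked_genes <- function(ranked, path) {
  utils::write.table(ranked[, c("group", "gene", "statistic", "p", "adj_p", "lfc")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ranked gene table written by [write_ranked_genes()]
#' @param path TSV path.
#' @return Data.frame with the serialized columns.
#' @export
read_ranked_genes <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
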