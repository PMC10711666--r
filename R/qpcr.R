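#' Collapse technical replicates and gate on housekeeping Ct
#'
#' Means over technical replicates per sample x gene (triplicates expected;
#' fewer trigger a warning but are tolerated). Samples whose housekeeping
#' mean Ct is not strictly below `hk_max`, or that lack the housekeeping
#' gene, are rejected with a reason.
#'
#' @param ct A `ct_table` (data.frame `sample_id, condition, gene,
#'   tech_rep, ct` with a `"housekeeping"` attribute), e.g. from
#'   [make_ct_table()] or [read_ct_table()].
#' @param housekeeping Housekeeping gene; defaults to the table attribute.
#' @param hk_max Housekeeping acceptance bound (strict; mean Ct of exactly
#'   `hk_max` rejects). Default 35.
#' @param expected_reps Expected technical replicates (default 3).
#' @return List with `means` (data.frame `sample_id, condition, gene,
#'   mean_ct, n_reps`), `hk_means`, and `rejected` (data.frame `sample_id,
#'   reason`).
#' @export
collapse_and_gate <- function(ct, housekeeping = attr(ct, "housekeeping"),
                              hk_max = 35, expected_reps = 3) {
  if (is.null(housekeeping)) stop("housekeeping gene not specified")
  if (any(ct$ct <= 0)) stop("Ct values must be positive")
  key <- interaction(ct$sample_id, ct$gene, drop = TRUE)
  agg <- do.call(rbind, lapply(split(ct, key), function(d) {
    data.frame(sample_id = d$sample_id[1], condition = d$condition[1],
               gene = d$gene[1], mean_ct = mean(d$ct), n_reps = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  if (any(agg$n_reps < expected_reps))
    warning(sum(agg$n_reps < expected_reps),
            " sample x gene mean(s) computed from fewer than ",
            expected_reps, " technical replicates")
  samples <- unique(agg$sample_id)
  hk <- agg[agg$gene == housekeeping, , drop = FALSE]
  rejected <- data.frame(sample_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  for (s in samples) {
    row <- hk[hk$sample_id == s, , drop = FALSE]
    if (!nrow(row)) {
      rejected <- rbind(rejected, data.frame(
        sample_id = s, reason = "missing housekeeping", stringsAsFactors = FALSE))
    } else if (row$mean_ct >= hk_max) {
      rejected <- rbind(rejected, data.frame(
        sample_id = s, reason = sprintf("housekeeping mean Ct %.2f >= %g",
                                        row$mean_ct, hk_max),
        stringsAsFactors = FALSE))
    }
  }
  keep <- !(agg$sample_id %in% rejected$sample_id)
  list(means = agg[keep, , drop = FALSE],
       hk_means = hk[, c("sample_id", "condition", "mean_ct")],
       rejected = rejected, housekeeping = housekeeping)
}

#' Delta-delta-Ct fold changes
#'
#' Per sample and target gene: delta Ct = target mean Ct minus housekeeping
#' mean Ct; delta-delta Ct = delta Ct minus the mean control delta Ct of
#' that gene; fold = 2^(-ddCt). Both `fold` (2^-ddCt) and `log2_fold`
#' (-ddCt) are emitted. At least `min_control_reps` control biological
#' replicates per gene are required (overridable with a warning).
#'
#' @param collapsed Output of [collapse_and_gate()].
#' @param control Control condition name.
#' @param min_control_reps Minimum control biological replicates (3).
#' @return Data.frame (class `fold_change_table`) with `sample_id,
#'   condition, gene, delta_ct, ddct, fold, log2_fold`.
#' @export
ddct_fold <- function(collapsed, control = "control", min_control_reps = 3) {
  means <- collapsed$means
  hk <- collapsed$housekeeping
  hk_by_sample <- stats::setNames(
    means$mean_ct[means$gene == hk], means$sample_id[means$gene == hk])
  targets <- means[means$gene != hk, , drop = FALSE]
  if (!nrow(targets)) stop("no target genes present")
  targets$delta_ct <- targets$mean_ct - hk_by_sample[targets$sample_id]
  if (!any(targets$condition == control)) stop("no control samples present")
  rows <- lapply(split(targets, targets$gene), function(d) {
    ctrl <- d$delta_ct[d$condition == control]
    if (length(ctrl) < min_control_reps)
      warning("gene ", d$gene[1], ": only ", length(ctrl),
              " control replicate(s), fewer than ", min_control_reps)
    if (!length(ctrl)) stop("gene ", d$gene[1], " has no control samples")
    d$ddct <- d$delta_ct - mean(ctrl)
    d
  })
  out <- do.call(rbind, rows)
  out$fold <- 2^(-out$ddct)
  out$log2_fold <- -out$ddct
  out <- out[order(out$gene, out$condition, out$sample_id),
             c("sample_id", "condition", "gene", "delta_ct", "ddct",
               "fold", "log2_fold")]
  rownames(out) <- NULL
  class(out) <- c("fold_change_table", "data.frame")
  out
}

#' Group statistics on fold changes (or delta Cts)
#'
#' Two groups are compared with the two-sided Mann-Whitney U test; three or
#' more groups with Kruskal-Wallis followed by Conover's post hoc test with
#' Bonferroni correction. Differences are flagged significant at p < 0.05.
#'
#' @param folds A `fold_change_table` (or any data.frame with `condition`
#'   and a value column).
#' @param gene Gene to test (required when several genes are present).
#' @param value Column to test: `"fold"` (default) or `"delta_ct"`.
#' @return For two groups, a list with the `lb_test` and a one-row summary
#'   data.frame; for more, a list with the Kruskal-Wallis `lb_test`, the
#'   Conover pairwise p matrix, and a pairwise summary data.frame.
#' @export
group_compare <- function(folds, gene = NULL, value = "fold") {
  d <- folds
  if (!is.null(gene)) d <- d[d$gene == gene, , drop = FALSE]
  if (!is.null(d$gene) && length(unique(d$gene)) > 1)
    stop("several genes present; pass `gene`")
  if (!value %in% colnames(d)) stop("no column '", value, "'")
  groups <- split(d[[value]], d$condition)
  if (length(groups) < 2) stop("need >= 2 groups")
  if (any(lengths(groups) < 2)) stop("every group needs >= 2 values")
  if (length(groups) == 2) {
    tst <- mann_whitney_u(groups[[1]], groups[[2]])
    summary <- data.frame(group1 = names(groups)[1], group2 = names(groups)[2],
                          p = tst$p_value, significant = tst$p_value < 0.05,
                          stars = p_stars(tst$p_value), stringsAsFactors = FALSE)
    list(test = tst, pairwise = summary)
  } else {
    kw <- kruskal_wallis(groups)
    pm <- conover_posthoc(groups, p_adjust = "bonferroni")
    cmb <- utils::combn(names(groups), 2)
    summary <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                          p = pm[cbind(cmb[1, ], cmb[2, ])],
                          stringsAsFactors = FALSE)
    summary$significant <- summary$p < 0.05
    summary$stars <- p_stars(summary$p)
    list(test = kw, conover = pm, pairwise = summary)
  }
}
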