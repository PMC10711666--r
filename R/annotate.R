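#' Marker database
#'
#' Named cell types mapped to marker gene lists. Lists are de-duplicated;
#' empty lists are rejected.
#'
#' @param entries Named list: cell type -> character vector of gene symbols.
#' @param source One of `"literature"`, `"sctype"`, `"reference_dge"`.
#' @return A `marker_db` object.
#' @export
marker_db <- function(entries, source = c("literature", "sctype", "reference_dge")) {
  source <- match.arg(source)
  if (!is.list(entries) || is.null(names(entries)) || !length(entries))
    stop("entries must be a non-empty named list")
  entries <- lapply(entries, function(g) unique(as.character(g)))
  if (any(lengths(entries) == 0L)) stop("marker gene lists must be non-empty")
  structure(list(entries = entries, source = source), class = "marker_db")
}

#' @export
print.marker_db <- function(x, ...) {
  cat(sprintf("marker_db (%s): %d cell types, %d genes total\n", x$source,
              length(x$entries), length(unique(unlist(x$entries)))))
  invisible(x)
}

#' Read / write a marker database as two-column TSV (cell_type, gene)
#' @param path TSV path.
#' @param source Source tag for the returned database.
#' @return A [marker_db()].
#' @export
read_marker_db <- function(path, source = "literature") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("cell_type", "gene") %in% colnames(df)))
    stop("marker TSV needs columns cell_type, gene")
  marker_db(split(df$gene, df$cell_type), source = source)
}

#' @rdname read_marker_db
#' @param db A [marker_db()].
#' @export
write_marker_db <- function(db, path) {
  df <- data.frame(cell_type = rep(names(db$entries), lengths(db$entries)),
                   gene = unlist(db$entries, use.names = FALSE),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Annotate clusters by marker over-representation
#'
#' For each cluster, the top `top_n` ranked marker genes are tested against
#' every candidate cell type in the database with a hypergeometric
#' over-representation test (candidate markers are first intersected with
#' the dataset's gene universe; the number of genes in the dataset is the
#' background). P-values are Benjamini-Hochberg adjusted across candidates
#' within the cluster. Among candidates with adjusted p below `alpha`, the
#' label with the most overlapping marker genes wins (ties: lower adjusted
#' p, then lexicographic). If no candidate is significant, the fallback is
#' the lowest adjusted p (ties: most matching genes), with the fallback
#' flag set. The embryonic-stem-cell label is accepted only when at least
#' one gate gene (`SOX2`, `NANOG`, `POU5F1`, `KLF1` by default) has nonzero
#' expression in at least one cell of the cluster; otherwise that candidate
#' is skipped and the next-ranked candidate is used.
#'
#' @param ranked Data.frame from [wilcoxon_rank_genes()] (columns `group`,
#'   `gene`, `statistic`, ...), or a named list of ranked gene character
#'   vectors per cluster.
#' @param db A [marker_db()].
#' @param background Gene-universe size (number of genes in the dataset).
#' @param universe Character vector of dataset genes used to intersect
#'   candidate marker sets; defaults to the genes appearing in `ranked`.
#' @param top_n Number of top-ranked genes per cluster to query (200).
#' @param alpha Adjusted-p significance cutoff (0.05).
#' @param esc_label Database label subject to the expression gate.
#' @param esc_gate_genes Gate genes.
#' @param expression Optional [normalized_matrix()] used to evaluate the
#'   gate.
#' @param cell_labels Cluster label per cell of `expression` (required when
#'   the database contains `esc_label` and `expression` is given).
#' @return Data.frame with one row per cluster: `cluster_id`, `label`,
#'   `adj_p`, `matched_genes`, `significant`, `fallback_used`,
#'   `gate_failed_labels`.
#' @export
annotate_clusters <- function(ranked, db, background, universe = NULL,
                              top_n = 200, alpha = 0.05,
                              esc_label = "Embryonic stem cells",
                              esc_gate_genes = c("SOX2", "NANOG", "POU5F1", "KLF1"),
                              expression = NULL, cell_labels = NULL) {
  stopifnot(inherits(db, "marker_db"))
  if (is.data.frame(ranked)) {
    if (is.null(universe)) universe <- unique(ranked$gene)
    ranked <- lapply(split(ranked, ranked$group), function(d)
      d$gene[order(-d$statistic, d$gene)])
  } else if (is.null(universe)) {
    universe <- unique(unlist(ranked))
  }
  if (!length(db$entries)) stop("empty marker database")

  gate_ok <- function(cluster_id) {
    if (is.null(expression)) return(TRUE)
    if (is.null(cell_labels)) stop("cell_labels required to evaluate the gate")
    gg <- intersect(esc_gate_genes, colnames(expression$values))
    if (!length(gg)) return(FALSE)
    cells <- cell_labels == cluster_id
    any(expression$values[cells, gg, drop = FALSE] > 0)
  }

  rows <- lapply(names(ranked), function(cl) {
    genes <- ranked[[cl]]
    if (!length(genes)) {
      return(data.frame(cluster_id = cl, label = NA_character_, adj_p = NA_real_,
                        matched_genes = 0L, significant = FALSE,
                        fallback_used = FALSE, gate_failed_labels = "",
                        stringsAsFactors = FALSE))
    }
    query <- utils::head(genes, top_n)
    cand <- names(db$entries)
    res <- lapply(cand, function(ct) {
      set <- intersect(db$entries[[ct]], universe)
      ov <- length(intersect(query, set))
      p <- if (length(set)) hypergeom_overrep(ov, length(set), length(query),
                                              background) else 1
      c(overlap = ov, p = p)
    })
    ov <- vapply(res, `[[`, 0, "overlap")
    p <- vapply(res, `[[`, 0, "p")
    adj <- benjamini_hochberg(p)

    gate_failed <- character(0)
    pick_from <- function(idx_order) {
      for (i in idx_order) {
        if (cand[i] == esc_label && !gate_ok(cl)) {
          gate_failed <<- c(gate_failed, cand[i])
          next
        }
        return(i)
      }
      NA_integer_
    }
    sig_idx <- which(adj < alpha)
    if (length(sig_idx)) {
      ord <- sig_idx[order(-ov[sig_idx], adj[sig_idx], cand[sig_idx])]
      pick <- pick_from(ord)
      fallback <- FALSE
      if (is.na(pick)) { sig_idx <- integer(0) } # all significant labels gated out
    }
    if (!length(sig_idx)) {
      ord <- order(adj, -ov, cand)
      ord <- setdiff(ord, which(cand %in% gate_failed))
      pick <- pick_from(ord)
      fallback <- TRUE
    }
    if (is.na(pick)) {
      return(data.frame(cluster_id = cl, label = NA_character_, adj_p = NA_real_,
                        matched_genes = 0L, significant = FALSE,
                        fallback_used = TRUE,
                        gate_failed_labels = paste(gate_failed, collapse = ";"),
                        stringsAsFactors = FALSE))
    }
    data.frame(cluster_id = cl, label = cand[pick], adj_p = adj[pick],
               matched_genes = as.integer(ov[pick]),
               significant = adj[pick] < alpha && !fallback,
               fallback_used = fallback,
               gate_failed_labels = paste(gate_failed, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Derive marker sets from a pairwise stage-vs-precursor DGE table
#'
#' For each developmental stage, the marker set is the genes with a
#' positive log fold change versus the precursor stage. The earliest stage
#' (`HB1` in the hepatoblast reference) has no precursor comparison; its
#' markers are the genes with a negative log fold change in the
#' `HB2`-vs-`HB1` comparison. Sets can be truncated to the top `top_n`
#' genes ranked by log fold change descending (absolute value for the
#' negative-lfc special case).
#'
#' @param ref_table Data.frame with columns `gene`, `stage`, `precursor`,
#'   `lfc` (one row per gene per comparison `stage` vs `precursor`).
#' @param top_n Optional truncation per stage (e.g. 100 for zonation
#'   reference sets).
#' @param negative_lfc_stage Stage whose markers come from negative lfc in
#'   its successor's comparison (default `"HB1"`).
#' @return A [marker_db()] with source `"reference_dge"`.
#' @export
derive_marker_sets_from_pairwise_dge <- function(ref_table, top_n = NULL,
                                                 negative_lfc_stage = "HB1") {
  need <- c("gene", "stage", "precursor", "lfc")
  if (!all(need %in% colnames(ref_table)))
    stop("ref_table needs columns ", paste(need, collapse = ", "))
  entries <- list()
  for (st in unique(ref_table$stage)) {
    d <- ref_table[ref_table$stage == st & ref_table$lfc > 0, , drop = FALSE]
    g <- d$gene[order(-d$lfc, d$gene)]
    if (!is.null(top_n)) g <- utils::head(g, top_n)
    if (length(g)) entries[[st]] <- g
    else warning("stage ", st, " has no positive-lfc genes; empty set skipped")
  }
  if (!is.null(negative_lfc_stage)) {
    d <- ref_table[ref_table$precursor == negative_lfc_stage &
                     ref_table$lfc < 0, , drop = FALSE]
    if (nrow(d)) {
      g <- d$gene[order(d$lfc, d$gene)]  # most negative first
      if (!is.null(top_n)) g <- utils::head(g, top_n)
      entries[[negative_lfc_stage]] <- g
    } else if (!negative_lfc_stage %in% names(entries)) {
      warning("no negative-lfc genes available for ", negative_lfc_stage)
    }
  }
  if (!length(entries)) stop("no marker sets could be derived")
  marker_db(entries, source = "reference_dge")
}

#' Require clusters to represent every control replicate
#'
#' Clusters lacking at least one cell from any control replicate are
#' excluded from downstream analysis.
#'
#' @param labels Cluster label per cell.
#' @param cell_meta Data.frame with `condition` and `replicate` columns.
#' @param control Value of `condition` identifying control cells.
#' @return List with `kept` (cluster labels retained), `excluded`
#'   (clusters removed) and `excluded_cells` (cell count removed).
#' @export
enforce_control_representation <- function(labels, cell_meta,
                                           control = "control") {
  is_ctrl <- cell_meta$condition == control
  if (!any(is_ctrl)) stop("no control replicates in metadata")
  reps <- unique(cell_meta$replicate[is_ctrl])
  cl <- unique(labels)
  ok <- vapply(cl, function(c) {
    present <- unique(cell_meta$replicate[is_ctrl & labels == c])
    all(reps %in% present)
  }, logical(1))
  list(kept = cl[ok], excluded = cl[!ok],
       excluded_cells = sum(labels %in% cl[!ok]))
}

#' Merge non-significant clusters into their nearest annotated neighbor
#'
#' Automates the manual merge step: each cluster whose annotation is not
#' significant is re-labeled to the significantly annotated cluster whose
#' mean expression profile (over HVGs) is nearest in euclidean distance;
#' ties go to the lower cluster index. Provenance is recorded in a
#' `merged_from` column.
#'
#' @param decisions Data.frame from [annotate_clusters()].
#' @param centroids Numeric matrix, one row per cluster (rownames =
#'   `cluster_id`), columns = genes (typically HVGs).
#' @return The decisions with non-significant rows re-labeled and a
#'   `merged_into` column.
#' @export
merge_nonsignificant_cluster <- function(decisions, centroids) {
  stopifnot(all(decisions$cluster_id %in% rownames(centroids)))
  out <- decisions
  out$merged_into <- NA_character_
  sig <- decisions$cluster_id[decisions$significant]
  if (!length(sig)) {
    warning("all clusters non-significant; nothing to merge into")
    return(out)
  }
  for (i in which(!decisions$significant)) {
    cl <- decisions$cluster_id[i]
    d <- vapply(sig, function(s)
      sqrt(sum((centroids[cl, ] - centroids[s, ])^2)), numeric(1))
    best <- sig[order(d, match(sig, decisions$cluster_id))][1]
    out$label[i] <- decisions$label[decisions$cluster_id == best]
    out$merged_into[i] <- best
  }
  out
}

#' Default periportal-to-pericentral zonation map
#'
#' Integer scores 0-5 for the six adult hepatocyte reference clusters,
#' periportal (0) to pericentral (5).
#' @return Named integer vector.
#' @export
zonation_map_default <- function() {
  c("Periportal-C5" = 0L, "Periportal-C14" = 1L, "Periportal-C6" = 2L,
    "Interzonal-C15" = 3L, "Pericentral-C1" = 4L, "Pericentral-C3" = 5L)
}

#' Zonation score per cell
#'
#' Direct lookup of each cell's reference zone cluster in the zonation map.
#'
#' @param cell_labels Reference zone cluster per cell.
#' @param zmap Named integer map (default [zonation_map_default()]); scores
#'   must be consecutive integers starting at 0.
#' @return Integer score per cell.
#' @export
zonation_score <- function(cell_labels, zmap = zonation_map_default()) {
  if (!identical(sort(unname(zmap)), seq_along(zmap) - 1L))
    stop("zonation map scores must be consecutive integers starting at 0")
  unknown <- setdiff(unique(cell_labels), names(zmap))
  if (length(unknown)) stop("unknown zone label(s): ",
                            paste(unknown, collapse = ", "))
  unname(zmap[as.character(cell_labels)])
}

#' Select the early cell for trajectory seeding
#'
#' Among the cells with nonzero expression of the gate gene, returns the
#' cell maximizing the target gene (ties: lowest cell index). Used to seed
#' trajectory inference, e.g. highest AFP among CEBPA-expressing cells for
#' the hepatic progenitor lineage.
#'
#' @param nm A [normalized_matrix()].
#' @param maximize_gene Gene whose expression is maximized.
#' @param gate_gene Gene that must be expressed (> 0).
#' @return Cell index (row of `nm$values`), with the cell id (if present in
#'   `cell_meta`) as its name.
#' @export
select_early_cell <- function(nm, maximize_gene, gate_gene) {
  stopifnot(inherits(nm, "normalized_matrix"))
  for (g in c(maximize_gene, gate_gene))
    if (!g %in% colnames(nm$values)) stop("gene not in matrix: ", g)
  gated <- which(nm$values[, gate_gene] > 0)
  if (!length(gated)) stop("no cell expresses the gate gene ", gate_gene)
  idx <- gated[which.max(nm$values[gated, maximize_gene])]
  nms <- if (!is.null(nm$cell_meta$cell_id)) nm$cell_meta$cell_id[idx] else NULL
  stats::setNames(idx, nms)
}
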