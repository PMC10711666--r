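#' Paired receptor-ligand interaction tables
#'
#' Container for CellPhoneDB-style output: a `means` and a `pvalues` matrix
#' sharing rows (receptor-ligand pairs, e.g. `"NRP1_VEGFA"`) and columns
#' (all ordered `"source|target"` cluster pairs, self-pairs included).
#'
#' @param means,pvalues Numeric matrices with identical dimnames.
#' @param condition Condition tag.
#' @param clusters Cluster label vector; inferred from column labels when
#'   omitted.
#' @return An `interaction_tables` object.
#' @export
interaction_tables <- function(means, pvalues, condition = "condition",
                               clusters = NULL) {
  if (!identical(dimnames(means), dimnames(pvalues)))
    stop("means and pvalues must share identical row/column labels")
  if (any(pvalues < 0 | pvalues > 1)) stop("pvalues must lie in [0, 1]")
  cols <- colnames(pvalues)
  if (any(!grepl("\\|", cols))) stop("malformed column label (expected 'A|B')")
  parts <- strsplit(cols, "|", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop("malformed column label (expected 'A|B')")
  if (is.null(clusters)) clusters <- unique(unlist(parts))
  src <- vapply(parts, `[`, "", 1); tgt <- vapply(parts, `[`, "", 2)
  if (!all(src %in% clusters) || !all(tgt %in% clusters))
    stop("column labels reference clusters outside the cluster list")
  structure(list(means = means, pvalues = pvalues, condition = condition,
                 clusters = clusters),
            class = "interaction_tables")
}

#' @export
print.interaction_tables <- function(x, ...) {
  cat(sprintf("interaction_tables (%s): %d pairs x %d cluster-pair columns (%d clusters)\n",
              x$condition, nrow(x$pvalues), ncol(x$pvalues), length(x$clusters)))
  invisible(x)
}

#' Read CellPhoneDB v2 means/pvalues text output
#'
#' Tab-separated files whose metadata columns (`id_cp_interaction`,
#' `interacting_pair`, ...) precede the `"A|B"` cluster-pair columns; rows
#' are keyed by `interacting_pair`.
#'
#' @param means_path,pvalues_path File paths.
#' @param condition Condition tag for the returned object.
#' @return An [interaction_tables()].
#' @export
read_cpdb_tables <- function(means_path, pvalues_path, condition = "condition") {
  read_one <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    cc <- grepl("|", colnames(df), fixed = TRUE)
    key <- if ("interacting_pair" %in% colnames(df)) df$interacting_pair else df[[1]]
    m <- as.matrix(df[, cc, drop = FALSE])
    rownames(m) <- key
    storage.mode(m) <- "double"
    m
  }
  mn <- read_one(means_path); pv <- read_one(pvalues_path)
  if (!identical(rownames(mn), rownames(pv)) ||
      !identical(colnames(mn), colnames(pv)))
    stop("means and pvalues files do not share the same rows/columns")
  interaction_tables(mn, pv, condition = condition)
}

#' Write an [interaction_tables()] as CellPhoneDB v2 style text files
#' @param tables An [interaction_tables()].
#' @param dir Output directory; `means.txt` and `pvalues.txt` are created.
#' @export
write_cpdb_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(m, path) {
    df <- data.frame(id_cp_interaction = sprintf("CPI-%04d", seq_len(nrow(m))),
                     interacting_pair = rownames(m), check.names = FALSE,
                     stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(m, check.names = FALSE))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  emit(tables$means, file.path(dir, "means.txt"))
  emit(tables$pvalues, file.path(dir, "pvalues.txt"))
  invisible(dir)
}

#' Count significant interactions per source-target cluster pair
#'
#' An interaction row counts toward column `"s|t"` when its p-value is
#' strictly below `alpha`. Returns counts, the per-condition total, and the
#' fraction matrix (counts divided by the total, which sums to 1 when the
#' total is positive).
#'
#' @param tables An [interaction_tables()].
#' @param alpha Significance cutoff (strict inequality; default 0.05).
#' @return An `interaction_summary`: list with `counts` and `fractions`
#'   (source x target matrices), `total`, `condition`, `clusters`.
#' @export
count_significant <- function(tables, alpha = 0.05) {
  stopifnot(inherits(tables, "interaction_tables"))
  cl <- tables$clusters
  counts <- matrix(0L, length(cl), length(cl), dimnames = list(cl, cl))
  sig <- tables$pvalues < alpha
  parts <- strsplit(colnames(tables$pvalues), "|", fixed = TRUE)
  for (j in seq_along(parts)) {
    counts[parts[[j]][1], parts[[j]][2]] <-
      counts[parts[[j]][1], parts[[j]][2]] + sum(sig[, j])
  }
  total <- sum(counts)
  fractions <- if (total > 0) counts / total else counts * 0
  structure(list(counts = counts, fractions = fractions, total = total,
                 condition = tables$condition, clusters = cl),
            class = "interaction_summary")
}

#' @export
print.interaction_summary <- function(x, ...) {
  cat(sprintf("interaction_summary (%s): %d significant interactions over %d x %d cluster grid\n",
              x$condition, x$total, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Treatment-minus-control interaction fraction delta
#'
#' Subtracts the control fraction matrix from the treatment fraction
#' matrix. Entries with a positive delta form the "enforced" partition,
#' entries with a negative delta the "reduced" partition; zero entries
#' belong to neither. The delta matrix sums to zero by construction.
#'
#' @param treat,ctrl `interaction_summary` objects over the same clusters.
#' @return List with `delta` (matrix), `enforced` and `reduced`
#'   (data.frames with `source`, `target`, `delta`).
#' @export
fraction_delta <- function(treat, ctrl) {
  stopifnot(inherits(treat, "interaction_summary"),
            inherits(ctrl, "interaction_summary"))
  if (!identical(treat$clusters, ctrl$clusters))
    stop("treatment and control summaries cover different cluster sets")
  delta <- treat$fractions - ctrl$fractions
  idx <- which(delta != 0, arr.ind = TRUE)
  part <- data.frame(source = rownames(delta)[idx[, 1]],
                     target = colnames(delta)[idx[, 2]],
                     delta = delta[idx], stringsAsFactors = FALSE)
  list(delta = delta,
       enforced = part[part$delta > 0, , drop = FALSE],
       reduced = part[part$delta < 0, , drop = FALSE])
}

#' Format / parse interaction identifiers
#'
#' Identifiers follow `"LIGAND_RECEPTOR_CellA|CellB"`. Cluster names may
#' contain spaces; `"|"` separates source from target, and parsing splits
#' the receptor-ligand pair from the cluster pair at the last `"_"`.
#'
#' @param pair Receptor-ligand pair name (e.g. `"NRP1_VEGFA"`).
#' @param source,target Cluster labels.
#' @return `format_interaction_id()`: character id.
#' @export
format_interaction_id <- function(pair, source, target) {
  paste0(pair, "_", source, "|", target)
}

#' @rdname format_interaction_id
#' @param id Identifier string(s).
#' @return `parse_interaction_id()`: data.frame with `pair`, `source`,
#'   `target`.
#' @export
parse_interaction_id <- function(id) {
  us <- regexpr("_[^_]*$", id)
  if (any(us < 0)) stop("identifier without '_' separator")
  pair <- substr(id, 1, us - 1)
  cellpair <- substr(id, us + 1, nchar(id))
  parts <- strsplit(cellpair, "|", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop("identifier without 'A|B' cluster pair")
  data.frame(pair = pair,
             source = vapply(parts, `[`, "", 1),
             target = vapply(parts, `[`, "", 2),
             stringsAsFactors = FALSE)
}

#' Per-condition significant-interaction identifier sets and UpSet regions
#'
#' Assigns each significant entry (p < `alpha`) the identifier
#' `"PAIR_CellA|CellB"` and enumerates every region of the condition Venn
#' (exclusive membership patterns) with exact counts.
#'
#' @param tables_list Named list of [interaction_tables()], one per
#'   condition.
#' @param alpha Significance cutoff.
#' @return List with `ids` (named list of identifier vectors) and `regions`
#'   (data.frame: one row per non-empty membership pattern, logical column
#'   per condition, and `count`).
#' @export
interaction_id_sets <- function(tables_list, alpha = 0.05) {
  if (is.null(names(tables_list))) stop("tables_list must be named by condition")
  ids <- lapply(tables_list, function(tb) {
    stopifnot(inherits(tb, "interaction_tables"))
    sig <- which(tb$pvalues < alpha, arr.ind = TRUE)
    if (!nrow(sig)) return(character(0))
    out <- paste0(rownames(tb$pvalues)[sig[, 1]], "_",
                  colnames(tb$pvalues)[sig[, 2]])
    if (anyDuplicated(out)) stop("duplicate identifiers within condition ",
                                 tb$condition, " (index corruption)")
    sort(out)
  })
  conds <- names(tables_list)
  universe <- sort(unique(unlist(ids)))
  memb <- vapply(ids, function(s) universe %in% s,
                 logical(length(universe)))
  if (length(universe) == 1L) memb <- matrix(memb, nrow = 1,
                                             dimnames = list(NULL, conds))
  pattern <- apply(memb, 1, paste, collapse = ",")
  regions <- NULL
  if (length(universe)) {
    tab <- table(pattern)
    pat <- do.call(rbind, strsplit(names(tab), ","))
    regions <- as.data.frame(pat == "TRUE")
    colnames(regions) <- conds
    regions$count <- as.integer(tab)
  } else {
    regions <- as.data.frame(matrix(logical(0), 0, length(conds),
                                    dimnames = list(NULL, conds)))
    regions$count <- integer(0)
  }
  list(ids = ids, regions = regions)
}

#' Receptor-ligand pairs induced by treatment
#'
#' A receptor-ligand pair is "induced" when the number of distinct
#' significant source|target cluster pairs carrying it increases by at
#' least `min_increase` in the treatment condition relative to control.
#'
#' @param treat_ids,ctrl_ids Identifier vectors (as produced by
#'   [interaction_id_sets()]).
#' @param min_increase Minimum gain in significant cluster-pair count
#'   (default 2).
#' @param means Optional [interaction_tables()] for the treatment
#'   condition; when given, each induced pair is annotated with the mean
#'   expression of its treatment partner columns.
#' @return Data.frame with `pair`, `n_treat`, `n_ctrl`, `increase`,
#'   `partners` (treatment cluster pairs, ";"-joined) and, when `means` is
#'   supplied, `mean_expression`.
#' @export
induced_pairs <- function(treat_ids, ctrl_ids, min_increase = 2, means = NULL) {
  pt <- if (length(treat_ids)) parse_interaction_id(treat_ids) else
    data.frame(pair = character(0), source = character(0), target = character(0))
  pc <- if (length(ctrl_ids)) parse_interaction_id(ctrl_ids) else
    data.frame(pair = character(0), source = character(0), target = character(0))
  nt <- table(pt$pair)
  nc <- table(pc$pair)
  pairs <- sort(unique(pt$pair))
  rows <- lapply(pairs, function(p) {
    n1 <- as.integer(nt[p])
    n0 <- if (p %in% names(nc)) as.integer(nc[p]) else 0L
    if (n1 - n0 < min_increase) return(NULL)
    sel <- pt$pair == p
    partners <- paste0(pt$source[sel], "|", pt$target[sel])
    out <- data.frame(pair = p, n_treat = n1, n_ctrl = n0,
                      increase = n1 - n0,
                      partners = paste(sort(partners), collapse = ";"),
                      stringsAsFactors = FALSE)
    if (!is.null(means) && p %in% rownames(means$means)) {
      cols <- intersect(partners, colnames(means$means))
      out$mean_expression <- if (length(cols))
        mean(means$means[p, cols]) else NA_real_
    }
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- data.frame(pair = character(0), n_treat = integer(0),
                      n_ctrl = integer(0), increase = integer(0),
                      partners = character(0), stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hierarchical row/column ordering for a delta heatmap
#'
#' Average-linkage hierarchical clustering on euclidean distances, applied
#' to rows and columns independently. Constant matrices keep their input
#' order with a warning.
#'
#' @param delta Numeric matrix with at least 2 rows.
#' @return List with `row_order`, `col_order` (integer permutations) and
#'   the `hclust` objects (`row_tree`, `col_tree`, NULL when degenerate).
#' @export
order_delta_heatmap <- function(delta) {
  delta <- as.matrix(delta)
  if (nrow(delta) < 2L) stop("need at least 2 rows")
  one_axis <- function(m) {
    d <- stats::dist(m)
    if (all(d == 0)) return(NULL)
    stats::hclust(d, method = "average")
  }
  rt <- one_axis(delta)
  ct <- if (ncol(delta) >= 2L) one_axis(t(delta)) else NULL
  if (is.null(rt)) warning("constant matrix: input row order retained")
  list(row_order = if (is.null(rt)) seq_len(nrow(delta)) else rt$order,
       col_order = if (is.null(ct)) seq_len(ncol(delta)) else ct$order,
       row_tree = rt, col_tree = ct)
}
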