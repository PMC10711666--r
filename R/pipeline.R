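#' Default demo pipeline configuration
#'
#' Parameters for an end-to-end run over the packaged synthetic fixture:
#' simulation spec, QC thresholds, annotation settings, scoring design,
#' interactome layout, histology and qPCR stages. Every threshold used by
#' the analysis recipe is surfaced here with its default.
#'
#' @param seed Master seed; stage seeds are derived by fixed offsets.
#' @param out_dir Output directory.
#' @return Nested configuration list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("lb_run_")) {
  list(
    seed = seed,
    out_dir = out_dir,
    simulate = list(spec = sc_sim_spec(seed = seed)),
    qc = list(cfg = qc_config()),
    annotate = list(top_n = 200, alpha = 0.05),
    score = list(delta = 0.5, n_cells_per_arm = 1000, n_genes = 400,
                 n_sig = 30, design = c(treated = "control")),
    interactome = list(
      cell_types = c("HSC", "AH", "CHOL", "DC"),
      n_interactions = 40,
      planted = list(control = 3L, treated = 8L),
      alpha = 0.05),
    sirius = list(stain_fractions = c(control = 0.05, treated = 0.30),
                  brightness_factor = 1.0),
    qpcr = list(genes = c("COL1A1", "ACTA2"),
                planted_fold = data.frame(
                  gene = c("COL1A1", "ACTA2"), condition = "treated",
                  fold = c(4, 2), stringsAsFactors = FALSE),
                noise_sd_ct = 0.15)
  )
}

# Append a stage record (with output file hashes) to a manifest list.
manifest_add <- function(manifest, stage, params, outputs) {
  hashes <- as.list(tools::md5sum(outputs))
  names(hashes) <- basename(outputs)
  manifest$stages[[stage]] <- list(parameters = params, outputs = hashes)
  manifest
}

#' Run the demo pipeline end to end
#'
#' Executes simulate -> QC -> marker ranking -> annotation -> signature
#' scoring/severity -> interactome, plus the Sirius-red and qPCR stages,
#' over seeded synthetic inputs, writing each stage's tables under
#' `config$out_dir` and a JSON manifest with parameters and content hashes
#' of every output. Rerunning with the same seed reproduces identical
#' hashes.
#'
#' @param config List from [pipeline_config()].
#' @return The manifest (invisibly also written to `manifest.json`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("liverbench")),
                   seed = config$seed, stages = list())
  seed <- config$seed

  # --- simulate ---------------------------------------------------------
  sim <- make_count_matrix(config$simulate$spec)
  sim_dir <- file.path(out, "counts")
  write_counts_10x(sim$cm, sim_dir)
  truth_path <- file.path(out, "truth_cell_types.tsv")
  utils::write.table(
    data.frame(cell_id = sim$cm$cell_meta$cell_id,
               cell_type = sim$truth$cell_type,
               is_doublet = sim$truth$is_doublet),
    truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- manifest_add(manifest, "simulate",
                           list(seed = config$simulate$spec$seed),
                           c(file.path(sim_dir, "matrix.mtx"), truth_path))

  # --- qc ---------------------------------------------------------------
  flt <- filter_cells_genes(sim$cm, config$qc$cfg)
  qc_path <- file.path(out, "qc_report.json")
  write_qc_report(flt$report, qc_path)
  manifest <- manifest_add(manifest, "qc", unclass(config$qc$cfg), qc_path)

  # --- normalize + rank markers + annotate ------------------------------
  nm <- normalize_log(flt$cm)
  keep <- !flt$cm$gene_meta$is_mito & !flt$cm$gene_meta$is_ribo
  truth_types <- sim$truth$cell_type[match(flt$cm$cell_meta$cell_id,
                                           sim$cm$cell_meta$cell_id)]
  ranked <- wilcoxon_rank_genes(nm$values[, keep, drop = FALSE], truth_types)
  ranked_path <- file.path(out, "ranked_markers.tsv")
  write_ranked_genes(ranked, ranked_path)

  db <- marker_db(sim$truth$marker_sets)
  decisions <- annotate_clusters(ranked, db, background = ncol(nm$values),
                                 top_n = config$annotate$top_n,
                                 alpha = config$annotate$alpha)
  ann_path <- file.path(out, "annotations.tsv")
  utils::write.table(decisions, ann_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- manifest_add(manifest, "annotate", config$annotate,
                           c(ranked_path, ann_path))

  # --- signature scoring + severity ------------------------------------
  sc <- config$score
  shift <- make_signature_shift_matrix(
    n_cells_per_arm = sc$n_cells_per_arm, n_genes = sc$n_genes,
    n_sig = sc$n_sig, delta = sc$delta, seed = seed + 101L)
  sig <- gene_signature("planted_injury", shift$signature)
  scores <- go_score_battery(shift$nm, list(sig), seed = seed + 102L)
  sev <- severity_ratios(scores, sc$design)
  sev_path <- file.path(out, "severity.tsv")
  utils::write.table(sev, sev_path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- manifest_add(manifest, "score",
                           sc[c("delta", "n_cells_per_arm", "n_sig")], sev_path)

  # --- interactome ------------------------------------------------------
  ia <- config$interactome
  prs <- sprintf("LIG%02d_REC%02d", seq_len(ia$n_interactions),
                 seq_len(ia$n_interactions))
  planted <- with_seed(seed + 103L, {
    lapply(ia$planted, function(k) {
      data.frame(pair = sample(prs, k),
                 source = sample(ia$cell_types, k, replace = TRUE),
                 target = sample(ia$cell_types, k, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
  })
  tables <- make_cpdb_tables(ia$cell_types, prs, planted, seed = seed + 104L)
  summaries <- lapply(tables, count_significant, alpha = ia$alpha)
  fd <- fraction_delta(summaries$treated, summaries$control)
  delta_path <- file.path(out, "interactome_delta.tsv")
  utils::write.table(fd$delta, delta_path, sep = "\t", quote = FALSE)
  idsets <- interaction_id_sets(tables, alpha = ia$alpha)
  regions_path <- file.path(out, "interactome_upset.tsv")
  utils::write.table(idsets$regions, regions_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- manifest_add(manifest, "interactome",
                           ia[c("alpha", "n_interactions")],
                           c(delta_path, regions_path))

  # --- sirius -----------------------------------------------------------
  sr <- config$sirius
  sirius_rows <- lapply(seq_along(sr$stain_fractions), function(i) {
    im <- make_histology_image(stain_fraction = sr$stain_fractions[[i]],
                               seed = seed + 200L + i)
    q <- quantify(im$image, brightness_factor = sr$brightness_factor)
    q$sample <- names(sr$stain_fractions)[i]
    q$planted <- sr$stain_fractions[[i]]
    q
  })
  sirius <- do.call(rbind, sirius_rows)
  sirius_path <- file.path(out, "sirius.tsv")
  utils::write.table(sirius, sirius_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- manifest_add(manifest, "sirius", sr["brightness_factor"],
                           sirius_path)

  # --- qpcr -------------------------------------------------------------
  qp <- config$qpcr
  ct <- make_ct_table(qp$genes, planted_fold = qp$planted_fold,
                      noise_sd_ct = qp$noise_sd_ct, seed = seed + 300L)
  folds <- ddct_fold(collapse_and_gate(ct), control = "control")
  folds_path <- file.path(out, "qpcr_folds.tsv")
  utils::write.table(folds, folds_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- manifest_add(manifest, "qpcr", list(noise_sd_ct = qp$noise_sd_ct),
                           folds_path)

  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Human-readable pipeline report
#'
#' Renders the stage tables of a completed [run_pipeline()] output
#' directory into a single text summary; the numbers are read back from
#' the stage TSVs, so the report matches them exactly. Missing stages are
#' marked skipped.
#'
#' @param out_dir Pipeline output directory containing `manifest.json`.
#' @return Character vector of report lines (invisibly); also printed.
#' @export
pipeline_report <- function(out_dir) {
  manifest_path <- file.path(out_dir, "manifest.json")
  if (!file.exists(manifest_path)) stop("no manifest.json in ", out_dir)
  manifest <- jsonlite::read_json(manifest_path)
  lines <- c(sprintf("liverbench pipeline report (seed %s)", manifest$seed), "")
  section <- function(title, path, render) {
    if (!file.exists(path)) return(c(sprintf("## %s: skipped", title), ""))
    c(sprintf("## %s", title), render(path), "")
  }
  lines <- c(lines, section("QC", file.path(out_dir, "qc_report.json"), function(p) {
    r <- jsonlite::read_json(p)
    sprintf("cells %s -> %s; genes %s -> %s", r$cells_before, r$cells_after,
            r$genes_before, r$genes_after)
  }))
  lines <- c(lines, section("Annotation", file.path(out_dir, "annotations.tsv"),
    function(p) {
      d <- utils::read.delim(p)
      sprintf("%s -> %s (adj_p %.3g%s)", d$cluster_id, d$label, d$adj_p,
              ifelse(d$significant, "", ", fallback"))
    }))
  lines <- c(lines, section("Severity", file.path(out_dir, "severity.tsv"),
    function(p) {
      d <- utils::read.delim(p)
      sprintf("%s %s: ratio %.3f, p %.3g %s", d$signature, d$treatment,
              d$ratio_of_means, d$p, d$stars)
    }))
  lines <- c(lines, section("Interactome UpSet",
    file.path(out_dir, "interactome_upset.tsv"), function(p) {
      d <- utils::read.delim(p)
      utils::capture.output(print(d, row.names = FALSE))
    }))
  lines <- c(lines, section("Sirius red", file.path(out_dir, "sirius.tsv"),
    function(p) {
      d <- utils::read.delim(p)
      sprintf("%s: planted %.0f%%, measured %.1f%% per tissue", d$sample,
              100 * d$planted, d$pct_stained_per_tissue)
    }))
  lines <- c(lines, section("qPCR folds", file.path(out_dir, "qpcr_folds.tsv"),
    function(p) {
      d <- utils::read.delim(p)
      agg <- stats::aggregate(fold ~ gene + condition, d, mean)
      sprintf("%s (%s): mean fold %.2f", agg$gene, agg$condition, agg$fold)
    }))
  cat(lines, sep = "\n")
  invisible(lines)
}
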