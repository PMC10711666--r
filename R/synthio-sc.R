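# Run expr with a fixed RNG state, restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Simulation spec for synthetic organoid scRNA-seq counts
#'
#' Defines the conditions emulated by [make_count_matrix()]: a small panel
#' of cell types with planted marker programs, multi-replicate samples per
#' condition, treatment-dependent cell-type proportions and signature
#' shifts, doublets, and mitochondrial/ribosomal content. Defaults emulate
#' a compact organoid experiment (three control and two treated replicates,
#' four cell types, negative-binomial counts) sized to generate in seconds.
#'
#' @param n_cell_types Number of planted cell types.
#' @param markers_per_type Marker genes planted per type.
#' @param marker_fold Mean fold elevation of a marker inside its type (> 1).
#' @param n_genes Total genes (including mito/ribo and signature genes).
#' @param cells_per_sample Cells per replicate sample.
#' @param samples Data.frame with columns `sample_id`, `condition`,
#'   `replicate`.
#' @param base_mean Log-normal location of gene base means (counts).
#' @param dispersion Negative-binomial dispersion (size = 1/dispersion).
#' @param libsize_sigma Log-normal sigma of cell library-size factors.
#' @param mito_gene_count,ribo_gene_count Number of "MT-" and "RPS"/"RPL"
#'   genes.
#' @param high_mito_frac Fraction of cells with boosted mitochondrial
#'   content (emulating damaged cells failing the 20% QC rule).
#' @param mito_boost Mean multiplier for mito genes in those cells.
#' @param doublet_rate Fraction of cells replaced by summed random pairs.
#' @param proportion_by_condition Named list: condition -> cell-type
#'   fraction vector (must sum to 1).
#' @param signature_genes Number of planted signature genes (disjoint from
#'   markers).
#' @param signature_shift Named list: condition -> log-fold shift applied to
#'   signature-gene means in cells of that condition.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return An `sc_sim_spec` list.
#' @export
sc_sim_spec <- function(n_cell_types = 4, markers_per_type = 20,
                        marker_fold = 4, n_genes = 1200,
                        cells_per_sample = 300,
                        samples = data.frame(
                          sample_id = c("ctrl_r1", "ctrl_r2", "ctrl_r3",
                                        "tgfb_r1", "tgfb_r2"),
                          condition = c("control", "control", "control",
                                        "TGFb", "TGFb"),
                          replicate = c(1L, 2L, 3L, 1L, 2L),
                          stringsAsFactors = FALSE),
                        base_mean = 2, dispersion = 0.8,
                        libsize_sigma = 0.25,
                        mito_gene_count = 10, ribo_gene_count = 20,
                        high_mito_frac = 0.03, mito_boost = 40,
                        doublet_rate = 0.05,
                        proportion_by_condition = list(
                          control = c(0.40, 0.30, 0.20, 0.10),
                          TGFb    = c(0.30, 0.25, 0.15, 0.30)),
                        signature_genes = 30,
                        signature_shift = list(TGFb = 0.5),
                        seed = 1L) {
  if (marker_fold <= 1) stop("marker_fold must exceed 1")
  if (markers_per_type * n_cell_types + mito_gene_count + ribo_gene_count +
      signature_genes > n_genes)
    stop("n_genes too small for the requested marker/mito/ribo/signature genes")
  if (doublet_rate < 0 || doublet_rate >= 1) stop("doublet_rate must lie in [0, 1)")
  for (cond in unique(samples$condition)) {
    p <- proportion_by_condition[[cond]]
    if (is.null(p) || length(p) != n_cell_types || abs(sum(p) - 1) > 1e-8)
      stop("proportion_by_condition must give a unit-sum vector of length ",
           n_cell_types, " for condition ", cond)
  }
  structure(as.list(environment()), class = "sc_sim_spec")
}

#' Simulate a count matrix with planted ground truth
#'
#' Negative-binomial counts with log-normal gene means and library-size
#' factors. Marker genes of a cell's type have their mean multiplied by
#' `marker_fold`; signature genes are shifted by `exp(signature_shift)` in
#' the corresponding condition; a `high_mito_frac` share of cells gets
#' boosted mitochondrial means; doublets are formed by summing the counts
#' of two random singlet cells and receive doublet scores in \[0.6, 0.95\]
#' (singlets in \[0, 0.39\]). Fully reproducible from `spec$seed`.
#'
#' @param spec An [sc_sim_spec()].
#' @return List with `cm` (a [count_matrix()]) and `truth` (per-cell
#'   `cell_type`, `is_doublet`, `high_mito`, plus `marker_sets`,
#'   `signature_genes`, and the spec).
#' @export
make_count_matrix <- function(spec = sc_sim_spec()) {
  stopifnot(inherits(spec, "sc_sim_spec"))
  with_seed(spec$seed, {
    n_types <- spec$n_cell_types
    # gene universe: markers, mito, ribo, signature, then filler genes
    marker_sets <- lapply(seq_len(n_types), function(t)
      sprintf("MK%d-%03d", t, seq_len(spec$markers_per_type)))
    names(marker_sets) <- paste0("Type", seq_len(n_types))
    mito_genes <- sprintf("MT-%02d", seq_len(spec$mito_gene_count))
    ribo_genes <- c(sprintf("RPS%02d", seq_len(ceiling(spec$ribo_gene_count / 2))),
                    sprintf("RPL%02d", seq_len(floor(spec$ribo_gene_count / 2))))
    sig_genes <- sprintf("SIG-%03d", seq_len(spec$signature_genes))
    n_filler <- spec$n_genes - length(unlist(marker_sets)) -
      length(mito_genes) - length(ribo_genes) - length(sig_genes)
    filler <- sprintf("FILL-%04d", seq_len(n_filler))
    genes <- c(unlist(marker_sets), mito_genes, ribo_genes, sig_genes, filler)

    gene_mean <- stats::rlnorm(spec$n_genes, meanlog = log(spec$base_mean), sdlog = 1)
    names(gene_mean) <- genes
    # mito/ribo genes are housekeeping-high so fractions are non-trivial
    gene_mean[mito_genes] <- gene_mean[mito_genes] * 4
    gene_mean[ribo_genes] <- gene_mean[ribo_genes] * 4

    n_cells <- nrow(spec$samples) * spec$cells_per_sample
    cell_sample <- rep(spec$samples$sample_id, each = spec$cells_per_sample)
    cell_cond <- rep(spec$samples$condition, each = spec$cells_per_sample)
    cell_repl <- rep(spec$samples$replicate, each = spec$cells_per_sample)
    cell_type <- integer(n_cells)
    for (s in seq_len(nrow(spec$samples))) {
      idx <- which(cell_sample == spec$samples$sample_id[s])
      p <- spec$proportion_by_condition[[spec$samples$condition[s]]]
      cell_type[idx] <- sample.int(n_types, length(idx), replace = TRUE, prob = p)
    }
    libf <- stats::rlnorm(n_cells, 0, spec$libsize_sigma)
    high_mito <- stats::runif(n_cells) < spec$high_mito_frac

    mu <- outer(libf, gene_mean)
    colnames(mu) <- genes
    for (t in seq_len(n_types)) {
      rows <- cell_type == t
      mu[rows, marker_sets[[t]]] <- mu[rows, marker_sets[[t]]] * spec$marker_fold
    }
    for (cond in names(spec$signature_shift)) {
      rows <- cell_cond == cond
      mu[rows, sig_genes] <- mu[rows, sig_genes] * exp(spec$signature_shift[[cond]])
    }
    mu[high_mito, mito_genes] <- mu[high_mito, mito_genes] * spec$mito_boost

    counts <- matrix(stats::rnbinom(length(mu), size = 1 / spec$dispersion, mu = mu),
                     nrow = n_cells, dimnames = list(NULL, genes))

    is_doublet <- rep(FALSE, n_cells)
    n_doub <- round(spec$doublet_rate * n_cells)
    if (n_doub > 0) {
      doub_idx <- sample.int(n_cells, n_doub)
      is_doublet[doub_idx] <- TRUE
      singlets <- which(!is_doublet)
      for (i in doub_idx) {
        pair <- sample(singlets, 2)
        counts[i, ] <- counts[pair[1], ] + counts[pair[2], ]
      }
    }
    dscore <- stats::runif(n_cells, 0, 0.39)
    dscore[is_doublet] <- stats::runif(n_doub, 0.6, 0.95)

    cell_meta <- data.frame(
      cell_id = sprintf("cell%05d", seq_len(n_cells)),
      sample_id = cell_sample, condition = cell_cond,
      replicate = cell_repl, doublet_score = dscore,
      stringsAsFactors = FALSE)
    rownames(counts) <- cell_meta$cell_id
    cm <- count_matrix(counts, cell_meta)
    truth <- list(cell_type = names(marker_sets)[cell_type],
                  is_doublet = is_doublet, high_mito = high_mito,
                  marker_sets = marker_sets, signature_genes = sig_genes,
                  spec = spec)
    list(cm = cm, truth = truth)
  })
}

#' Simulate a normalized matrix with an additive planted signature shift
#'
#' Constructs log-scale expression directly: every gene has a cell-
#' independent baseline level plus Gaussian noise, the signature genes are
#' co-elevated by `baseline` in all cells (injury programs are moderately
#' active already in control organoids, which keeps the ratio-of-means
#' readout well-defined), and shifted by an additional `delta` in treated
#' cells. Because the shift is additive on the scored scale, the expected
#' treated-minus-control difference of the control-matched signature score
#' equals `delta`.
#'
#' @param n_cells_per_arm Cells per arm (control and treated).
#' @param n_genes Total genes.
#' @param n_sig Number of signature genes.
#' @param delta Planted additive shift in treated cells.
#' @param baseline Signature co-elevation planted in both arms.
#' @param noise_sd Per-value Gaussian noise SD.
#' @param seed Integer seed.
#' @return List with `nm` (a [normalized_matrix()] whose `cell_meta` has a
#'   `condition` column with values `"control"`/`"treated"`) and
#'   `signature` (the planted gene names).
#' @export
make_signature_shift_matrix <- function(n_cells_per_arm = 2000, n_genes = 500,
                                        n_sig = 30, delta = 0.5,
                                        baseline = 1.0, noise_sd = 0.2,
                                        seed = 1L) {
  with_seed(seed, {
    n_cells <- 2L * n_cells_per_arm
    genes <- sprintf("G%04d", seq_len(n_genes))
    sig <- sample(genes, n_sig)
    base <- stats::runif(n_genes, 1.5, 4)
    values <- matrix(rep(base, each = n_cells), nrow = n_cells,
                     dimnames = list(NULL, genes))
    values <- values + matrix(stats::rnorm(n_cells * n_genes, 0, noise_sd),
                              nrow = n_cells)
    cond <- rep(c("control", "treated"), each = n_cells_per_arm)
    values[, sig] <- values[, sig] + baseline
    values[cond == "treated", sig] <- values[cond == "treated", sig] + delta
    values[values < 0] <- 0
    nm <- normalized_matrix(values,
                            cell_meta = data.frame(condition = cond,
                                                   stringsAsFactors = FALSE))
    list(nm = nm, signature = sig)
  })
}
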