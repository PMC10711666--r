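#' Simulate receptor-ligand interaction tables with planted significance
#'
#' Builds paired "means"/"pvalues" matrices in the CellPhoneDB v2 layout
#' (rows = receptor-ligand pairs, columns = all ordered "source|target"
#' cluster pairs, self-pairs included) for each condition. Planted entries
#' receive p-values below 0.05 and elevated means; all other entries
#' receive p-values at or above 0.05.
#'
#' @param cell_types Character vector of cluster labels (may contain
#'   spaces).
#' @param interactions Data.frame with columns `ligand`, `receptor`, or a
#'   character vector of pair names already joined with "_".
#' @param planted Named list: condition -> data.frame with columns `pair`,
#'   `source`, `target` marking the entries to plant as significant.
#' @param alpha_noise Log-normal sigma of the mean-expression noise.
#' @param seed Integer seed.
#' @return Named list of `interaction_tables` objects, one per condition.
#' @export
make_cpdb_tables <- function(cell_types, interactions, planted,
                             alpha_noise = 0.25, seed = 1L) {
  pairs <- if (is.data.frame(interactions))
    paste(interactions$ligand, interactions$receptor, sep = "_") else
      as.character(interactions)
  if (anyDuplicated(pairs)) stop("duplicated receptor-ligand pairs")
  cols <- as.vector(t(outer(cell_types, cell_types, paste, sep = "|")))
  with_seed(seed, {
    out <- lapply(names(planted), function(cond) {
      pl <- planted[[cond]]
      pv <- matrix(stats::runif(length(pairs) * length(cols), 0.05, 1),
                   nrow = length(pairs), dimnames = list(pairs, cols))
      mn <- matrix(stats::rlnorm(length(pv), log(0.2), alpha_noise),
                   nrow = length(pairs), dimnames = list(pairs, cols))
      if (!is.null(pl) && nrow(pl)) {
        bad <- !(pl$source %in% cell_types) | !(pl$target %in% cell_types)
        if (any(bad)) stop("planted entry references unknown cluster: ",
                           paste(unique(c(pl$source[bad], pl$target[bad])),
                                 collapse = ", "))
        if (!all(pl$pair %in% pairs)) stop("planted entry references unknown pair")
        for (i in seq_len(nrow(pl))) {
          cc <- paste(pl$source[i], pl$target[i], sep = "|")
          pv[pl$pair[i], cc] <- stats::runif(1, 0, 0.049)
          mn[pl$pair[i], cc] <- stats::rlnorm(1, log(1.5), alpha_noise)
        }
      }
      interaction_tables(means = mn, pvalues = pv, condition = cond,
                         clusters = cell_types)
    })
    names(out) <- names(planted)
    out
  })
}

#' Simulate a Sirius-red-stained organoid image with truth masks
#'
#' Renders elliptical tissue regions (darker than the near-white background
#' in the blue channel) on an 8-bit RGB canvas. Within tissue, an exact
#' `stain_fraction` of pixels is drawn with a strongly suppressed green
#' channel (collagen-stain-like), a `vacuole_fraction` of intra-organoid
#' pixels is punched back to background, and `artifact_count` near-black
#' blobs are placed outside tissue. Per-pixel truth masks are returned.
#'
#' @param width_px,height_px Canvas size in pixels.
#' @param um_per_px Physical scale (micrometers per pixel).
#' @param n_organoids Number of elliptical tissue regions.
#' @param tissue_color RGB triple of unstained tissue.
#' @param stain_color RGB triple of stained tissue (low green).
#' @param nuclei_color RGB triple of counterstained nuclei (hematoxylin-like:
#'   low green, tissue-like blue).
#' @param stain_fraction Fraction of tissue pixels stained, in \[0, 1\].
#' @param nuclei_fraction Fraction of unstained tissue pixels drawn as
#'   nuclei.
#' @param vacuole_fraction Fraction of intra-organoid pixels rendered as
#'   background (stain-free holes), in \[0, 1\].
#' @param artifact_count Number of near-black artifact blobs.
#' @param noise_sd Gaussian pixel noise SD (8-bit units).
#' @param seed Integer seed.
#' @return List with `image` (an `rgb_image`) and `truth` (logical matrices
#'   `tissue`, `stain`, `artifact`).
#' @export
make_histology_image <- function(width_px = 256, height_px = 256,
                                 um_per_px = 1.0, n_organoids = 3,
                                 tissue_color = c(200, 170, 140),
                                 stain_color = c(190, 50, 120),
                                 nuclei_color = c(80, 60, 130),
                                 stain_fraction = 0.2,
                                 nuclei_fraction = 0.005,
                                 vacuole_fraction = 0.05,
                                 artifact_count = 0, noise_sd = 3,
                                 seed = 1L) {
  if (stain_fraction < 0 || stain_fraction > 1 ||
      vacuole_fraction < 0 || vacuole_fraction > 1)
    stop("fractions must lie in [0, 1]")
  with_seed(seed, {
    H <- height_px; W <- width_px
    px_y <- matrix(rep(seq_len(H), W), nrow = H)
    px_x <- matrix(rep(seq_len(W), each = H), nrow = H)
    inside <- matrix(FALSE, H, W)
    for (i in seq_len(n_organoids)) {
      cx <- stats::runif(1, 0.25 * W, 0.75 * W)
      cy <- stats::runif(1, 0.25 * H, 0.75 * H)
      rx <- stats::runif(1, 0.22, 0.38) * W
      ry <- stats::runif(1, 0.22, 0.38) * H
      inside <- inside | (((px_x - cx) / rx)^2 + ((px_y - cy) / ry)^2 <= 1)
    }
    # punch vacuoles: small discs inside organoids reverted to background
    vac <- matrix(FALSE, H, W)
    if (vacuole_fraction > 0) {
      target <- vacuole_fraction * sum(inside)
      guard <- 0
      while (sum(vac & inside) < target && guard < 200) {
        guard <- guard + 1
        idx <- which(inside & !vac)
        if (!length(idx)) break
        ctr <- idx[sample.int(length(idx), 1)]
        cy <- (ctr - 1) %% H + 1; cx <- (ctr - 1) %/% H + 1
        r <- stats::runif(1, 2, 0.06 * min(H, W))
        vac <- vac | ((px_x - cx)^2 + (px_y - cy)^2 <= r^2)
      }
    }
    tissue <- inside & !vac

    stain <- matrix(FALSE, H, W)
    n_stain <- round(stain_fraction * sum(tissue))
    if (n_stain > 0) {
      idx <- which(tissue)
      stain[idx[sample.int(length(idx), n_stain)]] <- TRUE
    }
    nuclei <- matrix(FALSE, H, W)
    n_nuc <- round(nuclei_fraction * sum(tissue & !stain))
    if (n_nuc > 0) {
      idx <- which(tissue & !stain)
      nuclei[idx[sample.int(length(idx), n_nuc)]] <- TRUE
    }

    img <- array(252, dim = c(H, W, 3))
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[tissue] <- tissue_color[ch]
      plane[stain] <- stain_color[ch]
      plane[nuclei] <- nuclei_color[ch]
      img[, , ch] <- plane
    }

    artifact <- matrix(FALSE, H, W)
    placed <- 0
    guard <- 0
    while (placed < artifact_count && guard < 1000) {
      guard <- guard + 1
      cx <- stats::runif(1, 3, W - 3); cy <- stats::runif(1, 3, H - 3)
      r <- stats::runif(1, 2, 5)
      blob <- (px_x - cx)^2 + (px_y - cy)^2 <= r^2
      # keep blobs clear of tissue and of each other so components stay distinct
      near <- (px_x - cx)^2 + (px_y - cy)^2 <= (r + 3)^2
      if (any(blob & inside) || any(near & artifact)) next
      artifact <- artifact | blob
      placed <- placed + 1
    }
    if (placed < artifact_count)
      warning("placed only ", placed, " of ", artifact_count, " artifacts")
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[artifact] <- stats::runif(sum(artifact), 0, 20)
      img[, , ch] <- plane
    }

    if (noise_sd > 0) {
      keep_black <- array(rep(artifact, 3), dim = dim(img))
      noise <- array(stats::rnorm(length(img), 0, noise_sd), dim = dim(img))
      noise[keep_black] <- 0
      img <- img + noise
    }
    img <- round(pmin(pmax(img, 0), 255))
    list(image = rgb_image(img, um_per_px),
         truth = list(tissue = tissue, stain = stain, nuclei = nuclei,
                      artifact = artifact))
  })
}

#' Simulate a qPCR Ct plate with planted fold changes
#'
#' Three technical replicates per sample x gene. A planted fold `f` for a
#' gene in a condition is realized as a Ct offset of `-log2(f)` relative to
#' the control mean; the housekeeping gene sits near Ct 20. With
#' `noise_sd_ct = 0` the downstream delta-delta-Ct estimate recovers the
#' planted folds exactly.
#'
#' @param genes Target gene names (housekeeping gene added separately).
#' @param housekeeping_gene Housekeeping gene name.
#' @param groups Named integer vector: condition -> number of biological
#'   replicates.
#' @param planted_fold Data.frame with columns `gene`, `condition`, `fold`
#'   (fold > 0); unlisted combinations default to fold 1.
#' @param noise_sd_ct Gaussian Ct noise SD (applied per technical
#'   replicate).
#' @param tech_reps Technical replicates per sample x gene (default 3).
#' @param seed Integer seed.
#' @return A `ct_table`: data.frame `sample_id, condition, gene, tech_rep,
#'   ct` with the housekeeping gene stored in the `"housekeeping"`
#'   attribute.
#' @export
make_ct_table <- function(genes, housekeeping_gene = "ACTB",
                          groups = c(control = 3, treated = 3),
                          planted_fold = NULL, noise_sd_ct = 0.15,
                          tech_reps = 3, seed = 1L) {
  if (!is.null(planted_fold) && any(planted_fold$fold <= 0))
    stop("planted fold values must be positive")
  with_seed(seed, {
    base_ct <- stats::runif(length(genes), 24, 28)
    names(base_ct) <- genes
    rows <- list()
    for (cond in names(groups)) {
      for (r in seq_len(groups[[cond]])) {
        sid <- sprintf("%s_b%d", cond, r)
        for (g in c(housekeeping_gene, genes)) {
          level <- if (g == housekeeping_gene) 20 else {
            f <- 1
            if (!is.null(planted_fold)) {
              hit <- planted_fold$gene == g & planted_fold$condition == cond
              if (any(hit)) f <- planted_fold$fold[which(hit)[1]]
            }
            base_ct[g] - log2(f)
          }
          ct <- level + stats::rnorm(tech_reps, 0, noise_sd_ct)
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sid, condition = cond, gene = g,
            tech_rep = seq_len(tech_reps), ct = ct,
            stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "housekeeping") <- housekeeping_gene
    class(out) <- c("ct_table", "data.frame")
    out
  })
}

#' Write / read a Ct table as CSV
#'
#' Columns `sample_id, condition, gene, tech_rep, ct`; the housekeeping
#' gene travels in a `# housekeeping:` comment header line.
#'
#' @param ct A `ct_table`.
#' @param path CSV path.
#' @export
write_ct_table <- function(ct, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# housekeeping: ", attr(ct, "housekeeping")), con)
  utils::write.csv(as.data.frame(ct), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ct_table
#' @export
read_ct_table <- function(path) {
  first <- readLines(path, n = 1)
  hk <- sub("^# housekeeping:\\s*", "", first)
  out <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  attr(out, "housekeeping") <- hk
  class(out) <- c("ct_table", "data.frame")
  out
}
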