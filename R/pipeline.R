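# End-to-end orchestration: simulate -> segment -> quantify -> report.

#' Analyze every cell in a multi-channel stack
#'
#' Max-projects the stack, segments cells from phase contrast, and computes
#' the full per-cell quantification: thresholds, cluster counts, backbone
#' topology and morphometry, MukB cluster Feret diameter, intensity-overlap
#' colocalization, compaction ratio, ori/ter foci with QC, arm asymmetry of
#' DNA and MukB, and DNA sum signal. Cells with more ter than ori foci are
#' marked `discarded`; metrics whose channels are missing stay NA.
#'
#' @param stack an [mcstack()] with a `phase` channel and any subset of
#'   dna, mukb, ori, ter.
#' @param config an [imaging_config()].
#' @param strain_label label copied into every row.
#' @return data.frame, one row per segmented cell (see [write_results()]
#'   for the column order).
#' @export
analyze_stack <- function(stack, config = imaging_config(),
                          strain_label = NA_character_) {
  stopifnot(inherits(stack, "mcstack"))
  proj <- max_project(stack)
  px <- proj$pixel_size_um
  phase <- channel_frame(proj, "phase")
  if (is.null(phase)) stop("phase channel required for segmentation")
  seg <- segment_cells(phase)
  psf_fwhm_px <- config$psf_fwhm_lateral_um / px
  have <- function(nm) !is.null(proj$channels[[nm]])
  for (nm in c("dna", "mukb", "ori", "ter"))
    if (!have(nm)) warning("channel '", nm, "' missing: dependent metrics NA")
  rows <- vector("list", seg$n)
  pad <- 6L
  H <- nrow(phase); W <- ncol(phase)
  for (i in seq_len(max(seg$n, 0L))) {
    info <- seg$cells[i, ]
    rs <- max(1L, info$rmin - pad):min(H, info$rmax + pad)
    cs <- max(1L, info$cmin - pad):min(W, info$cmax + pad)
    cell <- seg$labels[rs, cs] == i
    crop <- function(nm) if (have(nm)) channel_frame(proj, nm)[rs, cs] else NULL
    row <- list(cell_id = i, strain_label = strain_label,
                qc_flag = info$qc_flag, discarded = FALSE, anucleate = FALSE,
                multi_ori = FALSE, area_px = info$area_px,
                dna_threshold = NA_real_, mukb_threshold = NA_real_,
                dna_in_mukb_percent = NA_real_, mukb_in_dna_percent = NA_real_,
                ori_overlaps_mukb = NA, ter_overlaps_mukb = NA,
                compaction_ratio = NA_real_, contour_length_um = NA_real_,
                width_fwhm_um = NA_real_, width_stations = NA_integer_,
                mukb_feret_um = NA_real_, dna_cluster_count = NA_integer_,
                mukb_cluster_count = NA_integer_, topology = NA_character_,
                cycle_count = NA_integer_, branch_nodes = NA_integer_,
                ori_count = NA_integer_, ter_count = NA_integer_,
                asym_dna = NA_real_, asym_mukb = NA_real_,
                sum_dna_intensity = NA_real_, normalized_sum = NA_real_,
                multiplicity_class = NA_character_,
                com_x = NA_real_, com_y = NA_real_,
                ori_x = NA_real_, ori_y = NA_real_)
    dna <- crop("dna"); mukb <- crop("mukb")
    dna_th <- mukb_th <- NULL
    if (!is.null(dna)) {
      dna_th <- threshold_channel(dna, cell,
                                  smooth_sigma_px = config$smooth_sigma_px)
      row$dna_threshold <- dna_th$threshold
      row$sum_dna_intensity <- sum(dna_th$image_raw_bgsub[cell])
      dcl <- label_clusters(dna_th, min_area_px = config$min_cluster_px)
      row$dna_cluster_count <- dcl$n
      bb <- suppressWarnings(extract_backbone(dna_th))
      row$topology <- classify_topology(bb)
      row$cycle_count <- bb$cycle_count
      row$branch_nodes <- bb$branch_nodes
      row$contour_length_um <- contour_length(bb, px)
      wf <- width_fwhm(bb, dna_th$image_raw_bgsub, px)
      row$width_fwhm_um <- wf$width_fwhm_um
      row$width_stations <- wf$n_stations
      com <- tryCatch(center_of_mass(dna_th$image_raw_bgsub, cell),
                      error = function(e) NULL)
      if (!is.null(com)) { row$com_x <- com[1L]; row$com_y <- com[2L] }
    }
    if (!is.null(mukb)) {
      mukb_th <- threshold_channel(mukb, cell,
                                   smooth_sigma_px = config$smooth_sigma_px)
      row$mukb_threshold <- mukb_th$threshold
      mcl <- label_clusters(mukb_th, min_area_px = config$min_cluster_px)
      row$mukb_cluster_count <- mcl$n
      if (mcl$n > 0L) {
        big <- which.max(mcl$clusters$area_px)
        row$mukb_feret_um <- feret_diameter(
          which(mcl$labels == big, arr.ind = TRUE)[, c(2L, 1L)], px)
      }
    }
    if (!is.null(dna_th) && !is.null(mukb_th)) {
      row$dna_in_mukb_percent <-
        as.numeric(intensity_overlap_fraction(dna_th$image_raw_bgsub,
                                              mukb_th$mask, cell))
      row$mukb_in_dna_percent <-
        as.numeric(intensity_overlap_fraction(mukb_th$image_raw_bgsub,
                                              dna_th$mask, cell))
      cr <- compaction_ratio(dna_th$image_raw_bgsub, dna_th$mask, mukb_th$mask)
      row$compaction_ratio <- cr$ratio
    }
    ori_f <- ter_f <- NULL
    if (have("ori")) {
      ori_f <- detect_foci(crop("ori"), cell, channel = "ori",
                           smooth_sigma_px = config$smooth_sigma_px)
      row$ori_count <- nrow(ori_f)
    }
    if (have("ter")) {
      ter_f <- detect_foci(crop("ter"), cell, channel = "ter",
                           smooth_sigma_px = config$smooth_sigma_px)
      row$ter_count <- nrow(ter_f)
    }
    if (!is.null(ori_f) && !is.null(ter_f)) {
      qc <- qc_foci(ori_f, ter_f)
      row$discarded <- !qc$keep
      row$anucleate <- qc$anucleate
    }
    if (!is.null(mukb_th)) {
      if (!is.null(ori_f) && nrow(ori_f) > 0L)
        row$ori_overlaps_mukb <- any(vapply(seq_len(nrow(ori_f)), function(k)
          focus_overlaps_mask(ori_f[k, ], mukb_th$mask, psf_fwhm_px),
          logical(1L)))
      if (!is.null(ter_f) && nrow(ter_f) > 0L)
        row$ter_overlaps_mukb <- any(vapply(seq_len(nrow(ter_f)), function(k)
          focus_overlaps_mask(ter_f[k, ], mukb_th$mask, psf_fwhm_px),
          logical(1L)))
    }
    if (!is.null(ori_f) && nrow(ori_f) > 0L && !is.na(row$com_x)) {
      best <- which.max(ori_f$peak_intensity)
      row$multi_ori <- nrow(ori_f) > 1L
      ori_pt <- c(ori_f$x[best], ori_f$y[best])
      row$ori_x <- ori_pt[1L]; row$ori_y <- ori_pt[2L]
      com <- c(row$com_x, row$com_y)
      if (sqrt(sum((ori_pt - com)^2)) > 1e-6) {
        if (!is.null(dna_th)) {
          a <- asymmetricity(dna_th$image_raw_bgsub, ori_pt, com,
                             config$roi_diameter_px)
          row$asym_dna <- a$A
        }
        if (!is.null(mukb_th)) {
          a <- asymmetricity(mukb_th$image_raw_bgsub, ori_pt, com,
                             config$roi_diameter_px)
          row$asym_mukb <- a$A
        }
      } else row$qc_flag <- "ori_at_com"
    }
    # report positions in full-frame coordinates
    off_x <- cs[1L] - 1L; off_y <- rs[1L] - 1L
    for (f in c("com_x", "ori_x")) if (!is.na(row[[f]])) row[[f]] <- row[[f]] + off_x
    for (f in c("com_y", "ori_y")) if (!is.na(row[[f]])) row[[f]] <- row[[f]] + off_y
    rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- if (seg$n > 0L) do.call(rbind, rows) else
    stats::setNames(data.frame(matrix(ncol = length(results_columns()),
                                      nrow = 0L)), results_columns())
  # ploidy: needs 1-ori/1-ter reference cells
  ok <- !(out$discarded %in% TRUE)
  ns <- tryCatch(normalized_sum_signal(out$sum_dna_intensity[ok],
                                       out$ori_count[ok], out$ter_count[ok]),
                 error = function(e) {
                   warning(conditionMessage(e)); NULL
                 })
  if (!is.null(ns)) {
    out$normalized_sum[ok] <- ns
    out$multiplicity_class[ok] <- classify_multiplicity(
      out$ori_count[ok], out$ter_count[ok], out$normalized_sum[ok])
  }
  out
}

#' Run the full pipeline from a configuration
#'
#' Configuration (YAML file or list) names the inputs and parameters:
#' \describe{
#'   \item{images}{list of entries with `path` (TIFF readable by
#'     [read_stack()]) and `strain_label`; or}
#'   \item{fixture_dir}{directory holding a `manifest.json` written by
#'     [write_fixture_suite()] -- every fixture image is analyzed with its
#'     fixture name as strain label; or}
#'   \item{simulate}{list with `strains` (preset names), `n_per_strain`,
#'     `seed` -- populations are generated in memory and analyzed.}
#'   \item{params}{overrides for [imaging_config()].}
#'   \item{output_dir}{where results.csv, the echoed configuration, and the
#'     report are written (optional; no files written when absent).}
#' }
#' Every parameter and seed is echoed into `run_config.json`; rerunning the
#' same configuration reproduces the CSV bit for bit.
#'
#' @param config path to a YAML file or a list.
#' @return the results data.frame (non-discarded cells), invisibly; also
#'   written to `output_dir/results.csv` when requested.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- do.call(imaging_config, if (is.null(config$params)) list() else
    config$params)
  results <- list()
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    seed <- if (is.null(sim$seed)) 1L else as.integer(sim$seed)
    n <- if (is.null(sim$n_per_strain)) 25L else as.integer(sim$n_per_strain)
    for (s in sim$strains) {
      pop <- render_population(rep(list(strain_preset(s)), n), layout = "grid",
                               seed = seed)
      results[[length(results) + 1L]] <-
        analyze_stack(pop$stack, cfg, strain_label = s)
      seed <- seed + 1000L
    }
  }
  if (!is.null(config$fixture_dir)) {
    manifest <- jsonlite::read_json(
      file.path(config$fixture_dir, "manifest.json"), simplifyVector = FALSE)
    for (nm in names(manifest$fixtures)) {
      stack <- read_stack(file.path(config$fixture_dir,
                                    manifest$fixtures[[nm]]$image))
      results[[length(results) + 1L]] <-
        analyze_stack(stack, cfg, strain_label = nm)
    }
  }
  if (!is.null(config$images)) {
    for (im in config$images) {
      stack <- read_stack(im$path, channel_map = im$channel_map,
                          pixel_size_um = im$pixel_size_um)
      results[[length(results) + 1L]] <-
        analyze_stack(stack, cfg, strain_label = im$strain_label)
    }
  }
  if (length(results) == 0L) stop("configuration names no inputs")
  res <- do.call(rbind, results)
  res <- res[!(res$discarded %in% TRUE), , drop = FALSE]
  res$cell_id <- seq_len(nrow(res))
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_results(res, file.path(config$output_dir, "results.csv"), cfg)
    jsonlite::write_json(config, file.path(config$output_dir, "run_config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_report(res, config$output_dir)
  }
  invisible(res)
}

#' Write the population report
#'
#' Markdown summary plus CSV tables (and histogram figures when a PNG
#' device is available), all regenerated from the results table alone.
#'
#' @param results per-cell results data.frame (or path to a results CSV).
#' @param outdir output directory.
#' @param figures write PNG histograms per metric and strain.
#' @return the [summarize_population()] report, invisibly.
#' @export
write_report <- function(results, outdir, figures = TRUE) {
  if (is.character(results)) results <- read_results(results)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  rep <- summarize_population(results)
  utils::write.csv(rep$summary, file.path(outdir, "summary.csv"),
                   row.names = FALSE)
  if (!is.null(rep$anova))
    utils::write.csv(rep$anova, file.path(outdir, "anova.csv"),
                     row.names = FALSE)
  md <- c("# Population report", "",
          "## Metric summaries (per strain)", "```",
          utils::capture.output(print(rep$summary, row.names = FALSE)), "```")
  if (!is.null(rep$binary))
    md <- c(md, "", "## Binary colocalization", "```",
            utils::capture.output(print(rep$binary, row.names = FALSE)), "```")
  if (!is.null(rep$anova))
    md <- c(md, "", "## One-way ANOVA across strains", "```",
            utils::capture.output(print(rep$anova, row.names = FALSE)), "```")
  writeLines(md, file.path(outdir, "report.md"))
  if (figures && capabilities("png")) {
    for (m in unique(rep$summary$metric)) {
      ok <- tryCatch({
        grDevices::png(file.path(outdir, paste0("hist_", m, ".png")),
                       width = 640, height = 480)
        groups <- unique(results$strain_label)
        v <- results[[m]][!is.na(results[[m]])]
        if (length(v)) {
          graphics::par(mfrow = c(1, length(groups)))
          for (g in groups) {
            vg <- results[[m]][results$strain_label == g]
            vg <- vg[!is.na(vg)]
            if (length(vg))
              graphics::hist(vg, main = paste(m, "-", g), xlab = m,
                             col = "grey80", border = "white")
          }
        }
        TRUE
      }, error = function(e) FALSE)
      try(grDevices::dev.off(), silent = TRUE)
      if (!ok) break
    }
  }
  invisible(rep)
}
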