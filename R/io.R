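# Image stacks, results tables, and genomic peak files.

#' Multi-channel image stack
#'
#' Container for one field of view: named per-channel z-stacks with physical
#' calibration. Channels are stored as H x W x Z arrays sharing one shape.
#'
#' @param channels named list of matrices (z = 1) or H x W x Z arrays;
#'   typical names: phase, dna, mukb, ori, ter (any subset).
#' @param pixel_size_um lateral pixel size in um; must be > 0.
#' @param z_step_um axial step in um (default 0.227).
#' @return object of class `mcstack` with fields `channels`, `pixel_size_um`,
#'   `z_step_um`, `z_slices`.
#' @export
mcstack <- function(channels, pixel_size_um, z_step_um = 0.227) {
  stopifnot(is.list(channels), length(channels) > 0,
            !is.null(names(channels)))
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a positive number")
  channels <- lapply(channels, function(ch) {
    if (is.matrix(ch)) ch <- array(ch, dim = c(dim(ch), 1L))
    stopifnot(length(dim(ch)) == 3L)
    ch
  })
  dims <- lapply(channels, dim)
  if (!all(vapply(dims, identical, logical(1L), dims[[1L]])))
    stop("all channels must share the same dimensions")
  if (dims[[1L]][3L] < 1L || dims[[1L]][3L] > 19L)
    stop("z_slices must be between 1 and 19")
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um, z_slices = dims[[1L]][3L]),
            class = "mcstack")
}

#' @export
print.mcstack <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("mcstack: %d x %d px, %d z-slice(s), %.3f um/px\n",
              d[1L], d[2L], x$z_slices, x$pixel_size_um))
  cat("channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

# Single 2-D frame of a channel (max-projected if needed).
channel_frame <- function(stack, name) {
  ch <- stack$channels[[name]]
  if (is.null(ch)) return(NULL)
  if (dim(ch)[3L] == 1L) ch[, , 1L] else apply(ch, c(1L, 2L), max)
}

#' Write a stack as multi-page TIFF with a JSON calibration sidecar
#'
#' Pages are ordered channel-major, z within channel, at 32-bit depth.
#' Intensities are stored divided by a per-channel power-of-two scale (kept
#' in the sidecar `<path>.json`). Channels holding integer photon counts are
#' flagged in the sidecar and re-rounded on read, so they round-trip
#' bit-exactly; continuous-valued channels round-trip to within the 32-bit
#' quantization (relative error < 1e-9).
#'
#' @param stack an [mcstack()].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "mcstack"))
  pages <- list(); scales <- numeric(0); offsets <- numeric(0)
  integer_ch <- logical(0)
  for (nm in names(stack$channels)) {
    ch <- stack$channels[[nm]]
    off <- min(ch, 0)                      # read noise can dip below zero
    scale <- 2^ceiling(log2(max(max(ch) - off, 1)))
    scales[nm] <- scale; offsets[nm] <- off
    integer_ch[nm] <- off == 0 && all(ch == round(ch))
    for (z in seq_len(dim(ch)[3L]))
      pages[[length(pages) + 1L]] <- (ch[, , z] - off) / scale
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  sidecar <- list(pixel_size_um = stack$pixel_size_um,
                  z_step_um = stack$z_step_um, z_slices = stack$z_slices,
                  channel_names = names(stack$channels),
                  channel_scales = as.list(scales),
                  channel_offsets = as.list(offsets),
                  channel_integer = as.list(integer_ch))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-channel TIFF stack
#'
#' Reads a multi-page TIFF written by [write_stack()] (calibration and
#' channel layout taken from the JSON sidecar) or a foreign multi-page TIFF,
#' in which case `channel_map` must assign pages to channels and
#' `pixel_size_um` must be supplied explicitly -- a missing calibration is an
#' error, never a silent default.
#'
#' @param path TIFF file.
#' @param channel_map named list mapping channel name to page indices (one
#'   index per z-slice); ignored when a sidecar is present.
#' @param pixel_size_um,z_step_um calibration overrides.
#' @return an [mcstack()].
#' @export
read_stack <- function(path, channel_map = NULL, pixel_size_um = NULL,
                       z_step_um = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    if (is.null(pixel_size_um)) pixel_size_um <- sc$pixel_size_um
    if (is.null(z_step_um)) z_step_um <- sc$z_step_um
    nz <- sc$z_slices
    channels <- list()
    for (i in seq_along(sc$channel_names)) {
      nm <- sc$channel_names[i]
      idx <- (i - 1L) * nz + seq_len(nz)
      arr <- array(0, dim = c(dim(pages[[1L]]), nz))
      off <- if (is.null(sc$channel_offsets[[nm]])) 0 else
        sc$channel_offsets[[nm]]
      for (z in seq_len(nz)) arr[, , z] <- pages[[idx[z]]] *
          sc$channel_scales[[nm]] + off
      if (isTRUE(sc$channel_integer[[nm]])) arr <- round(arr)
      channels[[nm]] <- arr
    }
  } else {
    if (is.null(channel_map))
      stop("no sidecar found; supply channel_map naming each page")
    channels <- lapply(channel_map, function(idx) {
      if (any(idx < 1L | idx > length(pages)))
        stop("channel_map page index out of range for ", path)
      arr <- array(0, dim = c(dim(pages[[1L]]), length(idx)))
      for (z in seq_along(idx)) {
        if (!identical(dim(pages[[idx[z]]]), dim(pages[[1L]])))
          stop("page shape mismatch across channels in ", path)
        arr[, , z] <- pages[[idx[z]]]
      }
      arr
    })
  }
  if (is.null(pixel_size_um))
    stop("pixel size not present in metadata and not supplied; ",
         "pass pixel_size_um explicitly")
  if (is.null(z_step_um)) z_step_um <- 0.227
  mcstack(channels, pixel_size_um = pixel_size_um, z_step_um = z_step_um)
}

#' Maximum-intensity projection
#'
#' Per pixel, per channel maximum over z. Idempotent; a 1-slice stack is
#' returned unchanged in content.
#'
#' @param stack an [mcstack()].
#' @return an `mcstack` with `z_slices = 1`.
#' @export
max_project <- function(stack) {
  stopifnot(inherits(stack, "mcstack"))
  channels <- lapply(stack$channels, function(ch) {
    if (dim(ch)[3L] == 1L) ch[, , 1L] else apply(ch, c(1L, 2L), max)
  })
  mcstack(channels, pixel_size_um = stack$pixel_size_um,
          z_step_um = stack$z_step_um)
}

#' Imaging configuration
#'
#' Physical and analysis constants: 0.065 um pixels, a 20 px (= 1.3 um)
#' asymmetry ROI diameter, the raw widefield PSF (FWHM 0.35 um lateral /
#' 0.80 um axial), and the significance thresholds used for star annotation.
#'
#' @param pixel_size_um,roi_diameter_px,psf_fwhm_lateral_um,psf_fwhm_axial_um
#'   overrides of the defaults.
#' @param smooth_sigma_px Gaussian smoothing sigma for thresholding, px.
#' @param min_cluster_px minimum cluster area kept by [label_clusters()].
#' @param significance_thresholds star thresholds, most to least stringent.
#' @return list of class `imaging_config`.
#' @export
imaging_config <- function(pixel_size_um = 0.065, roi_diameter_px = 20L,
                           psf_fwhm_lateral_um = 0.35,
                           psf_fwhm_axial_um = 0.80,
                           smooth_sigma_px = 1,
                           min_cluster_px = 4L,
                           significance_thresholds =
                             c(0.05, 0.01, 0.001, 0.0001)) {
  structure(list(pixel_size_um = pixel_size_um,
                 roi_diameter_px = as.integer(roi_diameter_px),
                 psf_fwhm_lateral_um = psf_fwhm_lateral_um,
                 psf_fwhm_axial_um = psf_fwhm_axial_um,
                 smooth_sigma_px = smooth_sigma_px,
                 min_cluster_px = as.integer(min_cluster_px),
                 significance_thresholds = significance_thresholds),
            class = "imaging_config")
}

# Stable, documented column order of the per-cell results table.
results_columns <- function() c(
  "cell_id", "strain_label", "qc_flag", "discarded", "anucleate",
  "multi_ori", "area_px", "dna_threshold", "mukb_threshold",
  "dna_in_mukb_percent", "mukb_in_dna_percent", "ori_overlaps_mukb",
  "ter_overlaps_mukb", "compaction_ratio", "contour_length_um",
  "width_fwhm_um", "width_stations", "mukb_feret_um", "dna_cluster_count",
  "mukb_cluster_count", "topology", "cycle_count", "branch_nodes",
  "ori_count", "ter_count", "asym_dna", "asym_mukb", "sum_dna_intensity",
  "normalized_sum", "multiplicity_class", "com_x", "com_y", "ori_x", "ori_y")

#' Write / read the per-cell results table
#'
#' CSV with a stable column order plus a JSON sidecar holding the analysis
#' configuration. Numeric fields are written with 17 significant digits so a
#' write-read round trip preserves them to full double precision.
#'
#' @param table data.frame, one row per cell.
#' @param path output CSV path.
#' @param config optional [imaging_config()] echoed into `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path, config = NULL) {
  cols <- c(intersect(results_columns(), names(table)),
            setdiff(names(table), results_columns()))
  out <- table[, cols, drop = FALSE]
  for (j in seq_along(out)) if (is.numeric(out[[j]]))
    out[[j]] <- vapply(out[[j]], function(v)
      if (is.na(v)) "" else format(v, digits = 17, scientific = FALSE),
      character(1L))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  if (!is.null(config))
    jsonlite::write_json(unclass(config), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a BED peak file on a circular genome
#'
#' Accepts 3+ whitespace-separated columns (chrom, start, end, ...); extra
#' columns are ignored. Coordinates are 0-based half-open. An interval with
#' `end <= start` is interpreted as wrapping through the coordinate origin;
#' `end == start` (empty) is rejected. Genome length and ori position must
#' be given explicitly -- the circular arithmetic has no defaults.
#'
#' @param path BED file.
#' @param genome_length_bp circular genome length, bp.
#' @param ori_position_bp position of oriC, bp, in `[0, genome_length_bp)`.
#' @return data.frame of class `peak_set` with columns start, end and
#'   attributes `genome_length_bp`, `ori_position_bp`.
#' @export
read_peaks <- function(path, genome_length_bp, ori_position_bp) {
  stopifnot(is.numeric(genome_length_bp), genome_length_bp > 0,
            is.numeric(ori_position_bp),
            ori_position_bp >= 0, ori_position_bp < genome_length_bp)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|track|browser|$)", lines)]
  starts <- ends <- numeric(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(f) < 3L)
      stop("malformed BED line ", i, ": fewer than 3 columns")
    s <- suppressWarnings(as.numeric(f[2L])); e <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(s) || is.na(e))
      stop("malformed BED line ", i, ": non-numeric coordinates")
    if (s < 0 || s >= genome_length_bp || e < 0 || e > genome_length_bp)
      stop("malformed BED line ", i, ": coordinates outside the genome")
    if (e == s) stop("malformed BED line ", i, ": empty interval")
    starts[i] <- s; ends[i] <- e
  }
  structure(data.frame(start = starts, end = ends),
            genome_length_bp = genome_length_bp,
            ori_position_bp = ori_position_bp,
            class = c("peak_set", "data.frame"))
}
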