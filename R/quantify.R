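# Colocalization (intensity overlap and binary foci), compaction ratio, and
# focus detection/counting.

#' Detect diffraction-limited foci
#'
#' Local maxima on the smoothed image above a noise-aware threshold. Peaks
#' closer than `min_sep_px` are merged keeping the brighter; centers are
#' refined to sub-pixel precision by an intensity-weighted centroid in a
#' 5 x 5 window. Zero foci is a valid result.
#'
#' @param image 2-D focus-channel matrix.
#' @param cellmask [segment_cells()] result or logical matrix.
#' @param cell_id cell label (ignored for a logical mask).
#' @param smooth_sigma_px smoothing sigma, px.
#' @param min_sep_px minimum peak separation, px.
#' @param threshold absolute intensity threshold on the smoothed,
#'   background-subtracted scale; default `max(5 * mad, 0.2 * peak range)`
#'   of the in-cell pixels.
#' @param channel label stored with the result ("ori" or "ter").
#' @return data.frame of class `foci_set`: columns x, y (sub-pixel, px),
#'   peak_intensity; attribute `channel`.
#' @export
detect_foci <- function(image, cellmask, cell_id = 1L, smooth_sigma_px = 1,
                        min_sep_px = 4, threshold = NULL, channel = "ori") {
  cell <- if (is.matrix(cellmask) && is.logical(cellmask)) cellmask else
    cellmask$labels == cell_id
  sm <- gaussian_blur(image, smooth_sigma_px, normalize = TRUE)
  vals <- sm[cell]
  bg <- stats::median(vals)
  if (is.null(threshold)) {
    noise <- stats::mad(vals)
    threshold <- max(5 * noise, 0.2 * (max(vals) - bg))
  }
  net <- sm - bg
  empty0 <- structure(data.frame(x = numeric(0), y = numeric(0),
                                 peak_intensity = numeric(0)),
                      channel = channel, class = c("foci_set", "data.frame"))
  if (threshold <= 0 || max(net[cell]) <= 0) return(empty0)
  # local maxima on the 8-neighborhood
  is_max <- net >= threshold & cell
  for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                 c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
    is_max <- is_max & net >= shift_mat(net, d[1L], d[2L], fill = -Inf)
  empty <- structure(data.frame(x = numeric(0), y = numeric(0),
                                peak_intensity = numeric(0)),
                     channel = channel, class = c("foci_set", "data.frame"))
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  peaks <- data.frame(x = idx[, 2L], y = idx[, 1L],
                      peak = net[idx])
  peaks <- peaks[order(-peaks$peak, peaks$y, peaks$x), , drop = FALSE]
  keep <- integer(0)
  for (i in seq_len(nrow(peaks))) {
    if (length(keep) == 0L ||
        all(sqrt((peaks$x[keep] - peaks$x[i])^2 +
                 (peaks$y[keep] - peaks$y[i])^2) >= min_sep_px))
      keep <- c(keep, i)
  }
  peaks <- peaks[keep, , drop = FALSE]
  # sub-pixel centroid in a 5x5 window on the background-subtracted image
  h <- nrow(image); w <- ncol(image)
  for (i in seq_len(nrow(peaks))) {
    rs <- max(1, peaks$y[i] - 2):min(h, peaks$y[i] + 2)
    cs <- max(1, peaks$x[i] - 2):min(w, peaks$x[i] + 2)
    win <- pmax(net[rs, cs, drop = FALSE], 0)
    if (sum(win) > 0) {
      peaks$x[i] <- sum(rep(cs, each = length(rs)) * win) / sum(win)
      peaks$y[i] <- sum(rep(rs, times = length(cs)) * win) / sum(win)
    }
  }
  structure(data.frame(x = peaks$x, y = peaks$y,
                       peak_intensity = peaks$peak),
            channel = channel, class = c("foci_set", "data.frame"))
}

#' Focus-count quality control
#'
#' Cells with more ter than ori foci are discarded; cells with zero foci in
#' both channels are kept but flagged anucleate.
#'
#' @param ori,ter `foci_set` data.frames.
#' @return list: `keep` (logical), `anucleate` (logical), `reason`.
#' @export
qc_foci <- function(ori, ter) {
  n_ori <- nrow(ori); n_ter <- nrow(ter)
  if (n_ter > n_ori)
    return(list(keep = FALSE, anucleate = FALSE,
                reason = sprintf("more ter (%d) than ori (%d) foci", n_ter, n_ori)))
  list(keep = TRUE, anucleate = n_ori == 0L && n_ter == 0L, reason = "ok")
}

#' Intensity-overlap colocalization
#'
#' Percentage of the total in-cell intensity of `image` that falls inside
#' `region_mask`: `100 * sum(image[region & cell]) / sum(image[cell])`.
#' Compute it once with the DNA image against the MukB mask (the primary,
#' DNA-in-MukB direction) and once with the MukB image against the DNA mask
#' (the converse).
#'
#' @param image background-subtracted intensity image.
#' @param region_mask logical matrix (e.g. the MukB mask).
#' @param cell logical cell mask.
#' @return percent in \[0, 100\], or NA (flagged by attribute
#'   `undefined = TRUE`) when the cell has zero total intensity.
#' @export
intensity_overlap_fraction <- function(image, region_mask, cell) {
  tot <- sum(image[cell])
  if (tot <= 0) return(structure(NA_real_, undefined = TRUE))
  100 * sum(image[region_mask & cell]) / tot
}

#' Binary focus-mask colocalization
#'
#' A focus colocalizes when its footprint (disk of one PSF FWHM diameter
#' around the sub-pixel center) covers at least one mask pixel.
#'
#' @param focus one row of a `foci_set` (or a list with `x`, `y`).
#' @param mask logical matrix.
#' @param psf_fwhm_px PSF FWHM in pixels (footprint diameter).
#' @return logical.
#' @export
focus_overlaps_mask <- function(focus, mask, psf_fwhm_px) {
  fp <- disk_mask(dim(mask), focus$x, focus$y, psf_fwhm_px / 2)
  any(mask & fp)
}

#' Per-area DNA compaction ratio
#'
#' Mean per-area DNA intensity inside the MukB-overlapping part of the
#' chromosome divided by the mean elsewhere on the chromosome:
#' `(sum(dna[in]) / area(in)) / (sum(dna[out]) / area(out))` with
#' `in = dna_mask & mukb_mask`, `out = dna_mask & !mukb_mask`. Equal
#' densities give 1.
#'
#' @param dna_image background-subtracted DNA image.
#' @param dna_mask,mukb_mask logical matrices.
#' @return list of class `compaction_result`: `ratio` (NA and
#'   `undefined = TRUE` when either partition is empty), `area_in`,
#'   `area_out`.
#' @export
compaction_ratio <- function(dna_image, dna_mask, mukb_mask) {
  if (inherits(dna_mask, "channel_mask")) dna_mask <- dna_mask$mask
  if (inherits(mukb_mask, "channel_mask")) mukb_mask <- mukb_mask$mask
  inside <- dna_mask & mukb_mask
  outside <- dna_mask & !mukb_mask
  a_in <- sum(inside); a_out <- sum(outside)
  if (a_in == 0L || a_out == 0L)
    return(structure(list(ratio = NA_real_, area_in = a_in, area_out = a_out),
                     undefined = TRUE, class = "compaction_result"))
  structure(list(ratio = (sum(dna_image[inside]) / a_in) /
                   (sum(dna_image[outside]) / a_out),
                 area_in = a_in, area_out = a_out),
            class = "compaction_result")
}
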