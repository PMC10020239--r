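# Cell masks from phase contrast and per-channel signal masks from
# fluorescence.

#' Segment cells from a phase-contrast image
#'
#' Cells appear dark on a bright background. The image is Otsu-thresholded,
#' holes are filled, and 8-connected components above a minimum area become
#' cells. Cells whose masks, dilated by `dilate_px`, touch another cell are
#' flagged `touching_neighbor` (automated stand-in for manual rejection of
#' too-close neighbors); cells touching the frame border are flagged
#' `border_clipped`.
#'
#' @param phase 2-D numeric matrix.
#' @param min_area_px minimum cell area in pixels.
#' @param dilate_px QC proximity radius in pixels: a cell whose mask,
#'   dilated by this much, reaches another cell is flagged (default 6 px,
#'   about 0.4 um).
#' @param min_contrast minimum intensity range; flatter images (empty
#'   fields) yield zero cells instead of thresholding pure noise.
#' @return list of class `cell_mask`: `labels` (integer matrix, labels
#'   contiguous from 1), `cells` (data.frame: cell_id, area_px, bbox columns,
#'   qc_flag), `n`.
#' @export
segment_cells <- function(phase, min_area_px = 200L, dilate_px = 6L,
                          min_contrast = 0.1) {
  stopifnot(is.matrix(phase))
  empty <- list(labels = matrix(0L, nrow(phase), ncol(phase)),
                cells = data.frame(cell_id = integer(0), area_px = integer(0),
                                   rmin = integer(0), rmax = integer(0),
                                   cmin = integer(0), cmax = integer(0),
                                   qc_flag = character(0)),
                n = 0L)
  class(empty) <- "cell_mask"
  rng <- range(phase)
  if (diff(rng) <= min_contrast * max(abs(rng), 1e-12)) return(empty)
  thr <- otsu_vec(as.numeric(phase))
  mask <- phase < thr
  if (!any(mask)) return(empty)
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1))) > 0
  lab <- label_components(mask, 8L)
  n0 <- attr(lab, "n")
  if (n0 == 0L) return(empty)
  areas <- tabulate(lab[lab > 0], nbins = n0)
  keep <- which(areas >= min_area_px)
  if (length(keep) == 0L) return(empty)
  relab <- integer(n0); relab[keep] <- seq_along(keep)
  labels <- matrix(0L, nrow(lab), ncol(lab))
  labels[lab > 0] <- relab[lab[lab > 0]]
  n <- length(keep)

  brush <- EBImage::makeBrush(2L * dilate_px + 1L, shape = "disc")
  cells <- data.frame(cell_id = seq_len(n), area_px = areas[keep],
                      rmin = 0L, rmax = 0L, cmin = 0L, cmax = 0L,
                      qc_flag = "ok", stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    sel <- labels == i
    rows <- range(which(rowSums(sel) > 0)); cols <- range(which(colSums(sel) > 0))
    cells$rmin[i] <- rows[1L]; cells$rmax[i] <- rows[2L]
    cells$cmin[i] <- cols[1L]; cells$cmax[i] <- cols[2L]
    if (rows[1L] == 1L || cols[1L] == 1L ||
        rows[2L] == nrow(labels) || cols[2L] == ncol(labels))
      cells$qc_flag[i] <- "border_clipped"
    dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(sel * 1), brush)) > 0
    if (any(labels[dil] != 0L & labels[dil] != i))
      cells$qc_flag[i] <- "touching_neighbor"
  }
  structure(list(labels = labels, cells = cells, n = n), class = "cell_mask")
}

#' Threshold a fluorescence channel within one cell
#'
#' Gaussian smoothing, background removal, then Otsu thresholding restricted
#' to the in-cell pixels. The background is the median of in-cell smoothed
#' pixels below their 25th percentile (robust to large bright structures).
#' The numeric threshold is returned for the per-cell record. A channel that
#' is all background yields an empty mask, not an error.
#'
#' @param image 2-D channel matrix (same frame as the cell labels).
#' @param cellmask a [segment_cells()] result, or a logical matrix.
#' @param cell_id which cell (ignored for a logical mask).
#' @param smooth_sigma_px Gaussian sigma in pixels.
#' @return list of class `channel_mask`: `mask` (logical, subset of the cell
#'   mask), `threshold` (on the background-subtracted smoothed scale),
#'   `background`, `image_bgsub` (smoothed, background-subtracted image,
#'   zero outside the cell; used for thresholding), `image_raw_bgsub` (the
#'   unsmoothed background-subtracted image, zero outside the cell; used for
#'   intensity sums so smoothing does not mix signal across mask or axis
#'   boundaries).
#' @export
threshold_channel <- function(image, cellmask, cell_id = 1L,
                              smooth_sigma_px = 1) {
  cell <- if (is.matrix(cellmask) && is.logical(cellmask)) cellmask else
    cellmask$labels == cell_id
  stopifnot(identical(dim(image), dim(cell)), any(cell))
  sm <- gaussian_blur(image, smooth_sigma_px, normalize = TRUE)
  vals <- sm[cell]
  bg <- stats::median(vals[vals <= stats::quantile(vals, 0.25)])
  bgsub <- pmax(sm - bg, 0)
  bgsub[!cell] <- 0
  raw <- pmax(image - bg, 0)
  raw[!cell] <- 0
  invals <- bgsub[cell]
  out <- list(mask = matrix(FALSE, nrow(image), ncol(image)),
              threshold = NA_real_, background = bg, image_bgsub = bgsub,
              image_raw_bgsub = raw)
  class(out) <- "channel_mask"
  flat_tol <- 1e-9 * max(abs(range(sm[cell])), 1e-300)
  if (diff(range(invals)) <= flat_tol) return(out)  # flat channel: empty mask
  thr <- otsu_vec(invals)
  out$threshold <- thr
  out$mask <- bgsub > thr & cell
  out
}

#' Label signal clusters in a channel mask
#'
#' 8-connected components; components smaller than `min_area_px` are removed
#' and counted in the `n_removed` attribute.
#'
#' @param mask logical matrix (e.g. from [threshold_channel()]).
#' @param min_area_px minimum component area kept.
#' @param intensity optional intensity image for per-cluster sums.
#' @return list: `labels` (integer matrix), `clusters` (data.frame:
#'   cluster_id, area_px, sum_intensity), `n`, attribute `n_removed`.
#' @export
label_clusters <- function(mask, min_area_px = 4L, intensity = NULL) {
  if (inherits(mask, "channel_mask")) {
    if (is.null(intensity)) intensity <- mask$image_bgsub
    mask <- mask$mask
  }
  stopifnot(is.matrix(mask))
  lab <- label_components(mask, 8L)
  n0 <- attr(lab, "n")
  if (n0 == 0L)
    return(structure(list(labels = matrix(0L, nrow(mask), ncol(mask)),
                          clusters = data.frame(cluster_id = integer(0),
                                                area_px = integer(0),
                                                sum_intensity = numeric(0)),
                          n = 0L), n_removed = 0L))
  areas <- tabulate(lab[lab > 0], nbins = n0)
  keep <- which(areas >= min_area_px)
  relab <- integer(n0); relab[keep] <- seq_along(keep)
  labels <- matrix(0L, nrow(lab), ncol(lab))
  labels[lab > 0] <- relab[lab[lab > 0]]
  sums <- if (is.null(intensity)) rep(NA_real_, length(keep)) else
    vapply(seq_along(keep), function(i) sum(intensity[labels == i]), numeric(1L))
  structure(list(labels = labels,
                 clusters = data.frame(cluster_id = seq_along(keep),
                                       area_px = areas[keep],
                                       sum_intensity = sums),
                 n = length(keep)),
            n_removed = n0 - length(keep))
}
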