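# Arm-asymmetry statistic A = |sum(IR) - sum(IL)| / (sum(IR) + sum(IL))
# around the origin of replication.

#' Intensity-weighted center of mass
#'
#' @param image 2-D intensity matrix.
#' @param mask optional logical matrix restricting the computation.
#' @return c(x, y) in pixel coordinates; errors on zero total signal.
#' @export
center_of_mass <- function(image, mask = NULL) {
  if (!is.null(mask)) {
    img <- image
    img[!mask] <- 0
  } else img <- image
  tot <- sum(img)
  if (tot <= 0) stop("zero total signal: center of mass undefined")
  xs <- matrix(seq_len(ncol(img)), nrow(img), ncol(img), byrow = TRUE)
  ys <- matrix(seq_len(nrow(img)), nrow(img), ncol(img))
  c(x = sum(xs * img) / tot, y = sum(ys * img) / tot)
}

#' Central axis through ori and the chromosome center of mass
#'
#' The oriented line from the center of mass to the origin of replication;
#' it splits the plane into a clockwise ("right") and an anticlockwise
#' ("left") half-plane, deterministically in image coordinates (y down).
#' The side labels are geometric, not genomic.
#'
#' @param ori c(x, y) position of the ori focus.
#' @param com c(x, y) chromosome center of mass.
#' @return list of class `central_axis`: `origin` (the ori point),
#'   `direction` (unit vector com -> ori).
#' @export
central_axis <- function(ori, com) {
  d <- c(ori[1L] - com[1L], ori[2L] - com[2L])
  nd <- sqrt(sum(d^2))
  if (nd == 0) stop("ori coincides with the center of mass: axis undefined")
  structure(list(origin = c(x = unname(ori[1L]), y = unname(ori[2L])),
                 direction = d / nd), class = "central_axis")
}

# Signed side of points relative to a central axis: positive = clockwise
# ("right") in image coordinates, negative = anticlockwise, zero = on axis.
axis_side <- function(axis, x, y) {
  u <- axis$direction
  u[1L] * (y - axis$origin[2L]) - u[2L] * (x - axis$origin[1L])
}

#' Arm asymmetricity around the origin of replication
#'
#' Sums the channel intensity over a circular ROI centered on the ori focus
#' (default diameter 20 px = 1.3 um at 0.065 um/px), split by the central
#' axis through ori and the chromosome center of mass, and returns
#' `A = |sum(IR) - sum(IL)| / (sum(IR) + sum(IL))`. Equal spread gives 0;
#' all signal on one arm gives 1. Pixels on the axis contribute half to
#' each side (or are excluded with `axis_pixels = "exclude"`).
#'
#' @param image 2-D channel matrix (DNA or MukB).
#' @param ori c(x, y) ori position (sub-pixel allowed).
#' @param com c(x, y) chromosome center of mass.
#' @param roi_diameter_px ROI diameter in pixels.
#' @param axis_pixels `"split"` (default) or `"exclude"`.
#' @return list of class `asymmetry_result`: `A`, `sum_right`, `sum_left`,
#'   `roi_center`, `roi_diameter_px`, `n_pixels`; `A` is NA with attribute
#'   `undefined = TRUE` when the ROI holds no signal.
#' @export
asymmetricity <- function(image, ori, com, roi_diameter_px = 20L,
                          axis_pixels = c("split", "exclude")) {
  axis_pixels <- match.arg(axis_pixels)
  axis <- central_axis(ori, com)
  roi <- disk_mask(dim(image), ori[1L], ori[2L], roi_diameter_px / 2)
  if (!any(roi)) stop("ROI does not intersect the image")
  idx <- which(roi, arr.ind = TRUE)
  s <- axis_side(axis, idx[, 2L], idx[, 1L])
  v <- image[roi]
  tol <- 1e-9
  sum_r <- sum(v[s > tol]); sum_l <- sum(v[s < -tol])
  on_axis <- sum(v[abs(s) <= tol])
  if (axis_pixels == "split") {
    sum_r <- sum_r + on_axis / 2
    sum_l <- sum_l + on_axis / 2
  }
  tot <- sum_r + sum_l
  out <- list(A = NA_real_, sum_right = sum_r, sum_left = sum_l,
              roi_center = c(x = unname(ori[1L]), y = unname(ori[2L])),
              roi_diameter_px = roi_diameter_px, n_pixels = nrow(idx))
  class(out) <- "asymmetry_result"
  if (tot <= 0) { attr(out, "undefined") <- TRUE; return(out) }
  out$A <- abs(sum_r - sum_l) / tot
  out
}
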