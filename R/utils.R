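# Internal helpers shared across modules. Images are plain numeric matrices;
# element [r, c] is the pixel centered at (x = c, y = r) in pixel units,
# origin top-left, y increasing downwards.

#' @importFrom EBImage filter2 makeBrush bwlabel fillHull dilate imageData Image
NULL

#' Gaussian smoothing with zero-padded boundaries
#'
#' Convolves an image with a normalized Gaussian kernel. Out-of-frame pixels
#' are treated as zero, so total in-frame intensity is conserved up to what
#' genuinely leaks across the border.
#'
#' @param img numeric matrix.
#' @param sigma kernel standard deviation in pixels; `sigma <= 0` returns the
#'   input unchanged.
#' @param normalize divide by the blurred indicator so border pixels are
#'   averages of in-frame values only (a uniform image smooths to itself);
#'   use `FALSE` (the default) where total intensity must be conserved, as
#'   in PSF simulation.
#' @return numeric matrix of the same dimensions.
#' @export
gaussian_blur <- function(img, sigma, normalize = FALSE) {
  if (sigma <= 0) return(img)
  size <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  if (size < 3L) return(img)
  if (normalize) {
    ones <- matrix(1, nrow(img), ncol(img))
    return(gaussian_blur(img, sigma) / gaussian_blur(ones, sigma))
  }
  brush <- EBImage::makeBrush(size = size, shape = "Gaussian", sigma = sigma)
  # filter2 requires the kernel to fit inside the image: pad if needed
  pad <- c(0L, 0L)
  if (size > nrow(img) || size > ncol(img)) {
    pad <- c(max(0L, size - nrow(img)), max(0L, size - ncol(img)))
    big <- matrix(0, nrow(img) + 2L * pad[1L], ncol(img) + 2L * pad[2L])
    big[pad[1L] + seq_len(nrow(img)), pad[2L] + seq_len(ncol(img))] <- img
    img2 <- big
  } else img2 <- img
  out <- EBImage::imageData(EBImage::filter2(img2, brush, boundary = 0))
  if (any(pad > 0L)) {
    out <- out[pad[1L] + seq_len(nrow(img)), pad[2L] + seq_len(ncol(img)),
               drop = FALSE]
  }
  out
}

# Otsu threshold on a numeric vector (histogram with `levels` bins over the
# data range). Needed because image-wide Otsu cannot be restricted to the
# pixels inside one cell mask.
otsu_vec <- function(v, levels = 256L) {
  v <- v[is.finite(v)]
  if (length(v) == 0L) return(NA_real_)
  rng <- range(v)
  if (diff(rng) <= 0) return(rng[1L])
  breaks <- seq(rng[1L], rng[2L], length.out = levels + 1L)
  h <- tabulate(findInterval(v, breaks, all.inside = TRUE), nbins = levels)
  mids <- (breaks[-1L] + breaks[-(levels + 1L)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  n <- w[levels]; mt <- m[levels]
  w0 <- w[-levels]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, levels - 1L)
  between[valid] <- (mt * w0[valid] / n - m[-levels][valid])^2 /
    (w0[valid] / n * w1[valid] / n) # proportional to between-class variance
  mids[-levels][which.max(between)]
}

# Shift a matrix by (dr, dc), filling exposed cells with `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  out <- matrix(fill, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)); cs <- seq_len(ncol(m))
  rsrc <- rs - dr; csrc <- cs - dc
  rok <- rsrc >= 1 & rsrc <= nrow(m); cok <- csrc >= 1 & csrc <= ncol(m)
  out[rs[rok], cs[cok]] <- m[rsrc[rok], csrc[cok]]
  out
}

# 8-connected labeling built on EBImage::bwlabel (4-connected) plus a
# union-find merge of labels that touch diagonally.
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::imageData(EBImage::bwlabel(m))
  if (connectivity == 4L || max(lab) <= 1) return(structure(lab, n = max(lab)))
  parent <- seq_len(max(lab))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (d in list(c(1, 1), c(1, -1))) {
    sh <- shift_mat(lab, d[1L], d[2L])
    sel <- lab > 0 & sh > 0 & lab != sh
    if (any(sel)) {
      pairs <- unique(cbind(as.integer(lab[sel]), as.integer(sh[sel])))
      for (k in seq_len(nrow(pairs))) {
        a <- find(pairs[k, 1L]); b <- find(pairs[k, 2L])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
    }
  }
  roots <- vapply(seq_along(parent), function(i) as.integer(find(i)),
                  integer(1L))
  new_id <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- new_id[lab[lab > 0]]
  structure(out, n = length(unique(new_id)))
}

# Boolean disk mask: pixels whose center is within `radius` px of (cx, cy).
disk_mask <- function(dim_hw, cx, cy, radius) {
  xs <- matrix(seq_len(dim_hw[2L]), dim_hw[1L], dim_hw[2L], byrow = TRUE)
  ys <- matrix(seq_len(dim_hw[1L]), dim_hw[1L], dim_hw[2L])
  (xs - cx)^2 + (ys - cy)^2 <= radius^2
}

# Vectorized bilinear interpolation; coordinates in pixel units (x = col,
# y = row). Points outside the frame return NA.
bilinear <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  out <- rep(NA_real_, length(x))
  ok <- x >= 1 & x <= w & y >= 1 & y <= h & is.finite(x) & is.finite(y)
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]
  x0 <- pmin(floor(x), w - 1L); y0 <- pmin(floor(y), h - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- (x0 - 1) * h + y0
  v <- img[i00] * (1 - fx) * (1 - fy) + img[i00 + h] * fx * (1 - fy) +
    img[i00 + 1] * (1 - fx) * fy + img[i00 + h + 1] * fx * fy
  out[ok] <- v
  out
}

# Smallest circular difference between two angles in degrees, in [0, 180].
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}
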