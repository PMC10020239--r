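# Synthetic multi-channel fluorescence images of A22-widened E. coli cells
# with toroidal / figure-eight / open nucleoids and known ground truth.
#
# Geometry: the DNA is a Gaussian-profile tube along a parametric closed
# curve (a circle for a toroid, two tangent circles for a figure-eight
# dimer). MukBEF occupies an angular arc of the ring; DNA density on that
# arc is elevated by a multiplicative compaction factor. Arm bias multiplies
# the density by (1 + b) on the clockwise side of the ori axis and (1 - b)
# on the anticlockwise side, so the asymmetricity statistic applied to the
# noiseless truth equals b when the geometry is grid-symmetric about that
# axis (the default: ori at angle 0).

#' Specification of one synthetic cell
#'
#' Builds a validated parameter set for [render_cell()]. Defaults emulate a
#' wildtype-like widened cell: ring radius 0.716 um (contour 4.5 um), tube
#' sigma 0.187 um (FWHM 0.44 um), MukB arc of +-25 deg centered on ori,
#' compaction factor 1.8, MukB arm bias 0.33. The point-spread function
#' default (sigma 0.07 um) emulates deconvolved widefield stacks, which is
#' what the quantification operates on; the raw widefield PSF is wider (see
#' [imaging_config()]).
#'
#' @param image_size integer (H, W) in pixels.
#' @param pixel_size_um physical pixel size, um/pixel.
#' @param topology one of `"toroid"`, `"figure_eight"`, `"open"`.
#' @param ring_radius_um ring radius of the nucleoid toroid, um.
#' @param tube_sigma_um Gaussian cross-section sigma of the DNA tube, um.
#' @param dna_total_intensity,mukb_total_intensity,focus_intensity photon
#'   totals for the DNA channel, the MukB channel, and each focus.
#' @param mukb_arc_center_deg,mukb_arc_halfwidth_deg angular span of MukB
#'   occupancy along the ring, degrees (0 deg = image-right, increasing
#'   clockwise on screen).
#' @param arm_bias ground-truth asymmetricity of MukB about the ori axis,
#'   in \[0, 1\].
#' @param dna_arm_bias same for the DNA channel (default 0).
#' @param compaction_factor per-area DNA density inside the MukB arc
#'   relative to elsewhere on the ring; >= 1.
#' @param ori_angles_deg,ter_angles_deg angular positions of ori/ter foci
#'   (1--4 each). For figure-eight cells, focus k is placed on ring
#'   ((k - 1) mod 2) + 1.
#' @param open_arc_deg for `topology = "open"`: arc length of the open
#'   nucleoid in degrees (< 360); the gap is centered opposite ori.
#' @param psf_sigma_um lateral PSF sigma, um; 0 disables blur.
#' @param noise_model `"none"`, `"poisson"`, or `"poisson+gaussian"`.
#' @param gaussian_sd read-noise sd in photons (used by poisson+gaussian).
#' @param cell_radius_um phase-contrast footprint radius; default fits the
#'   ring plus 3 tube sigmas plus 0.35 um.
#' @param seed integer seed for the cell's noise stream.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(image_size = c(140L, 140L),
                           pixel_size_um = 0.065,
                           topology = c("toroid", "figure_eight", "open"),
                           ring_radius_um = 0.716,
                           tube_sigma_um = 0.187,
                           dna_total_intensity = 2e5,
                           mukb_total_intensity = 6e4,
                           focus_intensity = 1.5e4,
                           mukb_arc_center_deg = 0,
                           mukb_arc_halfwidth_deg = 25,
                           arm_bias = 0.33,
                           dna_arm_bias = 0,
                           compaction_factor = 1.8,
                           ori_angles_deg = 0,
                           ter_angles_deg = 180,
                           open_arc_deg = 300,
                           psf_sigma_um = 0.07,
                           noise_model = c("poisson", "none", "poisson+gaussian"),
                           gaussian_sd = 2,
                           cell_radius_um = NULL,
                           seed = 1L) {
  topology <- match.arg(topology)
  noise_model <- match.arg(noise_model)
  if (is.null(cell_radius_um)) {
    extent <- if (topology == "figure_eight") 2 * ring_radius_um else ring_radius_um
    cell_radius_um <- extent + 3 * tube_sigma_um + 0.35
  }
  spec <- structure(list(
    image_size = as.integer(image_size), pixel_size_um = pixel_size_um,
    topology = topology, ring_radius_um = ring_radius_um,
    tube_sigma_um = tube_sigma_um,
    dna_total_intensity = dna_total_intensity,
    mukb_total_intensity = mukb_total_intensity,
    focus_intensity = focus_intensity,
    mukb_arc_center_deg = mukb_arc_center_deg,
    mukb_arc_halfwidth_deg = mukb_arc_halfwidth_deg,
    arm_bias = arm_bias, dna_arm_bias = dna_arm_bias,
    compaction_factor = compaction_factor,
    ori_angles_deg = ori_angles_deg, ter_angles_deg = ter_angles_deg,
    open_arc_deg = open_arc_deg,
    psf_sigma_um = psf_sigma_um, noise_model = noise_model,
    gaussian_sd = gaussian_sd, cell_radius_um = cell_radius_um,
    seed = as.integer(seed)), class = "synthetic_spec")
  validate_spec(spec)
  spec
}

#' Validate a synthetic cell specification
#'
#' Checks the invariants of [synthetic_spec()]: biases in \[0, 1\],
#' compaction factor >= 1, 1--4 foci per channel, and that the ring plus 3
#' tube sigmas fits inside the cell footprint, which in turn must fit the
#' frame.
#'
#' @param spec a `synthetic_spec`.
#' @return the spec, invisibly; errors otherwise.
#' @export
validate_spec <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$arm_bias < 0 || spec$arm_bias > 1) stop("arm_bias must be in [0, 1]")
  if (spec$dna_arm_bias < 0 || spec$dna_arm_bias > 1)
    stop("dna_arm_bias must be in [0, 1]")
  if (spec$compaction_factor < 1) stop("compaction_factor must be >= 1")
  for (ch in c("ori_angles_deg", "ter_angles_deg")) {
    n <- length(spec[[ch]])
    if (n < 1L || n > 4L) stop(ch, " must list 1 to 4 foci")
  }
  extent <- if (spec$topology == "figure_eight") 2 * spec$ring_radius_um else
    spec$ring_radius_um
  if (2 * extent + 6 * spec$tube_sigma_um > 2 * spec$cell_radius_um)
    stop("ring diameter + 6 tube sigmas exceeds the cell footprint")
  rpx <- spec$cell_radius_um / spec$pixel_size_um
  if (2 * rpx + 4 > min(spec$image_size))
    stop(sprintf(paste0("cell footprint (%.0f px across) does not fit the ",
                        "%d x %d frame; enlarge image_size or shrink the cell"),
                 2 * rpx, spec$image_size[1L], spec$image_size[2L]))
  invisible(spec)
}

# Ring centers (x, y, px) for a spec, given the frame center.
ring_centers_px <- function(spec, cx, cy) {
  rpx <- spec$ring_radius_um / spec$pixel_size_um
  if (spec$topology == "figure_eight") {
    list(c(cx - rpx, cy), c(cx + rpx, cy))
  } else list(c(cx, cy))
}

# Noiseless, unblurred tube field for one channel along the spec's rings.
# `arc_only` restricts the tube to the MukB arc; `bias` is the arm bias.
tube_field <- function(spec, cx, cy, arc_only = FALSE, bias = 0,
                       compaction = 1) {
  h <- spec$image_size[1L]; w <- spec$image_size[2L]
  rpx <- spec$ring_radius_um / spec$pixel_size_um
  spx <- spec$tube_sigma_um / spec$pixel_size_um
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- matrix(seq_len(h), h, w)
  field <- matrix(0, h, w)
  ori_ang <- spec$ori_angles_deg[1L] * pi / 180
  u <- c(cos(ori_ang), sin(ori_ang))      # ori axis direction (y down)
  for (ctr in ring_centers_px(spec, cx, cy)) {
    dx <- xs - ctr[1L]; dy <- ys - ctr[2L]
    r <- sqrt(dx^2 + dy^2)
    th <- (atan2(dy, dx) * 180 / pi) %% 360
    g <- exp(-(r - rpx)^2 / (2 * spx^2))
    on_arc <- ang_diff(th, spec$mukb_arc_center_deg) <= spec$mukb_arc_halfwidth_deg
    dens <- if (arc_only) as.numeric(on_arc) else
      1 + (compaction - 1) * as.numeric(on_arc)
    if (spec$topology == "open" && !arc_only) {
      gap_center <- (spec$ori_angles_deg[1L] + 180) %% 360
      gap_half <- (360 - spec$open_arc_deg) / 2
      dens <- dens * as.numeric(ang_diff(th, gap_center) > gap_half)
    }
    if (bias > 0) {
      s <- sign(u[1L] * dy - u[2L] * dx)   # clockwise side positive
      dens <- dens * (1 + bias * s)
    }
    field <- field + dens * g
  }
  field
}

# Geometric footprint of the DNA tube ("dna": half-maximum band along the
# whole curve) or of the MukB occupancy ("mukb": the band cut to the arc).
footprint_mask <- function(dim_hw, centers, ring_radius_px, tube_sigma_px,
                           which = c("dna", "mukb"),
                           arc_center_deg = 0, arc_halfwidth_deg = 180,
                           open_gap = NULL) {
  which <- match.arg(which)
  h <- dim_hw[1L]; w <- dim_hw[2L]
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- matrix(seq_len(h), h, w)
  half <- sqrt(2 * log(2)) * tube_sigma_px
  out <- matrix(FALSE, h, w)
  for (ctr in centers) {
    dx <- xs - ctr[1L]; dy <- ys - ctr[2L]
    band <- abs(sqrt(dx^2 + dy^2) - ring_radius_px) <= half
    th <- (atan2(dy, dx) * 180 / pi) %% 360
    if (which == "mukb")
      band <- band & ang_diff(th, arc_center_deg) <= arc_halfwidth_deg
    if (!is.null(open_gap))
      band <- band & ang_diff(th, open_gap$center) > open_gap$half
    out <- out | band
  }
  out
}

true_footprint <- function(spec, cx, cy, which) {
  gap <- if (spec$topology == "open" && which == "dna")
    list(center = (spec$ori_angles_deg[1L] + 180) %% 360,
         half = (360 - spec$open_arc_deg) / 2) else NULL
  footprint_mask(spec$image_size, ring_centers_px(spec, cx, cy),
                 spec$ring_radius_um / spec$pixel_size_um,
                 spec$tube_sigma_um / spec$pixel_size_um, which,
                 spec$mukb_arc_center_deg, spec$mukb_arc_halfwidth_deg, gap)
}

#' Ground-truth footprint masks of a rendered cell
#'
#' Reconstructs the geometric half-maximum footprints of the DNA tube and of
#' the MukB arc from a `ground_truth`, for recovery tests of mask-dependent
#' quantities (overlap fraction, compaction ratio) that would otherwise
#' confound estimator error with segmentation error.
#'
#' @param truth a `ground_truth` from [render_cell()].
#' @param dim_hw frame (H, W); defaults to the rendered frame.
#' @return list with logical matrices `dna` and `mukb`.
#' @export
true_masks <- function(truth, dim_hw = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (is.null(dim_hw)) dim_hw <- truth$image_size
  rpx <- truth$ring_radius_um / truth$pixel_size_um
  ctr <- truth$cell_center_px
  centers <- if (truth$topology == "figure_eight")
    list(c(ctr[1L] - rpx, ctr[2L]), c(ctr[1L] + rpx, ctr[2L])) else
      list(c(ctr[1L], ctr[2L]))
  gap <- if (truth$topology == "open")
    list(center = (truth$ori_angle_deg + 180) %% 360,
         half = (360 - truth$open_arc_deg) / 2) else NULL
  spx <- truth$tube_sigma_um / truth$pixel_size_um
  list(dna = footprint_mask(dim_hw, centers, rpx, spx, "dna",
                            open_gap = gap),
       mukb = footprint_mask(dim_hw, centers, rpx, spx, "mukb",
                             truth$mukb_arc_center_deg,
                             truth$mukb_arc_halfwidth_deg))
}

# Splat unit mass at sub-pixel position (x, y) onto the 4 nearest pixels.
splat <- function(field, x, y, mass) {
  h <- nrow(field); w <- ncol(field)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  for (k in 1:4) {
    xx <- x0 + (k - 1) %% 2; yy <- y0 + (k - 1) %/% 2
    wgt <- (if ((k - 1) %% 2 == 0) 1 - fx else fx) *
      (if ((k - 1) %/% 2 == 0) 1 - fy else fy)
    if (xx >= 1 && xx <= w && yy >= 1 && yy <= h)
      field[yy, xx] <- field[yy, xx] + mass * wgt
  }
  field
}

# Focus positions (x, y) in px for a channel's angle list.
focus_positions <- function(spec, cx, cy, angles_deg) {
  ctrs <- ring_centers_px(spec, cx, cy)
  rpx <- spec$ring_radius_um / spec$pixel_size_um
  t(vapply(seq_along(angles_deg), function(k) {
    ctr <- ctrs[[((k - 1L) %% length(ctrs)) + 1L]]
    a <- angles_deg[k] * pi / 180
    c(ctr[1L] + rpx * cos(a), ctr[2L] + rpx * sin(a))
  }, numeric(2L)))
}

apply_noise <- function(img, spec) {
  if (spec$noise_model == "none") return(img)
  out <- matrix(stats::rpois(length(img), pmax(img, 0)), nrow(img), ncol(img))
  if (spec$noise_model == "poisson+gaussian" && spec$gaussian_sd > 0)
    out <- out + matrix(stats::rnorm(length(img), 0, spec$gaussian_sd),
                        nrow(img), ncol(img))
  out
}

#' Render one synthetic cell
#'
#' Produces a 5-channel image (phase, dna, mukb, ori, ter) plus the ground
#' truth needed for recovery tests. Before blur and noise, each fluorescence
#' channel is scaled so its summed intensity equals the specified total
#' exactly. Foci are point sources splatted at sub-pixel positions and take
#' the PSF width through the blur step.
#'
#' @param spec a [synthetic_spec()].
#' @param center_px optional (x, y) cell center in pixels; defaults to the
#'   frame center.
#' @return list with elements `stack` (an `mcstack`, see [mcstack()]) and
#'   `truth` (a `ground_truth` list: resolved spec values plus
#'   `true_contour_length_um`, `true_fwhm_um`, `true_dna_in_mukb_fraction`,
#'   `true_focus_count`, `chromosome_multiplicity`, `com_px`, `ori_px`,
#'   `ter_px`, `cell_center_px`, `cell_radius_px`).
#' @export
render_cell <- function(spec, center_px = NULL) {
  validate_spec(spec)
  h <- spec$image_size[1L]; w <- spec$image_size[2L]
  # half-integer center for even frames: no pixel row/column lies exactly on
  # the ori axis, so the ground-truth asymmetricity is undiluted
  if (is.null(center_px)) center_px <- c((w + 1) / 2, (h + 1) / 2)
  cx <- center_px[1L]; cy <- center_px[2L]
  rpx_cell <- spec$cell_radius_um / spec$pixel_size_um
  if (cx - rpx_cell < 2 || cx + rpx_cell > w - 1 ||
      cy - rpx_cell < 2 || cy + rpx_cell > h - 1)
    stop("cell footprint does not fit the frame at the requested center")

  dna <- tube_field(spec, cx, cy, arc_only = FALSE, bias = spec$dna_arm_bias,
                    compaction = spec$compaction_factor)
  dna <- dna * (spec$dna_total_intensity / sum(dna))
  mukb <- tube_field(spec, cx, cy, arc_only = TRUE, bias = spec$arm_bias)
  mukb <- mukb * (spec$mukb_total_intensity / sum(mukb))

  ori_pos <- focus_positions(spec, cx, cy, spec$ori_angles_deg)
  ter_pos <- focus_positions(spec, cx, cy, spec$ter_angles_deg)
  ori_img <- matrix(0, h, w); ter_img <- matrix(0, h, w)
  for (k in seq_len(nrow(ori_pos)))
    ori_img <- splat(ori_img, ori_pos[k, 1L], ori_pos[k, 2L], spec$focus_intensity)
  for (k in seq_len(nrow(ter_pos)))
    ter_img <- splat(ter_img, ter_pos[k, 1L], ter_pos[k, 2L], spec$focus_intensity)

  # ground truth from the noiseless, unblurred fields; the MukB footprint is
  # the geometric arc sector cut to the tube's half-maximum band
  mukb_fp <- true_footprint(spec, cx, cy, "mukb")
  truth <- structure(list(
    topology = spec$topology,
    ring_radius_um = spec$ring_radius_um, tube_sigma_um = spec$tube_sigma_um,
    compaction_factor = spec$compaction_factor,
    arm_bias = spec$arm_bias, dna_arm_bias = spec$dna_arm_bias,
    true_contour_length_um = switch(spec$topology,
      toroid = 2 * pi * spec$ring_radius_um,
      figure_eight = 2 * (2 * pi * spec$ring_radius_um),
      open = 2 * pi * spec$ring_radius_um * spec$open_arc_deg / 360),
    true_fwhm_um = 2 * sqrt(2 * log(2)) * spec$tube_sigma_um,
    true_dna_in_mukb_fraction = sum(dna[mukb_fp]) / sum(dna),
    true_focus_count = c(ori = nrow(ori_pos), ter = nrow(ter_pos)),
    chromosome_multiplicity = if (spec$topology == "figure_eight") 2L else 1L,
    dna_total_intensity = spec$dna_total_intensity,
    mukb_total_intensity = spec$mukb_total_intensity,
    com_px = c(cx, cy), ori_px = ori_pos, ter_px = ter_pos,
    cell_center_px = c(cx, cy), cell_radius_px = rpx_cell,
    mukb_arc_center_deg = spec$mukb_arc_center_deg,
    mukb_arc_halfwidth_deg = spec$mukb_arc_halfwidth_deg,
    open_arc_deg = spec$open_arc_deg,
    ori_angle_deg = spec$ori_angles_deg[1L],
    image_size = c(h, w),
    pixel_size_um = spec$pixel_size_um, seed = spec$seed),
    class = "ground_truth")

  # phase contrast: dark footprint on bright background with an edge halo
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- matrix(seq_len(h), h, w)
  rr <- sqrt((xs - cx)^2 + (ys - cy)^2)
  phase <- matrix(0.75, h, w)
  phase[rr <= rpx_cell] <- 0.25
  phase[abs(rr - rpx_cell) <= 1.5] <- 1
  phase <- gaussian_blur(phase, 1)

  psf_px <- spec$psf_sigma_um / spec$pixel_size_um
  channels <- list(phase = phase, dna = dna, mukb = mukb,
                   ori = ori_img, ter = ter_img)
  if (psf_px > 0)
    for (ch in c("dna", "mukb", "ori", "ter"))
      channels[[ch]] <- gaussian_blur(channels[[ch]], psf_px)
  if (spec$noise_model != "none") {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(spec$seed)
    for (ch in c("dna", "mukb", "ori", "ter"))
      channels[[ch]] <- apply_noise(channels[[ch]], spec)
    channels$phase <- channels$phase +
      matrix(stats::rnorm(h * w, 0, 0.01), h, w)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }
  list(stack = mcstack(channels, pixel_size_um = spec$pixel_size_um),
       truth = truth)
}

#' Render a population of cells into one field of view
#'
#' Places cells on a grid (or at random non-overlapping positions) with a
#' configurable margin between footprints. `margin_px = 0` produces the
#' touching-cells fixture: footprints 2 px apart, close enough that
#' segmentation QC flags both neighbors.
#'
#' @param specs list of [synthetic_spec()]; each cell's noise stream is
#'   seeded by `seed + cell index`.
#' @param layout `"grid"` or `"random"`.
#' @param margin_px extra separation between cell footprints, px.
#' @param seed integer base seed.
#' @return list with `stack` (one `mcstack` field of view) and `truths`
#'   (list of per-cell ground truths with positions offset into the field).
#' @export
render_population <- function(specs, layout = c("grid", "random"),
                              margin_px = 8L, seed = 1L) {
  layout <- match.arg(layout)
  n <- length(specs)
  if (n == 0L) {
    empty <- matrix(0, 64L, 64L)
    return(list(stack = mcstack(list(phase = empty + 0.75, dna = empty,
                                     mukb = empty, ori = empty, ter = empty),
                                pixel_size_um = 0.065),
                truths = list()))
  }
  px <- specs[[1L]]$pixel_size_um
  rpx <- vapply(specs, function(s) ceiling(s$cell_radius_um / s$pixel_size_um),
                numeric(1L))
  # at margin 0 the dark cell interiors (inside the phase halo) come within
  # the QC dilation radius of each other: the touching-cells fixture
  tile <- 2L * max(rpx) - 4L + margin_px
  if (layout == "grid") {
    ncol_g <- ceiling(sqrt(n))
    nrow_g <- ceiling(n / ncol_g)
    H <- as.integer(nrow_g * tile + 12L); W <- as.integer(ncol_g * tile + 12L)
    centers <- t(vapply(seq_len(n), function(i) {
      gr <- (i - 1L) %/% ncol_g; gc <- (i - 1L) %% ncol_g
      c(6L + gc * tile + tile / 2, 6L + gr * tile + tile / 2)
    }, numeric(2L)))
  } else {
    side <- as.integer(ceiling(sqrt(n) * tile * 1.4) + 4L)
    H <- W <- side
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    centers <- matrix(NA_real_, n, 2L)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(2000L)) {
        cand <- c(stats::runif(1, rpx[i] + 2, W - rpx[i] - 2),
                  stats::runif(1, rpx[i] + 2, H - rpx[i] - 2))
        if (i == 1L || all(sqrt(rowSums((centers[seq_len(i - 1L), , drop = FALSE] -
             matrix(cand, i - 1L, 2L, byrow = TRUE))^2)) >=
             rpx[i] + rpx[seq_len(i - 1L)] + margin_px + 2)) {
          centers[i, ] <- cand; placed <- TRUE; break
        }
      }
      if (!placed) stop("could not place cell ", i,
                        " without overlap; enlarge the field or reduce n")
    }
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }
  field <- list(phase = matrix(0.75, H, W), dna = matrix(0, H, W),
                mukb = matrix(0, H, W), ori = matrix(0, H, W),
                ter = matrix(0, H, W))
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- specs[[i]]
    sp$seed <- as.integer(seed + i)
    sp$image_size <- c(as.integer(2L * rpx[i] + 10L), as.integer(2L * rpx[i] + 10L))
    rc <- render_cell(sp)
    hh <- sp$image_size[1L]; ww <- sp$image_size[2L]
    r0 <- as.integer(round(centers[i, 2L] - (hh + 1) / 2))
    c0 <- as.integer(round(centers[i, 1L] - (ww + 1) / 2))
    rows <- r0 + seq_len(hh); cols <- c0 + seq_len(ww)
    keep_r <- rows >= 1 & rows <= H; keep_c <- cols >= 1 & cols <= W
    for (ch in names(field)) {
      sub <- rc$stack$channels[[ch]][, , 1L]
      if (ch == "phase") {
        # composite as deviation from the shared background so touching
        # interiors and halos accumulate instead of overwriting each other
        field[[ch]][rows[keep_r], cols[keep_c]] <-
          field[[ch]][rows[keep_r], cols[keep_c]] +
          (sub[keep_r, keep_c] - 0.75)
      } else {
        field[[ch]][rows[keep_r], cols[keep_c]] <-
          field[[ch]][rows[keep_r], cols[keep_c]] + sub[keep_r, keep_c]
      }
    }
    tr <- rc$truth
    off <- c(c0, r0)
    tr$com_px <- tr$com_px + off
    tr$cell_center_px <- tr$cell_center_px + off
    tr$ori_px <- tr$ori_px + matrix(off, nrow(tr$ori_px), 2L, byrow = TRUE)
    tr$ter_px <- tr$ter_px + matrix(off, nrow(tr$ter_px), 2L, byrow = TRUE)
    truths[[i]] <- tr
  }
  list(stack = mcstack(field, pixel_size_um = px), truths = truths)
}

#' Strain presets for the synthetic generator
#'
#' Returns a [synthetic_spec()] preconfigured with the population parameters
#' each strain exhibits: ring size from the mean contour length, tube sigma
#' from the mean FWHM width, compaction factor, arm biases, and MukB arc
#' placement (over ori for wildtype; reaching ter for the MatP deletion and
#' the ATPase-deficient EQ mutant).
#'
#' @param strain one of `"wildtype"`, `"matP_del"`, `"mukB_EQ"`,
#'   `"mukB_del_dimer"`.
#' @param ... overrides passed on to [synthetic_spec()].
#' @return a `synthetic_spec`.
#' @export
strain_preset <- function(strain = c("wildtype", "matP_del", "mukB_EQ",
                                     "mukB_del_dimer"), ...) {
  strain <- match.arg(strain)
  fw <- 2 * sqrt(2 * log(2))
  args <- switch(strain,
    wildtype = list(ring_radius_um = 4.5 / (2 * pi), tube_sigma_um = 0.44 / fw,
                    compaction_factor = 1.8, arm_bias = 0.33,
                    dna_arm_bias = 0.27, mukb_arc_center_deg = 0,
                    mukb_arc_halfwidth_deg = 25),
    # MatP deletion: MukBEF no longer displaced from ter -- occupancy spreads
    # from ori across one arm onto the ter region, strongly asymmetric
    matP_del = list(ring_radius_um = 3.5 / (2 * pi), tube_sigma_um = 0.45 / fw,
                    compaction_factor = 1.75, arm_bias = 0.49,
                    dna_arm_bias = 0.32, mukb_arc_center_deg = 75,
                    mukb_arc_halfwidth_deg = 115),
    # ATPase-deficient EQ mutant: MukBEF loads but cannot translocate away
    # from ter; occupancy covers most of the ring with weak compaction
    mukB_EQ = list(ring_radius_um = 3.8 / (2 * pi), tube_sigma_um = 0.41 / fw,
                   compaction_factor = 1.2, arm_bias = 0.26,
                   dna_arm_bias = 0.25, mukb_arc_center_deg = 90,
                   mukb_arc_halfwidth_deg = 170),
    mukB_del_dimer = list(topology = "figure_eight",
                          ring_radius_um = 3.5 / (2 * pi),
                          tube_sigma_um = 0.44 / fw,
                          dna_total_intensity = 4e5,
                          compaction_factor = 1.05, arm_bias = 0,
                          mukb_total_intensity = 1e4,
                          mukb_arc_halfwidth_deg = 15,
                          ori_angles_deg = c(90, 90),
                          ter_angles_deg = c(270, 270),
                          image_size = c(180L, 180L)))
  do.call(synthetic_spec, utils::modifyList(args, list(...)))
}

#' Write the canonical fixture suite
#'
#' Emits the standard test fixtures as multi-page TIFF stacks with JSON
#' ground-truth sidecars plus a manifest listing files, seeds, and the
#' chosen noise levels. Fixtures: a noiseless unblurred toroid, a blurred
#' and noisy toroid, a figure-eight dimer, a MatP-deletion-like cell with
#' MukB over ter, and a 50-cell population field.
#'
#' @param outdir writable directory (created if missing).
#' @param seed integer base seed.
#' @return the manifest, invisibly (also written to `manifest.json`).
#' @export
write_fixture_suite <- function(outdir, seed = 1L) {
  if (!dir.exists(outdir))
    suppressWarnings(dir.create(outdir, recursive = TRUE))
  probe <- file.path(outdir, ".write_probe")
  ok <- dir.exists(outdir) &&
    tryCatch({ writeLines("x", probe); TRUE }, error = function(e) FALSE,
             warning = function(w) FALSE)
  if (!ok) stop("output directory is not writable: ", outdir)
  unlink(probe)
  fixtures <- list(
    toroid_noiseless = list(
      spec = strain_preset("wildtype", noise_model = "none", psf_sigma_um = 0,
                           seed = seed), kind = "cell"),
    toroid_noisy = list(
      spec = strain_preset("wildtype", noise_model = "poisson+gaussian",
                           seed = seed + 1L), kind = "cell"),
    figure_eight_dimer = list(
      spec = strain_preset("mukB_del_dimer", noise_model = "poisson",
                           seed = seed + 2L), kind = "cell"),
    matp_like = list(
      spec = strain_preset("matP_del", noise_model = "poisson",
                           seed = seed + 3L), kind = "cell"),
    population50 = list(
      spec = strain_preset("wildtype", noise_model = "poisson"),
      kind = "population", n = 50L))
  entries <- list()
  for (nm in names(fixtures)) {
    fx <- fixtures[[nm]]
    if (fx$kind == "cell") {
      rc <- render_cell(fx$spec)
      stack <- rc$stack; truths <- list(rc$truth)
    } else {
      pop <- render_population(rep(list(fx$spec), fx$n), layout = "grid",
                               seed = seed + 10L)
      stack <- pop$stack; truths <- pop$truths
    }
    tif <- file.path(outdir, paste0(nm, ".tif"))
    write_stack(stack, tif)
    truth_file <- file.path(outdir, paste0(nm, "_truth.json"))
    jsonlite::write_json(lapply(truths, unclass), truth_file,
                         auto_unbox = TRUE, digits = NA)
    entries[[nm]] <- list(
      image = basename(tif), truth = basename(truth_file),
      seed = fx$spec$seed, n_cells = length(truths),
      noise_model = fx$spec$noise_model,
      photon_budget = list(dna = fx$spec$dna_total_intensity,
                           mukb = fx$spec$mukb_total_intensity,
                           focus = fx$spec$focus_intensity))
  }
  manifest <- list(seed = seed, pixel_size_um = 0.065,
                   note = paste("photon budgets chosen so the peak DNA tube",
                                "signal is ~40x the Poisson shot noise;",
                                "read noise sd 2 photons where enabled"),
                   fixtures = entries)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
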