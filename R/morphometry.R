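# Central-ridge extraction and chromosome morphometry: skeleton tracing,
# topology classification, contour length, FWHM width, Feret diameter.

# Zhang-Suen morphological thinning of a logical mask, vectorized over the
# whole frame. Produces a mostly 8-connected, one-pixel-wide skeleton.
thin_mask <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  if (sum(m) == 0L) return(m > 0)
  neigh <- function(m) list(
    p2 = shift_mat(m, -1, 0), p3 = shift_mat(m, -1, 1),
    p4 = shift_mat(m, 0, 1),  p5 = shift_mat(m, 1, 1),
    p6 = shift_mat(m, 1, 0),  p7 = shift_mat(m, 1, -1),
    p8 = shift_mat(m, 0, -1), p9 = shift_mat(m, -1, -1))
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      nb <- neigh(m)
      B <- Reduce(`+`, nb)
      seqv <- with(nb, list(p2, p3, p4, p5, p6, p7, p8, p9, p2))
      A <- 0
      for (k in 1:8) A <- A + (seqv[[k]] == 0) * (seqv[[k + 1]] == 1)
      cond <- m == 1 & B >= 2 & B <= 6 & A == 1
      cond <- cond & if (sub == 1)
        (nb$p2 * nb$p4 * nb$p6 == 0) & (nb$p4 * nb$p6 * nb$p8 == 0)
      else
        (nb$p2 * nb$p4 * nb$p8 == 0) & (nb$p2 * nb$p6 * nb$p8 == 0)
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m > 0
}

# Skeleton pixel graph. Nodes are skeleton pixels; 4-neighbors are always
# connected; diagonal neighbors only when they share no common 4-connected
# skeleton pixel (avoids spurious triangles along staircases).
skeleton_graph <- function(skel) {
  h <- nrow(skel)
  lin <- which(skel)
  n <- length(lin)
  id <- integer(length(skel)); id[lin] <- seq_len(n)
  rows <- ((lin - 1L) %% h) + 1L
  cols <- ((lin - 1L) %/% h) + 1L
  inb <- function(r, c) r >= 1L & r <= h & c >= 1L & c <= ncol(skel)
  at <- function(r, c) {
    ok <- inb(r, c)
    out <- logical(length(r)); out[ok] <- skel[cbind(r[ok], c[ok])]
    out
  }
  edges <- list()
  for (d in list(c(0L, 1L), c(1L, 0L))) {
    r2 <- rows + d[1L]; c2 <- cols + d[2L]
    sel <- at(r2, c2)
    if (any(sel))
      edges[[length(edges) + 1L]] <- cbind(seq_len(n)[sel],
                                           id[(c2[sel] - 1L) * h + r2[sel]])
  }
  for (d in list(c(1L, 1L), c(-1L, 1L))) {
    r2 <- rows + d[1L]; c2 <- cols + d[2L]
    sel <- at(r2, c2)
    # drop the diagonal shortcut when a shared 4-neighbor exists
    sel <- sel & !at(rows + d[1L], cols) & !at(rows, cols + d[2L])
    if (any(sel))
      edges[[length(edges) + 1L]] <- cbind(seq_len(n)[sel],
                                           id[(c2[sel] - 1L) * h + r2[sel]])
  }
  E <- if (length(edges)) do.call(rbind, edges) else
    matrix(integer(0), 0L, 2L)
  adj <- vector("list", n)
  for (k in seq_len(nrow(E))) {
    adj[[E[k, 1L]]] <- c(adj[[E[k, 1L]]], E[k, 2L])
    adj[[E[k, 2L]]] <- c(adj[[E[k, 2L]]], E[k, 1L])
  }
  adj <- lapply(adj, function(v) sort(unique(v)))
  list(x = cols, y = rows, adj = adj, n = n, n_edges = nrow(E))
}

# Remove spur branches shorter than prune_len that hang off junctions.
prune_spurs <- function(g, prune_len = 5L) {
  keep <- rep(TRUE, g$n)
  repeat {
    deg <- vapply(seq_len(g$n), function(i)
      if (keep[i]) sum(keep[g$adj[[i]]]) else -1L, integer(1L))
    ends <- which(deg == 1L)
    removed_any <- FALSE
    for (e in ends) {
      if (!keep[e]) next
      chain <- e; cur <- e; prev <- 0L
      is_spur <- FALSE
      while (length(chain) <= prune_len) {
        nxt <- setdiff(g$adj[[cur]][keep[g$adj[[cur]]]], prev)
        if (length(nxt) == 0L) break               # isolated open path end
        if (length(nxt) > 1L || deg[nxt[1L]] >= 3L) { is_spur <- TRUE; break }
        prev <- cur; cur <- nxt[1L]; chain <- c(chain, cur)
        if (deg[cur] == 1L) break                  # reached the other end
      }
      if (is_spur && length(chain) <= prune_len) {
        keep[chain] <- FALSE
        removed_any <- TRUE
      }
    }
    if (!removed_any) break
  }
  keep
}

#' Extract the chromosome central ridge (backbone)
#'
#' Thins the DNA mask to a one-pixel skeleton, prunes spurs shorter than
#' `prune_len` pixels, builds the skeleton adjacency graph, detects loops,
#' and orders paths deterministically (start at the topmost-then-leftmost
#' pixel; closed loops oriented clockwise in image coordinates).
#'
#' @param dna_mask logical matrix or [threshold_channel()] result.
#' @param prune_len spur-pruning length, px.
#' @return object of class `backbone`: `paths` (list of n x 2 matrices of
#'   (x, y) pixel coordinates), `closed` (logical per path), `cycle_count`,
#'   `branch_nodes`, `n_components`, `skeleton` (logical matrix).
#' @export
extract_backbone <- function(dna_mask, prune_len = 5L) {
  if (inherits(dna_mask, "channel_mask")) dna_mask <- dna_mask$mask
  stopifnot(is.matrix(dna_mask))
  out <- structure(list(paths = list(), closed = logical(0),
                        cycle_count = 0L, branch_nodes = 0L,
                        n_components = 0L,
                        skeleton = matrix(FALSE, nrow(dna_mask), ncol(dna_mask))),
                   class = "backbone")
  if (!any(dna_mask)) {
    warning("empty mask: zero-length backbone")
    return(out)
  }
  skel <- thin_mask(dna_mask)
  g <- skeleton_graph(skel)
  keep <- prune_spurs(g, prune_len)
  # rebuild on kept nodes
  sk2 <- matrix(FALSE, nrow(skel), ncol(skel))
  sk2[cbind(g$y[keep], g$x[keep])] <- TRUE
  g <- skeleton_graph(sk2)
  out$skeleton <- sk2
  n <- g$n
  if (n == 0L) { warning("mask too small to skeletonize"); return(out) }
  deg <- vapply(g$adj, length, integer(1L))

  # connected components
  comp <- integer(n); cc <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cc <- cc + 1L
    queue <- s; comp[s] <- cc
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (u in g$adj[[v]]) if (comp[u] == 0L) { comp[u] <- cc; queue <- c(queue, u) }
    }
  }
  out$n_components <- cc
  out$cycle_count <- g$n_edges - n + cc

  # branch nodes: connected clusters of junction pixels count once
  junc <- which(deg >= 3L)
  if (length(junc)) {
    jset <- rep(FALSE, n); jset[junc] <- TRUE
    seen <- rep(FALSE, n); nb <- 0L
    for (s in junc) {
      if (seen[s]) next
      nb <- nb + 1L
      queue <- s; seen[s] <- TRUE
      while (length(queue)) {
        v <- queue[[1L]]; queue <- queue[-1L]
        for (u in g$adj[[v]]) if (jset[u] && !seen[u]) { seen[u] <- TRUE; queue <- c(queue, u) }
      }
    }
    out$branch_nodes <- nb
  }

  # ordered paths: walk each branch/cycle exactly once via an edge-used set
  used <- new.env(parent = emptyenv())
  ekey <- function(a, b) paste0(min(a, b), "_", max(a, b))
  start_order <- order(g$y, g$x)
  paths <- list(); closed <- logical(0)
  terminals <- which(deg != 2L)
  walk <- function(from, to) {
    p <- c(from, to)
    assign(ekey(from, to), TRUE, envir = used)
    prev <- from; cur <- to
    while (deg[cur] == 2L) {
      nxt <- setdiff(g$adj[[cur]], prev)
      if (length(nxt) == 0L) break
      if (!is.null(used[[ekey(cur, nxt[1L])]])) break
      assign(ekey(cur, nxt[1L]), TRUE, envir = used)
      p <- c(p, nxt[1L]); prev <- cur; cur <- nxt[1L]
    }
    p
  }
  for (t in start_order) {
    if (deg[t] == 2L || deg[t] == 0L) next
    for (nb2 in g$adj[[t]]) {
      if (!is.null(used[[ekey(t, nb2)]])) next
      p <- walk(t, nb2)
      paths[[length(paths) + 1L]] <- p
      closed <- c(closed, p[1L] == p[length(p)])
    }
  }
  # pure cycles (components whose nodes all have degree 2)
  for (s in start_order) {
    if (deg[s] != 2L) next
    nb2 <- g$adj[[s]]
    if (is.null(used[[ekey(s, nb2[1L])]])) {
      p <- walk(s, nb2[1L])
      if (p[1L] == p[length(p)] || all(deg[p] == 2L)) {
        paths[[length(paths) + 1L]] <- c(p, s)[seq_len(length(p) +
          as.integer(p[length(p)] != s))]
        closed <- c(closed, TRUE)
      } else {
        paths[[length(paths) + 1L]] <- p
        closed <- c(closed, FALSE)
      }
    }
  }
  if (length(paths) == 0L && n >= 1L) {    # single pixels
    paths <- lapply(which(deg == 0L), identity)
    closed <- rep(FALSE, length(paths))
  }
  out$paths <- lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    if (closed[i] && length(p) > 1L && p[1L] == p[length(p)])
      p <- p[-length(p)]
    coords <- cbind(x = g$x[p], y = g$y[p])
    if (closed[i] && nrow(coords) >= 3L) {
      # deterministic clockwise orientation (image coordinates, y down)
      xs <- coords[, 1L]; ys <- coords[, 2L]
      area2 <- sum(xs * c(ys[-1L], ys[1L]) - c(xs[-1L], xs[1L]) * ys)
      if (area2 < 0) coords <- coords[c(1L, rev(seq_len(nrow(coords))[-1L])), ,
                                      drop = FALSE]
    }
    coords
  })
  out$closed <- closed
  out
}

# Moving-average smoothing of an ordered pixel path; circular for closed
# paths, truncated window at the ends of open paths (collinear runs are
# fixed points, so straight and 45-degree segments keep their exact length).
smooth_path <- function(coords, closed, window = 5L) {
  n <- nrow(coords)
  if (n < window || window < 3L) return(coords)
  half <- window %/% 2L
  out <- coords
  for (i in seq_len(n)) {
    if (closed) {
      idx <- ((i - half - 1L):(i + half - 1L)) %% n + 1L
    } else {
      k <- min(half, i - 1L, n - i)   # symmetric window: endpoints stay put
      idx <- (i - k):(i + k)
    }
    out[i, ] <- colMeans(coords[idx, , drop = FALSE])
  }
  out
}

path_length <- function(coords, closed) {
  n <- nrow(coords)
  if (n < 2L) return(0)
  d <- sqrt(diff(coords[, 1L])^2 + diff(coords[, 2L])^2)
  tot <- sum(d)
  if (closed) tot <- tot + sqrt(sum((coords[1L, ] - coords[n, ])^2))
  tot
}

#' Contour length of a backbone
#'
#' Polyline length of the ordered central ridge, converted to um. The raw
#' chain counts diagonal steps as sqrt(2) px; a light moving-average
#' smoothing (window `smooth_window`) removes the digitization zigzag bias
#' before summing, leaving straight and 45-degree paths unchanged. For
#' multi-loop topologies the loop/path lengths are summed.
#'
#' @param bb a [extract_backbone()] result.
#' @param pixel_size_um um per pixel.
#' @param smooth_window odd window for path smoothing; 0 disables.
#' @return length in um (0 for an empty backbone).
#' @export
contour_length <- function(bb, pixel_size_um, smooth_window = 5L) {
  stopifnot(inherits(bb, "backbone"))
  if (length(bb$paths) == 0L) return(0)
  tot <- 0
  for (i in seq_along(bb$paths)) {
    coords <- bb$paths[[i]]
    if (smooth_window >= 3L)
      coords <- smooth_path(coords, bb$closed[i], smooth_window)
    tot <- tot + path_length(coords, bb$closed[i])
  }
  tot * pixel_size_um
}

#' Mean FWHM width along the backbone
#'
#' At stations every `station_step` px of arc length, samples the intensity
#' profile perpendicular to the local tangent (length `2*profile_half_px`,
#' bilinear interpolation) and measures the full width at half maximum above
#' the local background (mean of the profile tails) by linear crossing.
#' Stations whose profile leaves the frame or has no half-max crossing are
#' skipped and counted.
#'
#' @param bb a [extract_backbone()] result.
#' @param image intensity image (background-subtracted DNA channel).
#' @param pixel_size_um um per pixel.
#' @param station_step arc-length spacing of stations, px.
#' @param profile_half_px half-length of the perpendicular profile, px; the
#'   default 12 px leaves the outer ~1.5 px as local-background tails well
#'   clear of a diffraction-scale tube.
#' @param min_stations minimum number of valid stations; fewer yields NA.
#' @return list: `width_fwhm_um` (mean over stations, NA if too few),
#'   `n_stations`, `n_skipped`.
#' @export
width_fwhm <- function(bb, image, pixel_size_um, station_step = 3,
                       profile_half_px = 12, min_stations = 10L) {
  stopifnot(inherits(bb, "backbone"))
  widths <- numeric(0); skipped <- 0L
  ts <- seq(-profile_half_px, profile_half_px, by = 0.25)
  for (i in seq_along(bb$paths)) {
    coords <- smooth_path(bb$paths[[i]], bb$closed[i], 5L)
    n <- nrow(coords)
    if (n < 5L) next
    if (bb$closed[i]) coords <- rbind(coords, coords[1L, ])
    seg <- sqrt(diff(coords[, 1L])^2 + diff(coords[, 2L])^2)
    s <- c(0, cumsum(seg))
    stations <- seq(0, s[length(s)] - ifelse(bb$closed[i], 1e-9, 0),
                    by = station_step)
    fx <- stats::approxfun(s, coords[, 1L]); fy <- stats::approxfun(s, coords[, 2L])
    for (st in stations) {
      eps <- min(2, s[length(s)] / 4)
      s0 <- max(0, st - eps); s1 <- min(s[length(s)], st + eps)
      tx <- fx(s1) - fx(s0); ty <- fy(s1) - fy(s0)
      nt <- sqrt(tx^2 + ty^2)
      if (nt == 0) { skipped <- skipped + 1L; next }
      nx <- -ty / nt; ny <- tx / nt
      px <- fx(st) + ts * nx; py <- fy(st) + ts * ny
      prof <- bilinear(image, px, py)
      if (anyNA(prof)) { skipped <- skipped + 1L; next }
      tails <- abs(ts) >= profile_half_px - 1.5
      bg <- mean(prof[tails])
      centr <- which(abs(ts) <= 3)
      pk <- centr[which.max(prof[centr])]
      if (prof[pk] <= bg) { skipped <- skipped + 1L; next }
      half <- bg + (prof[pk] - bg) / 2
      li <- pk; while (li > 1L && prof[li] > half) li <- li - 1L
      ri <- pk; while (ri < length(ts) && prof[ri] > half) ri <- ri + 1L
      if (prof[li] > half || prof[ri] > half) { skipped <- skipped + 1L; next }
      tl <- ts[li] + (half - prof[li]) / (prof[li + 1L] - prof[li]) * 0.25
      tr <- ts[ri] - (half - prof[ri]) / (prof[ri - 1L] - prof[ri]) * 0.25
      widths <- c(widths, (tr - tl) * pixel_size_um)
    }
  }
  if (length(widths) < min_stations)
    return(list(width_fwhm_um = NA_real_, n_stations = length(widths),
                n_skipped = skipped))
  list(width_fwhm_um = mean(widths), n_stations = length(widths),
       n_skipped = skipped)
}

#' Feret (maximum caliper) diameter of a pixel cluster
#'
#' Maximum pairwise distance over convex-hull pixel centers, calibrated.
#'
#' @param coords n x 2 matrix of (x, y) pixel coordinates, or a logical mask.
#' @param pixel_size_um um per pixel.
#' @return diameter in um; 0 for a single pixel.
#' @export
feret_diameter <- function(coords, pixel_size_um) {
  if (is.matrix(coords) && (is.logical(coords) ||
      all(coords %in% c(0, 1)) && nrow(coords) > 2 && ncol(coords) > 2)) {
    idx <- which(coords != 0, arr.ind = TRUE)
    coords <- cbind(x = idx[, 2L], y = idx[, 1L])
  }
  coords <- unique(coords[, 1:2, drop = FALSE])
  n <- nrow(coords)
  if (n <= 1L) return(0)
  if (n == 2L) return(sqrt(sum((coords[1L, ] - coords[2L, ])^2)) * pixel_size_um)
  hull <- grDevices::chull(coords[, 1L], coords[, 2L])
  hc <- coords[hull, , drop = FALSE]
  max(stats::dist(hc)) * pixel_size_um
}

#' Classify backbone topology
#'
#' One clean loop is a toroid; two loops sharing a node form a figure-eight
#' (catenated sister dimers); no loop is an open nucleoid; anything else is
#' complex.
#'
#' @param bb a [extract_backbone()] result.
#' @return one of `"toroid"`, `"figure_eight"`, `"open"`, `"complex"`.
#' @export
classify_topology <- function(bb) {
  stopifnot(inherits(bb, "backbone"))
  if (bb$cycle_count == 1L && bb$branch_nodes == 0L) return("toroid")
  if (bb$cycle_count == 2L && bb$branch_nodes >= 1L) return("figure_eight")
  if (bb$cycle_count == 0L) return("open")
  "complex"
}
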