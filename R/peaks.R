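# Circular-genome window analysis of binding-site peaks around oriC.

#' Count peaks upstream and downstream of ori
#'
#' A peak belongs to a window of `window_bp` on either side of the ori
#' position when its midpoint lies within that distance along the circular
#' genome: increasing-coordinate side counts as upstream, decreasing side
#' as downstream. Wrapping intervals and wrapping windows are handled; a
#' midpoint exactly at ori counts for neither side and is reported.
#'
#' @param peaks a [read_peaks()] result.
#' @param window_bp half-window size in bp; must be <= genome_length / 2.
#' @return list: `n_upstream`, `n_downstream`, `n_at_ori`.
#' @export
window_peaks <- function(peaks, window_bp) {
  L <- attr(peaks, "genome_length_bp")
  ori <- attr(peaks, "ori_position_bp")
  stopifnot(!is.null(L), !is.null(ori), window_bp <= L / 2)
  wraps <- peaks$end <= peaks$start
  span <- ifelse(wraps, peaks$end + L - peaks$start, peaks$end - peaks$start)
  mid <- (peaks$start + span / 2) %% L
  # signed circular offset from ori in (-L/2, L/2]
  d <- ((mid - ori + L / 2) %% L) - L / 2
  list(n_upstream = sum(d > 0 & d <= window_bp),
       n_downstream = sum(d < 0 & -d <= window_bp),
       n_at_ori = sum(d == 0))
}

#' Relative arm excess of upstream peaks
#'
#' `100 * (n_up - n_down) / n_down`: the percentage by which upstream peaks
#' exceed downstream peaks.
#'
#' @param n_up,n_down non-negative counts.
#' @return percent; NA with attribute `undefined = TRUE` when
#'   `n_down == 0`.
#' @export
arm_excess <- function(n_up, n_down) {
  if (n_down == 0) return(structure(NA_real_, undefined = TRUE))
  100 * (n_up - n_down) / n_down
}
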