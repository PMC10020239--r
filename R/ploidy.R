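# Normalized sum chromosome signal, ori/ter count tables, and chromosome
# multiplicity classification.

#' Normalized sum chromosome signal
#'
#' Divides each cell's summed background-subtracted DNA intensity by the
#' median over reference cells carrying a single ori and a single ter, so
#' the reference population has median 1 by construction and a dimer with
#' twice the DNA content scores 2. Normalization by the reference median is
#' invariant to a uniform gain applied to the whole field of view.
#'
#' @param sum_dna numeric vector of per-cell summed DNA intensities.
#' @param ori_count,ter_count integer vectors of focus counts.
#' @return numeric vector of normalized sums; errors when no reference
#'   (1 ori, 1 ter) cell exists.
#' @export
normalized_sum_signal <- function(sum_dna, ori_count, ter_count) {
  ref <- ori_count == 1L & ter_count == 1L & !is.na(sum_dna)
  if (!any(ref, na.rm = TRUE))
    stop("no reference cells with 1 ori and 1 ter focus")
  sum_dna / stats::median(sum_dna[which(ref)])
}

#' Group ori counts by ter count
#'
#' Cells are grouped by their ter focus count; groups smaller than
#' `min_group` are excluded from the table and reported in the
#' `excluded` attribute.
#'
#' @param ori_count,ter_count integer vectors (QC-passed cells).
#' @param min_group minimum group size retained.
#' @return data.frame: ter_count, n, mean_ori, sd_ori; attribute `excluded`
#'   (data.frame of dropped groups) and attribute `histograms` (per retained
#'   group, the table of ori counts).
#' @export
ori_per_ter_table <- function(ori_count, ter_count, min_group = 6L) {
  ok <- !is.na(ori_count) & !is.na(ter_count)
  ori_count <- ori_count[ok]; ter_count <- ter_count[ok]
  groups <- sort(unique(ter_count))
  tab <- do.call(rbind, lapply(groups, function(g) {
    v <- ori_count[ter_count == g]
    data.frame(ter_count = g, n = length(v), mean_ori = mean(v),
               sd_ori = stats::sd(v))
  }))
  small <- tab$n < min_group
  hists <- lapply(groups[!small], function(g) table(ori_count[ter_count == g]))
  names(hists) <- as.character(groups[!small])
  structure(tab[!small, , drop = FALSE],
            excluded = tab[small, , drop = FALSE],
            histograms = hists)
}

#' Gaussian fits of normalized sums per ori-count group
#'
#' Maximum-likelihood Gaussian fit (sample mean and sd) of the normalized
#' sum signal within each ori-count group; a histogram least-squares variant
#' is available for cross-checking.
#'
#' @param normalized_sum numeric vector.
#' @param ori_count integer grouping vector.
#' @param min_n minimum group size fitted.
#' @param method `"ml"` (sample moments) or `"histogram"` (least-squares fit
#'   of a Gaussian to binned counts).
#' @return data.frame: ori_count, n, mean, sd, sd_degenerate flag.
#' @export
fit_gaussian_means <- function(normalized_sum, ori_count, min_n = 3L,
                               method = c("ml", "histogram")) {
  method <- match.arg(method)
  ok <- !is.na(normalized_sum) & !is.na(ori_count)
  normalized_sum <- normalized_sum[ok]; ori_count <- ori_count[ok]
  groups <- sort(unique(ori_count))
  out <- do.call(rbind, lapply(groups, function(g) {
    v <- normalized_sum[ori_count == g]
    if (length(v) < min_n) return(NULL)
    if (method == "ml") {
      mu <- mean(v); sdv <- stats::sd(v)
    } else {
      hh <- graphics::hist(v, breaks = "FD", plot = FALSE)
      fit <- try(stats::nls(counts ~ a * exp(-(mids - mu)^2 / (2 * s^2)),
                            data = data.frame(counts = hh$counts, mids = hh$mids),
                            start = list(a = max(hh$counts), mu = mean(v),
                                         s = max(stats::sd(v), 1e-3))),
                 silent = TRUE)
      if (inherits(fit, "try-error")) { mu <- mean(v); sdv <- stats::sd(v) }
      else { mu <- stats::coef(fit)[["mu"]]; sdv <- abs(stats::coef(fit)[["s"]]) }
    }
    data.frame(ori_count = g, n = length(v), mean = mu, sd = sdv,
               sd_degenerate = is.na(sdv) || sdv == 0)
  }))
  out
}

#' Classify chromosome multiplicity
#'
#' Monomer: at most 2 ori, 1 ter, normalized sum below `thresholds[1]`.
#' Dimer: 2 ori, 2 ter, normalized sum in `[thresholds[1], thresholds[2])`.
#' Multimer: everything else with 2 or more ter foci; remaining cells fall
#' back on the normalized sum alone. Thresholds default to the midpoints
#' between expected integer chromosome equivalents.
#'
#' @param ori_count,ter_count integer scalars or vectors.
#' @param normalized_sum numeric, same length.
#' @param thresholds c(monomer/dimer, dimer/multimer) cutoffs.
#' @return character vector: "monomer", "dimer", or "multimer".
#' @export
classify_multiplicity <- function(ori_count, ter_count, normalized_sum,
                                  thresholds = c(1.5, 3)) {
  mapply(function(o, t, s) {
    if (is.na(o) || is.na(t) || is.na(s)) return(NA_character_)
    if (o <= 2L && t == 1L && s < thresholds[1L]) return("monomer")
    if (o == 2L && t == 2L && s >= thresholds[1L] && s < thresholds[2L])
      return("dimer")
    if (t >= 2L) return("multimer")
    if (s < thresholds[1L]) "monomer" else
      if (s < thresholds[2L]) "dimer" else "multimer"
  }, ori_count, ter_count, normalized_sum, USE.NAMES = FALSE)
}
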