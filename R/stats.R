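# Population statistics and significance conventions.

#' Single-factor (one-way) ANOVA
#'
#' Classic between/within sum-of-squares decomposition with p from the F
#' distribution on (k - 1, N - k) degrees of freedom (equal variances
#' assumed, as in a single-factor ANOVA table).
#'
#' @param groups list of numeric vectors, each of length >= 2.
#' @return list: `F`, `p`, `df` (c(between, within)), `flag` ("" normally;
#'   "zero_within_variance" gives p = 0, "identical_data" gives F = NaN).
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(vapply(groups, length, integer(1L)) >= 2L))
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(seq_along(groups), vapply(groups, length, integer(1L))))
  k <- length(groups); N <- length(values)
  df <- c(k - 1L, N - k)
  means <- vapply(groups, mean, numeric(1L))
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1L)))
  if (ssw == 0) {
    if (all(means == means[1L]))
      return(list(F = NaN, p = NA_real_, df = df, flag = "identical_data"))
    return(list(F = Inf, p = 0, df = df, flag = "zero_within_variance"))
  }
  ft <- stats::oneway.test(values ~ fac, var.equal = TRUE)
  list(F = unname(ft$statistic), p = unname(ft$p.value), df = df, flag = "")
}

#' Significance stars
#'
#' Star conventions: ns for p > 0.05, * for 0.01 < p <= 0.05, ** for
#' 0.001 < p <= 0.01, *** for 0.0001 < p <= 0.001, **** for p <= 0.0001.
#' Boundary p values go to the more significant bin.
#'
#' @param p p value in \[0, 1\].
#' @return one of "ns", "*", "**", "***", "****".
#' @export
significance_stars <- function(p) {
  if (is.na(p) || p < 0 || p > 1) stop("p must be in [0, 1]")
  if (p <= 1e-4) "****" else if (p <= 1e-3) "***" else
    if (p <= 1e-2) "**" else if (p <= 0.05) "*" else "ns"
}

#' Population summary report
#'
#' Per-strain summaries of every numeric metric (n, mean, sd, sem, median --
#' medians matter for the asymmetricity distributions), binomial sds for the
#' binary colocalization fractions, and a one-way ANOVA with stars across
#' strains for each metric. Deterministic: identical input tables yield
#' identical reports.
#'
#' @param table per-cell results (see [write_results()]); discarded cells
#'   are dropped.
#' @param group_col grouping column, default "strain_label".
#' @param metrics numeric columns to summarize; defaults to the standard
#'   quantification columns present in the table.
#' @return list of class `population_report`: `summary` (data.frame),
#'   `binary` (data.frame of binary colocalization fractions), `anova`
#'   (data.frame metric/F/p/stars).
#' @export
summarize_population <- function(table, group_col = "strain_label",
                                 metrics = NULL) {
  if (!is.null(table$discarded)) table <- table[!(table$discarded %in% TRUE), ]
  if (nrow(table) == 0L) stop("no QC-passed cells to summarize")
  if (is.null(metrics))
    metrics <- intersect(c("dna_in_mukb_percent", "mukb_in_dna_percent",
                           "compaction_ratio", "contour_length_um",
                           "width_fwhm_um", "mukb_feret_um", "asym_dna",
                           "asym_mukb", "normalized_sum", "sum_dna_intensity"),
                         names(table))
  groups <- unique(table[[group_col]])
  rows <- list(); av <- list()
  for (m in metrics) {
    for (g in groups) {
      v <- table[[m]][table[[group_col]] == g]
      v <- v[!is.na(v)]
      n <- length(v)
      if (n == 0L) { warning("empty group ", g, " for ", m); next }
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, group = g, n = n, mean = mean(v),
        sd = if (n > 1L) stats::sd(v) else NA_real_,
        sem = if (n > 1L) stats::sd(v) / sqrt(n) else NA_real_,
        median = stats::median(v))
    }
    gl <- lapply(groups, function(g) {
      v <- table[[m]][table[[group_col]] == g]; v[!is.na(v)]
    })
    gl <- gl[vapply(gl, length, integer(1L)) >= 2L]
    if (length(gl) >= 2L) {
      a <- one_way_anova(gl)
      av[[length(av) + 1L]] <- data.frame(
        metric = m, F = a$F, p = a$p,
        stars = if (is.na(a$p)) NA_character_ else significance_stars(a$p))
    }
  }
  binary <- NULL
  for (m in intersect(c("ori_overlaps_mukb", "ter_overlaps_mukb"), names(table))) {
    for (g in groups) {
      v <- table[[m]][table[[group_col]] == g]
      v <- v[!is.na(v)]
      if (!length(v)) next
      f <- mean(v)
      binary <- rbind(binary, data.frame(
        metric = m, group = g, n = length(v), fraction = f,
        sd_binomial = sqrt(f * (1 - f) / length(v))))
    }
  }
  structure(list(summary = do.call(rbind, rows),
                 binary = binary,
                 anova = if (length(av)) do.call(rbind, av) else NULL),
            class = "population_report")
}

#' @export
print.population_report <- function(x, ...) {
  cat("Population summary\n==================\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$binary)) {
    cat("\nBinary colocalization\n")
    print(x$binary, row.names = FALSE)
  }
  if (!is.null(x$anova)) {
    cat("\nOne-way ANOVA across groups\n")
    print(x$anova, row.names = FALSE)
  }
  invisible(x)
}
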