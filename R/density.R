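## Density grouping and summary layer: monolayers are binned by their mean
## cell-cell distance R_cc into contiguous equal-width intervals (D1, D2,
## ...; width 2.6 um by default), summarized per interval, and compared
## pairwise with the two-sided Wilcoxon rank-sum test.

#' Density binning scheme
#'
#' Contiguous, non-overlapping, half-open intervals
#' `[origin + k w, origin + (k+1) w)` of equal width `w` labelled D1..Dk.
#' The origin defaults to the minimum observed R_cc when binning (the
#' conventional D1 left edge is configurable).
#'
#' @param intervalWidth interval width in um (default 2.6).
#' @param origin left edge of D1 (um); NA = minimum observed R_cc.
#' @param nIntervals number of labelled intervals (default 6, D1-D6).
#' @param histogramBinWidth bin width for R_cc histograms (um, default
#'   0.2).
#' @return A `DensityBinning` list-like object.
#' @export
densityBinning <- function(intervalWidth = 2.6, origin = NA_real_,
                           nIntervals = 6L, histogramBinWidth = 0.2) {
  stopifnot(intervalWidth > 0, nIntervals >= 1L, histogramBinWidth > 0)
  structure(list(intervalWidth = intervalWidth, origin = origin,
                 nIntervals = as.integer(nIntervals),
                 histogramBinWidth = histogramBinWidth,
                 labels = paste0("D", seq_len(nIntervals))),
            class = "DensityBinning")
}

#' Assign monolayers to density intervals
#'
#' Each R_cc value falls into exactly one half-open interval (values on an
#' edge go to the interval on the right). Values beyond the labelled span
#' are assigned to an overflow bin with a warning.
#'
#' @param rccValues numeric vector of per-monolayer R_cc (um), or a list
#'   of [Monolayer-class] objects.
#' @param binning a [densityBinning()].
#' @return A factor of interval labels, with attribute `"edges"` (the
#'   interval boundaries).
#' @export
binMonolayers <- function(rccValues, binning = densityBinning()) {
  if (is.list(rccValues)) {
    rccValues <- vapply(rccValues, function(m) rcc(m), numeric(1))
  }
  origin <- if (is.na(binning$origin)) min(rccValues) else binning$origin
  w <- binning$intervalWidth
  k <- floor((rccValues - origin) / w + 1e-9)
  over <- k < 0 | k >= binning$nIntervals
  if (any(over)) {
    warning(sprintf("%d monolayer(s) outside the labelled span; assigned to 'overflow'", sum(over)))
  }
  lab <- ifelse(over, "overflow", paste0("D", k + 1L))
  levels <- c(binning$labels, if (any(over)) "overflow")
  out <- factor(lab, levels = levels)
  attr(out, "edges") <- origin + w * (0:binning$nIntervals)
  out
}

#' R_cc histogram counts
#'
#' Histogram of mean cell-cell distances with the binning scheme's
#' histogram bin width.
#'
#' @inheritParams binMonolayers
#' @return A data.frame with `mid`, `count`.
#' @export
rccHistogram <- function(rccValues, binning = densityBinning()) {
  if (is.list(rccValues)) {
    rccValues <- vapply(rccValues, function(m) rcc(m), numeric(1))
  }
  w <- binning$histogramBinWidth
  lo <- floor(min(rccValues) / w) * w
  breaks <- seq(lo, max(rccValues) + w, by = w)
  h <- graphics::hist(rccValues, breaks = breaks, plot = FALSE, right = FALSE)
  data.frame(mid = h$mids, count = h$counts)
}

#' Per-monolayer summary row
#'
#' Computes the quantities the interval summaries aggregate: R_cc, mean
#' shape index, ensemble-averaged shape function magnitudes, crossover
#' scale and defect densities at the crossover (interior cells only).
#'
#' @param monolayer a [Monolayer-class].
#' @param fov field of view for the coarse-graining (um).
#' @param defects logical: also run defect detection (slower).
#' @return One-row data.frame.
#' @export
monolayerSummary <- function(monolayer, fov = 124, defects = FALSE) {
  st <- shapeTable(monolayer)
  int <- !st$is_border
  an <- crossoverAnalysis(monolayer, fov = fov)
  out <- data.frame(
    n_cells = sum(int),
    rcc = rcc(monolayer),
    mean_p0 = mean(st$p0[int]),
    mean_abs_gamma2 = mean(st$abs_gamma2[int]),
    mean_abs_gamma6 = mean(st$abs_gamma6[int]),
    r_cross_norm = crossoverScale(an$profile),
    crossover_status = an$profile@status
  )
  if (defects) {
    for (p in c(2L, 6L)) {
      dd <- defectDensityVsRadius(monolayer, p = p, fov = fov, analysis = an)
      out[[paste0("defects_per_100_at_rx_p", p)]] <-
        if (is.null(dd$atCrossover)) NA_real_ else dd$atCrossover$density_per_100
    }
  }
  out
}

#' Interval summary table
#'
#' Aggregates per-monolayer summaries by density interval: monolayer and
#' cell counts, mean and standard deviation of the shape index and shape
#' function magnitudes, the hexatic-nematic difference, the mean
#' normalized crossover scale, and (when present) defect densities.
#'
#' @param summaries data.frame of [monolayerSummary()] rows.
#' @param intervals factor from [binMonolayers()] (same order).
#' @return A data.frame with one row per non-empty interval.
#' @export
intervalSummary <- function(summaries, intervals) {
  stopifnot(nrow(summaries) == length(intervals))
  sp <- split(summaries, intervals, drop = TRUE)
  rows <- lapply(names(sp), function(lv) {
    s <- sp[[lv]]
    r <- data.frame(
      interval = lv,
      n_monolayers = nrow(s),
      n_cells = sum(s$n_cells),
      mean_rcc = mean(s$rcc),
      mean_p0 = mean(s$mean_p0), sd_p0 = stats::sd(s$mean_p0),
      mean_abs_gamma2 = mean(s$mean_abs_gamma2),
      sd_abs_gamma2 = stats::sd(s$mean_abs_gamma2),
      mean_abs_gamma6 = mean(s$mean_abs_gamma6),
      sd_abs_gamma6 = stats::sd(s$mean_abs_gamma6),
      hexatic_excess = mean(s$mean_abs_gamma6 - s$mean_abs_gamma2),
      mean_r_cross_norm = mean(s$r_cross_norm, na.rm = TRUE),
      n_crossover = sum(!is.na(s$r_cross_norm))
    )
    for (cn in grep("^defects_per_100", names(s), value = TRUE)) {
      r[[paste0("mean_", cn)]] <- mean(s[[cn]], na.rm = TRUE)
    }
    r
  })
  do.call(rbind, rows)
}

#' Two-sample rank-sum comparison
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test between two samples,
#' with the conventional significance labels: `*` for p <= 0.05, `**` for
#' p < 0.01, `***` for p < 0.001, `****` for p < 0.0001, `ns` for
#' p > 0.05.
#'
#' @param a,b numeric samples (each n >= 2).
#' @param exact passed to [stats::wilcox.test()] (default NULL: exact for
#'   small samples without ties).
#' @return A list: `statistic` (W), `pValue`, `label`.
#' @export
compareGroups <- function(a, b, exact = NULL) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 observations")
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                            exact = exact))
  list(statistic = unname(wt$statistic), pValue = wt$p.value,
       label = significanceLabel(wt$p.value))
}

#' Significance label for a p-value
#'
#' @param p p-value.
#' @return `"****"`, `"***"`, `"**"`, `"*"` or `"ns"`.
#' @export
significanceLabel <- function(p) {
  if (p < 0.0001) "****"
  else if (p < 0.001) "***"
  else if (p < 0.01) "**"
  else if (p <= 0.05) "*"
  else "ns"
}
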