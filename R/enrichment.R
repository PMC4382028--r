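#' Crossover windows for breakpoint-feature association
#'
#' For each classified event, delineates the window most likely to have
#' contained the recombinogenic DNA break: from the last marker heterozygous
#' in both sectors to the first marker of the distal reciprocal-LOH zone,
#' spanning the full conversion tract (union over both sectors). For a
#' conversionless crossover this reduces to the shared transition interval.
#' Events lacking a proximal heterozygous flank (tract running off the map)
#' are skipped with a warning.
#'
#' @param events list of `conversion_event` objects.
#' @return A `co_windows` data frame: `event_id`, `left_bp`, `right_bp`.
#' @export
co_windows <- function(events) {
  rows <- lapply(seq_along(events), function(i) {
    ev <- events[[i]]
    if (!ev$has_prox) {
      warning("event ", i, " lacks a proximal heterozygous flank; skipped")
      return(NULL)
    }
    regions <- ev$regions
    data.frame(event_id = if (is.na(ev$event_id)) as.character(i) else
                 ev$event_id,
               left_bp = regions$end_bp[1L],
               right_bp = regions$start_bp[ev$recip_start],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(event_id = character(0), left_bp = numeric(0),
                      right_bp = numeric(0))
  class(out) <- c("co_windows", "data.frame")
  out
}

#' Fraction of the screened genome inside crossover windows
#'
#' Sums the window lengths (coordinate differences, `right - left`) and
#' divides by the total screened space, `region_length * n_sectors`.
#'
#' @param windows a `co_windows` data frame (or any data frame with
#'   `left_bp` and `right_bp`).
#' @param region_length length of the screened interval per sector, bp.
#' @param n_sectors number of sectors screened.
#' @param merge if `TRUE`, overlapping windows are merged before summing
#'   (sensitivity analysis); by default windows are summed per event.
#' @return The dimensionless fraction `f` in \[0, 1\].
#' @export
window_fraction <- function(windows, region_length, n_sectors, merge = FALSE) {
  if (region_length <= 0) stop("region_length must be positive")
  if (n_sectors < 1) stop("n_sectors must be >= 1")
  if (nrow(windows) == 0L) return(0)
  if (any(windows$right_bp <= windows$left_bp))
    stop("windows must have left_bp < right_bp")
  total <- if (merge) {
    ir <- IRanges::reduce(IRanges::IRanges(start = windows$left_bp,
                                           end = windows$right_bp))
    sum(IRanges::end(ir) - IRanges::start(ir))
  } else {
    sum(windows$right_bp - windows$left_bp)
  }
  f <- total / (region_length * n_sectors)
  if (f > 1)
    stop("summed windows exceed the screened space (f > 1)")
  f
}

#' Expected number of features inside crossover windows
#'
#' Under a uniform null, the expected count is the total number of feature
#' replicates in the screened space (features in the region times sectors)
#' multiplied by the window fraction.
#'
#' @param n_features_region number of feature instances in the screened
#'   region (one sector).
#' @param n_sectors number of sectors.
#' @param f window fraction from [window_fraction()].
#' @return Expected count (real).
#' @export
expected_count <- function(n_features_region, n_sectors, f) {
  if (n_features_region < 0 || n_sectors < 0) stop("counts must be >= 0")
  if (f < 0 || f > 1) stop("f must be in [0, 1]")
  n_features_region * n_sectors * f
}

#' Genomic feature track
#'
#' A named set of intervals (1-based inclusive internally). With
#' `midpoint_rule = TRUE` each interval is collapsed to its midpoint before
#' overlap testing — used for large elements (Ty retrotransposons) whose
#' size would otherwise make them overlap windows too easily.
#'
#' @param name feature class name.
#' @param intervals data frame with `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @param midpoint_rule logical.
#' @return A `feature_track` object.
#' @export
feature_track <- function(name, intervals, midpoint_rule = FALSE) {
  stopifnot(is.data.frame(intervals),
            all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$end < intervals$start))
    stop("feature intervals must have start <= end")
  intervals <- intervals[order(intervals$chrom, intervals$start), ,
                         drop = FALSE]
  rownames(intervals) <- NULL
  structure(list(name = name, intervals = intervals,
                 midpoint_rule = isTRUE(midpoint_rule)),
            class = "feature_track")
}

#' Observed feature count inside crossover windows
#'
#' Counts feature instances, per sector replicate, that overlap the
#' crossover windows. Each window belongs to one sector (one event), so the
#' observed count is the number of (feature, sector) pairs in which the
#' feature overlaps that sector's window set; with one window per sector
#' this is the number of overlapping feature-window pairs. Interval features
#' overlap when the intersection is non-empty; midpoint-rule features
#' overlap when the interval midpoint lies inside a window.
#'
#' @param features a [feature_track()].
#' @param windows a `co_windows` data frame.
#' @param sector optional vector assigning each window to a sector (default:
#'   `event_id`, i.e. one sector per window); features overlapping several
#'   windows of the same sector are counted once for that sector.
#' @return Integer count.
#' @export
observed_count <- function(features, windows, sector = NULL) {
  stopifnot(inherits(features, "feature_track"))
  if (nrow(windows) == 0L) return(0L)
  iv <- features$intervals
  if (features$midpoint_rule) {
    mid <- floor((iv$start + iv$end) / 2)
    fr <- IRanges::IRanges(start = mid, end = mid)
  } else {
    fr <- IRanges::IRanges(start = iv$start, end = iv$end)
  }
  wr <- IRanges::IRanges(start = windows$left_bp, end = windows$right_bp)
  if (is.null(sector)) sector <- windows$event_id
  hits <- IRanges::findOverlaps(fr, wr)
  pairs <- unique(data.frame(f = S4Vectors::queryHits(hits),
                             s = sector[S4Vectors::subjectHits(hits)]))
  nrow(pairs)
}

#' Chi-square test of feature enrichment in crossover windows
#'
#' One-degree-of-freedom goodness of fit over the two cells in-window /
#' out-of-window:
#' \deqn{\chi^2 = (O - E)^2/E + ((N - O) - (N - E))^2/(N - E)}
#' with `O` observed, `E` expected and `N` the total feature replicates. No
#' continuity correction. When `E < 5` the result carries a low-expected
#' warning flag (the asymptotic p-value is then unreliable).
#'
#' @param observed observed in-window count.
#' @param expected expected in-window count (> 0, < `n_total`).
#' @param n_total total feature replicates in the screened space.
#' @return List: `statistic`, `p_value`, `low_expected`.
#' @export
enrichment_test <- function(observed, expected, n_total) {
  if (expected <= 0) stop("expected must be positive")
  if (n_total < observed) stop("n_total must be >= observed")
  if (expected >= n_total) stop("expected must be below n_total")
  stat <- (observed - expected)^2 / expected +
    (observed - expected)^2 / (n_total - expected)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       low_expected = expected < 5)
}

#' Feature-enrichment analysis over a set of tracks
#'
#' Runs the full association analysis for each feature class: window
#' fraction, expected and observed counts, and the chi-square comparison.
#' Classes are tested independently (per-class reporting); an optional
#' Bonferroni correction across classes is available but off by default.
#'
#' @param tracks list of [feature_track()] objects.
#' @param windows a `co_windows` data frame.
#' @param region_length screened interval length per sector, bp.
#' @param n_sectors number of sectors screened.
#' @param merge merge overlapping windows before summing lengths.
#' @param bonferroni apply Bonferroni correction across feature classes.
#' @return An `enrichment_result` data frame: `class`, `n_total`, `f`,
#'   `expected`, `observed`, `chi2`, `p`, `low_expected` (and `p_adj` when
#'   `bonferroni`).
#' @export
run_enrichment <- function(tracks, windows, region_length, n_sectors,
                           merge = FALSE, bonferroni = FALSE) {
  f <- window_fraction(windows, region_length, n_sectors, merge = merge)
  rows <- lapply(tracks, function(tk) {
    n_region <- nrow(tk$intervals)
    n_total <- n_region * n_sectors
    exp_ct <- expected_count(n_region, n_sectors, f)
    obs <- observed_count(tk, windows)
    tst <- enrichment_test(obs, exp_ct, n_total)
    data.frame(class = tk$name, n_total = n_total, f = f,
               expected = exp_ct, observed = obs,
               chi2 = tst$statistic, p = tst$p_value,
               low_expected = tst$low_expected, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (bonferroni) out$p_adj <- pmin(1, out$p * nrow(out))
  class(out) <- c("enrichment_result", "data.frame")
  out
}
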