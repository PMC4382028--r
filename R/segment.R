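#' Zygosity-calling thresholds
#'
#' Calling bands on the normalized hybridization ratio scale. A SNP is called
#' heterozygous when both allele ratios fall inside the het band; homozygous
#' for one parent when that allele's ratio is at least `hom_present` and the
#' other allele's ratio at most `hom_absent`. The defaults sit inside the
#' two-copy (1.5-2) and zero-copy (0-0.5) calling ranges with a guard gap, so
#' ratios in the unclaimed territory between bands are called AMBIGUOUS
#' rather than forced into a state.
#'
#' @param het_lo,het_hi heterozygous band (default 0.7-1.3).
#' @param hom_present minimum ratio of the retained allele for a homozygous
#'   call (default 1.4).
#' @param hom_absent maximum ratio of the lost allele for a homozygous call
#'   (default 0.6).
#' @return A `zygosity_thresholds` list.
#' @export
zygosity_thresholds <- function(het_lo = 0.7, het_hi = 1.3,
                                hom_present = 1.4, hom_absent = 0.6) {
  if (!(het_lo < het_hi)) stop("het band must have het_lo < het_hi")
  if (hom_absent >= het_lo || hom_present <= het_hi)
    stop("homozygous bands must not overlap the het band")
  structure(list(het_lo = het_lo, het_hi = het_hi,
                 hom_present = hom_present, hom_absent = hom_absent),
            class = "zygosity_thresholds")
}

#' Call per-SNP zygosity from allele-ratio pairs
#'
#' @param profile a `ratio_profile` (see [ratio_profile()]), or a data frame
#'   with `ratio_A` and `ratio_B` columns.
#' @param thresholds a [zygosity_thresholds()] configuration.
#' @return A character vector, one call per SNP, in
#'   `c("HET", "HOM_A", "HOM_B", "AMBIGUOUS")`.
#' @export
#' @examples
#' m <- snp_map("chrIV", c(100, 200, 300))
#' call_zygosity(ratio_profile(m, c(1.0, 1.8, 1.35), c(1.0, 0.2, 0.65)))
call_zygosity <- function(profile, thresholds = zygosity_thresholds()) {
  rA <- profile$ratio_A
  rB <- profile$ratio_B
  if (is.null(rA) || is.null(rB))
    stop("profile must have ratio_A and ratio_B columns")
  if (!all(is.finite(rA)) || !all(is.finite(rB)) || any(rA < 0) || any(rB < 0))
    stop("ratios must be finite and non-negative")
  th <- thresholds
  calls <- rep("AMBIGUOUS", length(rA))
  het <- rA >= th$het_lo & rA <= th$het_hi & rB >= th$het_lo & rB <= th$het_hi
  homA <- rA >= th$hom_present & rB <= th$hom_absent
  homB <- rB >= th$hom_present & rA <= th$hom_absent
  calls[het] <- "HET"
  calls[homA] <- "HOM_A"
  calls[homB] <- "HOM_B"
  calls
}

#' Segment a zygosity track into LOH segments and transition intervals
#'
#' Collapses the non-ambiguous calls of one sector into maximal runs of
#' constant state (segments) and records the transition between each
#' adjacent pair of segments as the interval bracketed by the flanking SNPs:
#' the last SNP of the left-hand state and the first SNP of the right-hand
#' state. Ambiguous calls are skipped (they belong to no segment). Isolated
#' state flips shorter than `min_run` SNPs whose two neighbouring runs share
#' a state are reassigned to that flanking state before segmenting, which
#' absorbs sporadic miscalls without moving transition coordinates off
#' observed SNPs; reassignment is repeated until stable. `min_run = 1`
#' disables smoothing.
#'
#' @param calls character vector of per-SNP calls (from [call_zygosity()]).
#' @param map the [snp_map] the calls live on.
#' @param min_run minimum run length (in SNPs) for a state flip to survive
#'   smoothing. Default 2.
#' @param smooth_window size (in SNPs) of the window a flip must fit inside,
#'   together with one flanking SNP on each side, to count as isolated;
#'   i.e. only runs of at most `smooth_window - 2` SNPs are reassigned.
#'   Default 3.
#' @return An object of class `loh_segments`: list with `segments` (data
#'   frame: `state`, `first_snp`, `last_snp` — indices into the map —
#'   `start_bp`, `end_bp`, `n_snps`) and `transitions` (data frame:
#'   `left_bp`, `right_bp`, `left_state`, `right_state`). An all-ambiguous
#'   profile yields zero-row tables, not an error.
#' @export
segment_profile <- function(calls, map, min_run = 2L, smooth_window = 3L) {
  stopifnot(inherits(map, "snp_map"))
  if (length(calls) != nrow(map))
    stop("calls must have one entry per map marker")
  if (min_run < 1L) stop("min_run must be >= 1")
  if (smooth_window < 3L) stop("smooth_window must be >= 3")
  keep <- which(calls != "AMBIGUOUS")
  empty <- list(
    segments = data.frame(state = character(0), first_snp = integer(0),
                          last_snp = integer(0), start_bp = numeric(0),
                          end_bp = numeric(0), n_snps = integer(0)),
    transitions = transition_frame(character(0), numeric(0), numeric(0),
                                   character(0)))
  if (length(keep) == 0L)
    return(structure(c(empty, list(map = map)), class = "loh_segments"))
  st <- calls[keep]

  # absorb sub-threshold flips embedded in a single flanking state
  repeat {
    r <- rle(st)
    n_runs <- length(r$values)
    if (n_runs < 3L) break
    short <- which(r$lengths < min_run & r$lengths <= smooth_window - 2L)
    short <- short[short > 1L & short < n_runs]
    short <- short[r$values[short - 1L] == r$values[short + 1L]]
    if (length(short) == 0L) break
    r$values[short[1L]] <- r$values[short[1L] - 1L]
    st <- inverse.rle(r)
  }

  r <- rle(st)
  last <- cumsum(r$lengths)
  first <- c(1L, utils::head(last, -1L) + 1L)
  seg <- data.frame(state = r$values,
                    first_snp = keep[first], last_snp = keep[last],
                    stringsAsFactors = FALSE)
  seg$start_bp <- map$pos[seg$first_snp]
  seg$end_bp <- map$pos[seg$last_snp]
  seg$n_snps <- last - first + 1L
  k <- nrow(seg)
  trans <- if (k >= 2L) {
    transition_frame(seg$state[-k], seg$end_bp[-k], seg$start_bp[-1L],
                     seg$state[-1L])
  } else empty$transitions
  structure(list(segments = seg, transitions = trans, map = map),
            class = "loh_segments")
}

transition_frame <- function(left_state, left_bp, right_bp, right_state) {
  data.frame(left_bp = left_bp, right_bp = right_bp,
             left_state = left_state, right_state = right_state,
             stringsAsFactors = FALSE)
}

#' Transition coordinates between consecutive segments
#'
#' Coordinates are taken from the flanking SNPs exactly (no interpolation):
#' left = position of the last SNP of the left-hand segment, right = position
#' of the first SNP of the right-hand segment.
#'
#' @param x an `loh_segments` object or its `segments` data frame.
#' @return Data frame with columns `left_bp`, `right_bp`, `left_state`,
#'   `right_state`; empty with fewer than two segments.
#' @export
transition_coordinates <- function(x) {
  seg <- if (inherits(x, "loh_segments")) x$segments else x
  k <- nrow(seg)
  if (k < 2L)
    return(transition_frame(character(0), numeric(0), numeric(0),
                            character(0)))
  transition_frame(seg$state[-k], seg$end_bp[-k], seg$start_bp[-1L],
                   seg$state[-1L])
}

#' @export
print.loh_segments <- function(x, ...) {
  cat(sprintf("loh_segments: %d segment(s), %d transition(s)\n",
              nrow(x$segments), nrow(x$transitions)))
  if (nrow(x$segments)) print.data.frame(x$segments, row.names = FALSE)
  invisible(x)
}
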