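#' Combine a red/white sector pair into four-chromatid region states
#'
#' Lays the two sectors' LOH segmentations side by side and partitions the
#' marker scaffold at the union of their transition points. Each resulting
#' region carries the zygosity of both sectors and the implied allele count
#' among the four chromatids of the mother cell (red copies + white copies,
#' with HET contributing one copy of each allele and HOM two of one), and is
#' typed as:
#'
#' * `het_het` — both sectors heterozygous (2:2 ground state),
#' * `conv_3_1` — one sector homozygous, the other heterozygous (3:1 tract),
#' * `conv_4_0` — both sectors homozygous for the same parent (4:0 tract),
#' * `reciprocal` — sectors homozygous for opposite parents (2:2 count; the
#'   LOH pattern distal to a reciprocal crossover).
#'
#' Only markers with a non-ambiguous call in both sectors contribute.
#'
#' @param red,white `loh_segments` objects for the two sectors, on the same
#'   map.
#' @param map the shared [snp_map].
#' @return A `region_states` data frame: `first_snp`, `last_snp` (map
#'   indices), `start_bp`, `end_bp`, `n_snps`, `red_state`, `white_state`,
#'   `count_A`, `count_B`, `type`, `donor` (`NA` for 2:2 regions), with the
#'   vector of contributing marker indices in attribute `snp_idx`.
#' @export
combine_sectors <- function(red, white, map) {
  stopifnot(inherits(red, "loh_segments"), inherits(white, "loh_segments"),
            inherits(map, "snp_map"))
  if (!identical(red$map$pos, map$pos) || !identical(white$map$pos, map$pos))
    stop("both sector segmentations must live on the supplied map")
  n <- nrow(map)
  track <- function(x) {
    st <- rep(NA_character_, n)
    seg <- x$segments
    for (i in seq_len(nrow(seg)))
      st[seg$first_snp[i]:seg$last_snp[i]] <- seg$state[i]
    st
  }
  rs <- track(red)
  ws <- track(white)
  keep <- which(!is.na(rs) & !is.na(ws))
  if (length(keep) == 0L)
    stop("no marker is callable in both sectors")
  joint <- paste(rs[keep], ws[keep], sep = "|")
  r <- rle(joint)
  last <- cumsum(r$lengths)
  first <- c(1L, utils::head(last, -1L) + 1L)
  pair <- strsplit(r$values, "|", fixed = TRUE)
  red_state <- vapply(pair, `[`, "", 1L)
  white_state <- vapply(pair, `[`, "", 2L)
  copies <- function(st) cbind(A = ifelse(st == "HET", 1L,
                                          ifelse(st == "HOM_A", 2L, 0L)),
                               B = ifelse(st == "HET", 1L,
                                          ifelse(st == "HOM_B", 2L, 0L)))
  cr <- copies(red_state)
  cw <- copies(white_state)
  count_A <- cr[, "A"] + cw[, "A"]
  count_B <- cr[, "B"] + cw[, "B"]
  type <- ifelse(red_state == "HET" & white_state == "HET", "het_het",
          ifelse(red_state != "HET" & white_state != "HET" &
                 red_state == white_state, "conv_4_0",
          ifelse(red_state != "HET" & white_state != "HET", "reciprocal",
                 "conv_3_1")))
  donor <- ifelse(count_A > 2L, "A", ifelse(count_B > 2L, "B", NA_character_))
  out <- data.frame(first_snp = keep[first], last_snp = keep[last],
                    start_bp = map$pos[keep[first]],
                    end_bp = map$pos[keep[last]],
                    n_snps = last - first + 1L,
                    red_state = red_state, white_state = white_state,
                    count_A = count_A, count_B = count_B,
                    type = type, donor = donor, stringsAsFactors = FALSE)
  attr(out, "snp_idx") <- keep
  attr(out, "map") <- map
  class(out) <- c("region_states", "data.frame")
  out
}

#' Classify the conversion tract of a sector-pair crossover
#'
#' Given the combined region states of a red/white pair that carries a
#' reciprocal crossover (distal reciprocal LOH), identifies the conversion
#' zone — the regions between the last fully heterozygous (2:2) region and
#' the distal reciprocal-LOH zone — and classifies it:
#'
#' * `NO_GC` — no conversion region; the red and white LOH transitions
#'   coincide (a "simple" crossover).
#' * `SIMPLE_3_1` — a single contiguous 3:1 region.
#' * `SIMPLE_4_0` — a single contiguous 4:0 region.
#' * `HYBRID_4_0_3_1` — one contiguous block of exactly one 4:0 region plus
#'   adjacent 3:1 region(s) sharing the 4:0 region's donor.
#' * `COMPLEX` — anything else: interior returns to 2:2, donor switches,
#'   reciprocal-pattern regions inside the zone, or multiple converted
#'   blocks.
#'
#' @param regions a `region_states` object from [combine_sectors()].
#' @param event_id optional identifier carried into reports.
#' @return A `conversion_event` object with fields `class`, `timing` (via
#'   [infer_timing()]), `donor` (via [infer_donor()]), tract lengths (via
#'   [tract_length()]), the region table, the conversion-zone row indices,
#'   and the per-sector transition coordinates.
#' @seealso [analyze_sector_pair()] for the one-call pipeline from ratio
#'   profiles.
#' @export
classify_event <- function(regions, event_id = NA_character_) {
  stopifnot(inherits(regions, "region_states"))
  k <- nrow(regions)
  # distal reciprocal zone: trailing run of reciprocal-type regions
  if (regions$type[k] != "reciprocal")
    stop("sector pair lacks distal reciprocal LOH: not a reciprocal ",
         "crossover", call. = FALSE)
  recip_start <- k
  while (recip_start > 1L && regions$type[recip_start - 1L] == "reciprocal")
    recip_start <- recip_start - 1L
  # proximal shared-heterozygous region (regions are maximal, so at most one
  # leads)
  has_prox <- regions$type[1L] == "het_het"
  zone <- seq_len(recip_start - 1L)
  if (has_prox) zone <- zone[-1L]

  cls <- if (length(zone) == 0L) {
    "NO_GC"
  } else {
    zr <- regions[zone, ]
    if (any(zr$type %in% c("het_het", "reciprocal"))) {
      "COMPLEX"
    } else {
      n40 <- sum(zr$type == "conv_4_0")
      donors <- unique(zr$donor)
      if (nrow(zr) == 1L) {
        if (zr$type == "conv_3_1") "SIMPLE_3_1" else "SIMPLE_4_0"
      } else if (n40 == 1L && length(donors) == 1L) {
        "HYBRID_4_0_3_1"
      } else "COMPLEX"
    }
  }

  ev <- structure(
    list(event_id = event_id, class = cls, regions = regions,
         zone = zone, recip_start = recip_start, has_prox = has_prox,
         red_transitions = NULL, white_transitions = NULL),
    class = "conversion_event")
  ev$timing <- infer_timing(ev)
  ev$donor <- infer_donor(ev)
  tl <- tract_length(ev)
  ev[names(tl)] <- tl
  ev
}

#' Infer the cell-cycle timing of the initiating lesion
#'
#' A 3:1 tract arises when a single chromatid, broken after DNA replication,
#' is repaired from the homolog (G2 lesion). A 4:0 or hybrid 4:0/3:1 tract
#' requires both sister chromatids broken at the same position, i.e. a
#' lesion before replication (G1). Complex events are assigned G1 if they
#' contain at least one 4:0 region, otherwise G2. Conversionless crossovers
#' carry no timing information.
#'
#' @param event a `conversion_event`.
#' @return `"G1"`, `"G2"` or `"UNCLASSIFIED"`.
#' @export
infer_timing <- function(event) {
  stopifnot(inherits(event, "conversion_event"))
  switch(event$class,
    NO_GC = "UNCLASSIFIED",
    SIMPLE_3_1 = "G2",
    SIMPLE_4_0 = "G1",
    HYBRID_4_0_3_1 = "G1",
    COMPLEX = {
      zr <- event$regions[event$zone, ]
      if (any(zr$type == "conv_4_0")) "G1" else "G2"
    })
}

#' Infer the donor homolog of a conversion event
#'
#' The donor is the homolog over-represented among the four chromatids in
#' the conversion regions (allele count > 2); the initiating lesion sat on
#' the other homolog. Events whose regions disagree are `MIXED`.
#'
#' @param event a `conversion_event`.
#' @return `"A"`, `"B"`, `"MIXED"`, or `NA` for conversionless events.
#' @export
infer_donor <- function(event) {
  stopifnot(inherits(event, "conversion_event"))
  zr <- event$regions[event$zone, ]
  donors <- unique(zr$donor[zr$type %in% c("conv_3_1", "conv_4_0")])
  if (length(donors) == 0L) return(NA_character_)
  if (length(donors) > 1L) return("MIXED")
  donors
}

#' Conversion-tract length estimates
#'
#' Tract length is bracketed by the marker scaffold: the minimum length is
#' the distance between the outermost markers inside the tract, and the
#' maximum the distance between the closest flanking markers outside it; the
#' reported length is their average, `avg = (min + max) / 2` exactly. For
#' complex tracts only the first and last transitions are used (the span of
#' all converted regions). Crossovers without a detectable conversion use a
#' minimal tract of 1 bp and a maximal tract equal to the distance between
#' the heterozygous and homozygous markers closest to the breakpoint. A
#' single-marker tract has its minimum floored at 1 bp. Tracts reaching the
#' edge of the map with no flanking marker are flagged `open_ended`, with
#' `max_bp` and `avg_bp` reported as `NA`.
#'
#' Distances are coordinate differences (right minus left), exclusive of
#' endpoints.
#'
#' @param event a `conversion_event`.
#' @return A list: `min_bp`, `max_bp`, `avg_bp`, `open_ended`.
#' @export
tract_length <- function(event) {
  stopifnot(inherits(event, "conversion_event"))
  regions <- event$regions
  snp_idx <- attr(regions, "snp_idx")
  map <- attr(regions, "map")
  pos <- map$pos
  if (event$class == "NO_GC") {
    if (!event$has_prox)
      return(list(min_bp = 1, max_bp = NA_real_, avg_bp = NA_real_,
                  open_ended = TRUE))
    left <- regions$end_bp[1L]
    right <- regions$start_bp[event$recip_start]
    mx <- right - left
    return(list(min_bp = 1, max_bp = mx, avg_bp = (1 + mx) / 2,
                open_ended = FALSE))
  }
  zr_idx <- event$zone[regions$type[event$zone] %in%
                         c("conv_3_1", "conv_4_0")]
  conv_first <- regions$first_snp[zr_idx[1L]]
  conv_last <- regions$last_snp[zr_idx[length(zr_idx)]]
  mn <- max(pos[conv_last] - pos[conv_first], 1)
  # closest flanking callable markers outside the tract
  i1 <- match(conv_first, snp_idx)
  i2 <- match(conv_last, snp_idx)
  open <- i1 == 1L || i2 == length(snp_idx)
  if (open)
    return(list(min_bp = mn, max_bp = NA_real_, avg_bp = NA_real_,
                open_ended = TRUE))
  mx <- pos[snp_idx[i2 + 1L]] - pos[snp_idx[i1 - 1L]]
  list(min_bp = mn, max_bp = mx, avg_bp = (mn + mx) / 2, open_ended = FALSE)
}

#' @export
print.conversion_event <- function(x, ...) {
  cat(sprintf(
    "conversion_event%s: class %s, timing %s, donor %s\n",
    if (is.na(x$event_id)) "" else paste0(" ", x$event_id),
    x$class, x$timing, if (is.na(x$donor)) "-" else x$donor))
  if (x$open_ended) {
    cat(sprintf("tract length: min %s bp, open-ended\n",
                format(x$min_bp, big.mark = ",")))
  } else {
    cat(sprintf("tract length: min %s / max %s / avg %s bp\n",
                format(x$min_bp, big.mark = ","),
                format(x$max_bp, big.mark = ","),
                format(x$avg_bp, big.mark = ",")))
  }
  invisible(x)
}

#' Per-SNP breakpoint-inclusion histogram
#'
#' For a set of classified events on one map, counts for every marker how
#' many events' crossover-associated conversion tracts include it. The tract
#' span of an event runs from its first to its last in-tract marker;
#' conversionless crossovers contribute their transition interval (both
#' flanking markers inclusive). Stacking many events reveals recombination
#' hotspots.
#'
#' @param events list of `conversion_event` objects on the same map.
#' @param map the shared [snp_map].
#' @return Integer vector of counts, one per marker, class
#'   `breakpoint_histogram` with the map attached.
#' @export
breakpoint_histogram <- function(events, map) {
  stopifnot(inherits(map, "snp_map"))
  counts <- integer(nrow(map))
  for (ev in events) {
    sp <- tract_span(ev)
    if (is.null(sp)) next
    counts <- counts + (map$pos >= sp[1L] & map$pos <= sp[2L])
  }
  structure(as.integer(counts), class = "breakpoint_histogram", map = map)
}

# genomic span [left, right] of an event's conversion tract (NO_GC: its
# transition interval); NULL when undefined
tract_span <- function(event) {
  regions <- event$regions
  if (event$class == "NO_GC") {
    if (!event$has_prox) return(NULL)
    return(c(regions$end_bp[1L], regions$start_bp[event$recip_start]))
  }
  zr_idx <- event$zone[regions$type[event$zone] %in%
                         c("conv_3_1", "conv_4_0")]
  c(regions$start_bp[zr_idx[1L]], regions$end_bp[zr_idx[length(zr_idx)]])
}

#' Count events whose tract overlaps an interval
#'
#' Hotspot query: how many events' conversion-tract spans intersect the
#' interval `[start_bp, end_bp]` (1-based inclusive).
#'
#' @param events list of `conversion_event` objects.
#' @param start_bp,end_bp interval bounds in bp.
#' @return Integer count.
#' @export
count_tract_overlaps <- function(events, start_bp, end_bp) {
  if (end_bp < start_bp) stop("end_bp must be >= start_bp")
  n <- 0L
  for (ev in events) {
    sp <- tract_span(ev)
    if (!is.null(sp) && sp[1L] <= end_bp && sp[2L] >= start_bp)
      n <- n + 1L
  }
  n
}

#' Run the full sector-pair pipeline on a pair of ratio profiles
#'
#' Convenience wrapper: calls zygosity, segments both sectors, combines them
#' and classifies the event.
#'
#' @param red,white `ratio_profile` objects for the two sectors.
#' @param map the shared [snp_map].
#' @param thresholds calling thresholds ([zygosity_thresholds()]).
#' @param min_run,smooth_window smoothing parameters for [segment_profile()].
#' @param event_id optional identifier.
#' @return A `conversion_event`, with the two sectors' transition tables in
#'   `red_transitions` / `white_transitions`.
#' @export
analyze_sector_pair <- function(red, white, map,
                                thresholds = zygosity_thresholds(),
                                min_run = 2L, smooth_window = 3L,
                                event_id = NA_character_) {
  seg_r <- segment_profile(call_zygosity(red, thresholds), map,
                           min_run = min_run, smooth_window = smooth_window)
  seg_w <- segment_profile(call_zygosity(white, thresholds), map,
                           min_run = min_run, smooth_window = smooth_window)
  regions <- combine_sectors(seg_r, seg_w, map)
  ev <- classify_event(regions, event_id = event_id)
  ev$red_transitions <- seg_r$transitions
  ev$white_transitions <- seg_w$transitions
  ev
}
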