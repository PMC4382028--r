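#' Read / write a SNP map
#'
#' Tab-separated with header `chrom  pos  name`; allele labels and the
#' selected-marker position are carried in `#key value` comment lines above
#' the header so a written map reads back identical.
#'
#' @param path file path.
#' @return [read_snp_map()] returns a [snp_map].
#' @export
read_snp_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- read_hash_meta(path)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "name")
  if (!all(need %in% names(tab)))
    stop(path, ": header must contain ", paste(need, collapse = ", "))
  if (nrow(tab) < 2L) stop(path, ": a snp map needs at least 2 markers")
  if (anyNA(tab$pos) || !is.numeric(tab$pos))
    stop(path, ": non-numeric or missing positions")
  if (is.unsorted(tab$pos, strictly = TRUE))
    stop(path, ": marker positions must be strictly increasing")
  alleles <- if (!is.null(meta$alleles))
    strsplit(meta$alleles, ",", fixed = TRUE)[[1L]] else c("A", "B")
  smp <- if (!is.null(meta$selected_marker_pos))
    as.numeric(meta$selected_marker_pos) else NA_real_
  snp_map(tab$chrom[1L], tab$pos, tab$name, alleles = alleles,
          selected_marker_pos = smp)
}

#' @rdname read_snp_map
#' @param map a [snp_map].
#' @export
write_snp_map <- function(map, path) {
  stopifnot(inherits(map, "snp_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#alleles %s",
                     paste(attr(map, "alleles"), collapse = ",")), con)
  smp <- attr(map, "selected_marker_pos")
  if (!is.na(smp))
    writeLines(sprintf("#selected_marker_pos %s",
                       format(smp, scientific = FALSE)), con)
  utils::write.table(as.data.frame(map)[, c("chrom", "pos", "name")], con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_hash_meta <- function(path) {
  lines <- readLines(path, n = 50L)
  lines <- lines[startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(sub("^#", "", ln), "[ \t]+")[[1L]]
    if (length(parts) >= 2L) out[[parts[1L]]] <- parts[2L]
  }
  out
}

#' Read / write a per-SNP allele-ratio table
#'
#' Tab-separated with header `chrom  pos  ratio_A  ratio_B`, one row per
#' marker of the map, in map order.
#'
#' @param path file path.
#' @param map the [snp_map] the ratios live on.
#' @return [read_ratio_table()] returns a `ratio_profile`.
#' @export
read_ratio_table <- function(path, map) {
  if (!file.exists(path)) stop("no such file: ", path)
  stopifnot(inherits(map, "snp_map"))
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ratio_A", "ratio_B")
  if (!all(need %in% names(tab)))
    stop(path, ": header must contain ", paste(need, collapse = ", "))
  if (nrow(tab) != nrow(map))
    stop(path, ": ", nrow(tab), " rows but the map has ", nrow(map),
         " markers")
  if (!identical(as.numeric(tab$pos), as.numeric(map$pos)))
    stop(path, ": positions do not match the map")
  ratio_profile(map, tab$ratio_A, tab$ratio_B)
}

#' @rdname read_ratio_table
#' @param profile a `ratio_profile`.
#' @export
write_ratio_table <- function(profile, path) {
  stopifnot(inherits(profile, "ratio_profile"))
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature track from a BED file
#'
#' BED is 0-based half-open on disk; intervals are converted to the 1-based
#' inclusive convention used internally (`start + 1`, `end`).
#'
#' @param path BED file (3+ columns: chrom, start, end, optional name).
#' @param name feature class name (default: basename without extension, or
#'   the 4th BED column's modal value if present).
#' @param midpoint_rule collapse intervals to midpoints for overlap testing.
#' @return A [feature_track()].
#' @export
read_features_bed <- function(path, name = NULL, midpoint_rule = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop(path, ": BED needs at least 3 columns")
  names(tab)[1:3] <- c("chrom", "start", "end")
  if (!is.numeric(tab$start) || !is.numeric(tab$end))
    stop(path, ": BED start/end must be numeric")
  if (any(tab$end <= tab$start))
    stop(path, ": BED intervals must have start < end")
  if (is.null(name)) {
    name <- if (ncol(tab) >= 4L) names(sort(table(tab[[4L]]),
                                            decreasing = TRUE))[1L]
            else sub("\\.[^.]*$", "", basename(path))
  }
  feature_track(name,
                data.frame(chrom = tab$chrom, start = tab$start + 1L,
                           end = tab$end, stringsAsFactors = FALSE),
                midpoint_rule = midpoint_rule)
}

#' Tabular report of classified events
#'
#' Flattens a list of `conversion_event` objects into one record per event:
#' id, class, timing, donor, tract lengths, the crossover window, and the
#' per-sector transition coordinates (serialized as
#' `left-right:leftState>rightState` strings joined by `;` so the table
#' round-trips losslessly through TSV and JSON).
#'
#' @param events list of `conversion_event` objects.
#' @return An `event_report` data frame.
#' @export
event_report <- function(events) {
  rows <- lapply(seq_along(events), function(i) {
    ev <- events[[i]]
    sp <- tract_span(ev)
    data.frame(
      event_id = if (is.na(ev$event_id)) as.character(i) else ev$event_id,
      class = ev$class, timing = ev$timing,
      donor = if (is.na(ev$donor)) "" else ev$donor,
      min_bp = ev$min_bp, max_bp = ev$max_bp, avg_bp = ev$avg_bp,
      open_ended = ev$open_ended,
      span_left = if (is.null(sp)) NA_real_ else sp[1L],
      span_right = if (is.null(sp)) NA_real_ else sp[2L],
      red_transitions = serialize_transitions(ev$red_transitions),
      white_transitions = serialize_transitions(ev$white_transitions),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("event_report", "data.frame")
  out
}

serialize_transitions <- function(tr) {
  if (is.null(tr) || nrow(tr) == 0L) return("")
  paste(sprintf("%s-%s:%s>%s",
                format(tr$left_bp, scientific = FALSE, trim = TRUE),
                format(tr$right_bp, scientific = FALSE, trim = TRUE),
                tr$left_state, tr$right_state),
        collapse = ";")
}

#' Write / read an event report
#'
#' `format` is chosen from the file extension: `.json` via jsonlite,
#' anything else as TSV. Re-reading reproduces identical records.
#'
#' @param report an `event_report` (or list of `conversion_event`s, which is
#'   converted first).
#' @param path output path.
#' @param seed,config optional run metadata recorded in the report.
#' @export
write_event_report <- function(report, path, seed = NULL, config = NULL) {
  if (!inherits(report, "event_report")) report <- event_report(report)
  meta <- list(package_version = as.character(utils::packageVersion("sectorLOH")),
               seed = seed,
               config = config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(metadata = meta, events = report), path,
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  } else {
    utils::write.table(report, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  invisible(path)
}

#' @rdname write_event_report
#' @export
read_event_report <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    tab <- as.data.frame(obj$events, stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = c(event_id = "character"))
  }
  need <- c("event_id", "class", "timing", "donor", "min_bp", "max_bp",
            "avg_bp", "open_ended", "span_left", "span_right",
            "red_transitions", "white_transitions")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(path, ": report is missing column(s) ", paste(miss, collapse = ", "))
  for (col in c("donor", "red_transitions", "white_transitions"))
    tab[[col]][is.na(tab[[col]])] <- ""
  tab <- tab[, need]
  class(tab) <- c("event_report", "data.frame")
  tab
}

#' Pipeline configuration
#'
#' Flat key-value configuration with a default for every field; unknown keys
#' are rejected. Serialized as `key: value` lines.
#'
#' @param ... overrides of the defaults (see `pipeline_config()` for the
#'   field list).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    het_lo = 0.7, het_hi = 1.3, hom_present = 1.4, hom_absent = 0.6,
    min_run = 2L, smooth_window = 3L,
    n_snps = 2300L, chrom_length = 1.1e6,
    tract_len_median_kb = 10, tract_len_sdlog = 0.6,
    prob_g1 = 0.6, prob_no_gc = 0.12,
    noise_sd = 0.12, noise_het = 1.0, noise_present = 1.75,
    noise_absent = 0.25,
    midpoint_classes = "Ty", merge_windows = FALSE,
    seed = NA_integer_, out_dir = ".")
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path file of `key: value` lines (`#` comments allowed).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", lines))
  bad <- vapply(kv, length, 0L) != 3L
  if (any(bad))
    stop(path, ": malformed config line: ", lines[which(bad)[1L]])
  vals <- lapply(kv, function(m) {
    v <- m[3L]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num
    else if (v %in% c("TRUE", "FALSE", "true", "false")) as.logical(toupper(v))
    else v
  })
  names(vals) <- vapply(kv, `[`, "", 2L)
  do.call(pipeline_config, vals)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  writeLines(sprintf("%s: %s", names(config),
                     vapply(config, function(v)
                       format(v, scientific = FALSE), "")), path)
  invisible(path)
}
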