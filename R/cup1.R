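#' Tandem-array state
#'
#' Copy-number state of one homolog's tandem gene array (the CUP1 locus
#' geometry: the W303-1A-derived homolog carries 14 copies of a 2-kb repeat,
#' the YJM789-derived homolog 7 copies of a 1.2-kb repeat). The restriction
#' fragment released by enzymes cutting only in the flanking sequence has
#' size `flank + unit * copies`.
#'
#' @param homolog `"A"` or `"B"`.
#' @param unit_kb repeat-unit length in kb (> 0).
#' @param copies integer repeat count (>= 0).
#' @param flank_kb total flanking sequence inside the restriction fragment, kb.
#' @return A `tandem_array_state` list with a `fragment_kb` field.
#' @export
#' @examples
#' tandem_array_state("A", unit_kb = 2, copies = 14, flank_kb = 2)$fragment_kb
tandem_array_state <- function(homolog = c("A", "B"), unit_kb, copies,
                               flank_kb) {
  homolog <- match.arg(homolog)
  if (unit_kb <= 0) stop("unit_kb must be positive")
  if (copies < 0) stop("copies must be non-negative")
  if (flank_kb < 0) stop("flank_kb must be non-negative")
  structure(list(homolog = homolog, unit_kb = unit_kb,
                 copies = as.integer(copies), flank_kb = flank_kb,
                 fragment_kb = flank_kb + unit_kb * copies),
            class = "tandem_array_state")
}

#' Default CUP1 array pair
#'
#' The parental diploid configuration: a 14-copy, 2-kb-unit array on the
#' W303-1A-derived homolog (~30 kb fragment) and a 7-copy, 1.2-kb-unit array
#' on the YJM789-derived homolog (~12 kb fragment).
#' @return list of two [tandem_array_state] objects named `A` and `B`.
#' @export
cup1_parental_arrays <- function() {
  list(A = tandem_array_state("A", unit_kb = 2.0, copies = 14, flank_kb = 2.0),
       B = tandem_array_state("B", unit_kb = 1.2, copies = 7, flank_kb = 3.6))
}

#' Simulate tandem-array copy-number variation across subcultures
#'
#' Serial-subculture model of repeat-number instability in a tandem array.
#' At each subculture, each homolog independently suffers a copy-number
#' event with probability `event_prob`; an event is a deletion with
#' probability `deletion_fraction` (otherwise an addition) of a step of
#' 1..`max_step` repeat units (truncated-geometric step sizes, small changes
#' more likely). Copy counts are floored at 1 repeat.
#'
#' @param initial list of two [tandem_array_state] objects (default
#'   [cup1_parental_arrays()]).
#' @param n_subcultures number of serial subcultures (>= 1).
#' @param event_prob per-homolog, per-subculture probability of a
#'   copy-number event, in \[0, 1\].
#' @param deletion_fraction probability that an event is a deletion, in
#'   \[0, 1\].
#' @param max_step maximum repeats gained or lost in one event.
#' @param seed integer seed.
#' @return A `cup1_trajectory` object: `copies` — an
#'   `(n_subcultures + 1) x 2` matrix of repeat counts (row 1 = initial
#'   state), `n_events` — events per homolog, `final` — final
#'   [tandem_array_state] pair, plus the simulation parameters.
#' @export
#' @examples
#' tr <- simulate_cup1_cnv(n_subcultures = 10, event_prob = 0.1, seed = 42)
#' tr$copies
simulate_cup1_cnv <- function(initial = cup1_parental_arrays(),
                              n_subcultures, event_prob,
                              deletion_fraction = 0.5, max_step = 5L,
                              seed) {
  if (event_prob < 0 || event_prob > 1)
    stop("event_prob must be a probability in [0, 1]")
  if (deletion_fraction < 0 || deletion_fraction > 1)
    stop("deletion_fraction must be a probability in [0, 1]")
  if (n_subcultures < 1) stop("n_subcultures must be >= 1")
  if (max_step < 1) stop("max_step must be >= 1")
  stopifnot(length(initial) == 2L,
            all(vapply(initial, inherits, TRUE, "tandem_array_state")))
  set_seed_checked(seed)
  copies <- matrix(0L, nrow = n_subcultures + 1L, ncol = 2L,
                   dimnames = list(NULL, names(initial)))
  copies[1L, ] <- vapply(initial, `[[`, 1L, "copies")
  n_events <- c(0L, 0L)
  for (s in seq_len(n_subcultures)) {
    cur <- copies[s, ]
    for (h in 1:2) {
      if (stats::runif(1L) < event_prob) {
        n_events[h] <- n_events[h] + 1L
        step <- min(stats::rgeom(1L, 0.5) + 1L, max_step)
        if (stats::runif(1L) < deletion_fraction) step <- -step
        cur[h] <- max(1L, cur[h] + step)
      }
    }
    copies[s + 1L, ] <- cur
  }
  final <- initial
  for (h in 1:2) {
    final[[h]]$copies <- copies[n_subcultures + 1L, h]
    final[[h]]$fragment_kb <- final[[h]]$flank_kb +
      final[[h]]$unit_kb * final[[h]]$copies
  }
  structure(list(copies = copies, n_events = n_events, final = final,
                 n_subcultures = n_subcultures, event_prob = event_prob,
                 deletion_fraction = deletion_fraction,
                 max_step = as.integer(max_step)),
            class = "cup1_trajectory")
}

#' @export
print.cup1_trajectory <- function(x, ...) {
  cat(sprintf(
    "cup1_trajectory: %d subcultures, events/homolog = %s, final copies = %s\n",
    x$n_subcultures, paste(x$n_events, collapse = "/"),
    paste(x$copies[nrow(x$copies), ], collapse = "/")))
  invisible(x)
}
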