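#' Hybridization-ratio noise model
#'
#' Describes the allele-specific hybridization signal expected at a SNP as a
#' function of how many chromatids in a sector carry that allele. On the
#' normalized scale used for calling, a heterozygous SNP (one copy per
#' genome) hybridizes around 1, a homozygous-present allele (two copies)
#' between 1.5 and 2, and an absent allele between 0 and 0.5; the defaults sit
#' at the midpoints of those calling bands. Gaussian noise with standard
#' deviation `sd` is added around the mean implied by the genotype.
#'
#' @param het mean ratio for a heterozygous SNP (one copy). Default 1.0.
#' @param present mean ratio when both chromatids carry the allele. Default 1.75.
#' @param absent mean ratio when neither chromatid carries it. Default 0.25.
#' @param sd gaussian standard deviation (>= 0). Default 0.12.
#' @return A `noise_model` list.
#' @export
noise_model <- function(het = 1.0, present = 1.75, absent = 0.25, sd = 0.12) {
  if (!(absent < het && het < present))
    stop("noise model means must be ordered absent < het < present")
  if (sd < 0) stop("sd must be non-negative")
  structure(list(het = het, present = present, absent = absent, sd = sd),
            class = "noise_model")
}

#' Simulate a reciprocal crossover with its conversion tract
#'
#' Simulates the four chromatids of a red/white sector pair produced by a
#' single mitotic reciprocal crossover (RCO) between the two homologs,
#' initiated by a double-strand break on `broken_homolog` and repaired using
#' the intact homolog as donor. The lesion timing controls the tract
#' geometry:
#'
#' * `"G2"` — one chromatid is broken after replication; its repair converts a
#'   single tract adjacent to the crossover, giving a 3:1 allele ratio among
#'   the four chromatids over the tract.
#' * `"G1"` — the break precedes replication, so both sister chromatids are
#'   broken at the same position and repaired independently. Equal tract
#'   lengths give a 4:0 tract; unequal lengths give a nested hybrid 4:0/3:1
#'   tract.
#'
#' Distal to the crossover the two sectors are homozygous for opposite
#' parental alleles (reciprocal LOH). Conversion tracts extend proximally
#' from the crossover position. With `patchiness > 0` each tract is broken
#' into alternating converted/unconverted pieces (breakpoints placed as a
#' Poisson process along the tract), emulating patchy repair of heteroduplex
#' mismatches; this is how complex tracts arise.
#'
#' @param map a [snp_map].
#' @param timing `"G1"` or `"G2"`.
#' @param tract_len_bp tract length(s) in bp: one length for G2; one or two
#'   for G1 (recycled if one; first length belongs to the chromatid that goes
#'   on to cross over).
#' @param co_pos crossover position in bp; must lie within the map span.
#' @param broken_homolog which homolog carries the initiating lesion
#'   (`"A"` or `"B"`); the other homolog is the conversion donor.
#' @param seed integer seed (used only when `patchiness > 0`; the rest of the
#'   construction is deterministic).
#' @param patchiness per-bp rate of donor/recipient switching inside a tract;
#'   0 (default) gives uninterrupted tracts.
#' @return An `rco_truth` object: the map, the simulation parameters, a
#'   `chromatids` character matrix (`n_snps` x 4, columns `red_1`, `red_2`,
#'   `white_1`, `white_2`, entries `"A"`/`"B"`) and a `tracts` data frame of
#'   converted intervals per chromatid.
#' @export
#' @examples
#' m <- generate_snp_map(200, 1e5, seed = 1)
#' tr <- simulate_rco_event(m, "G2", 1e4, co_pos = 6e4, broken_homolog = "B",
#'                          seed = 1)
#' tr
simulate_rco_event <- function(map, timing = c("G2", "G1"), tract_len_bp,
                               co_pos, broken_homolog = c("B", "A"),
                               seed = 1L, patchiness = 0) {
  stopifnot(inherits(map, "snp_map"))
  timing <- match.arg(timing)
  broken_homolog <- match.arg(broken_homolog)
  if (co_pos < map$pos[1L] || co_pos > map$pos[nrow(map)])
    stop("co_pos must lie within the map span")
  if (any(tract_len_bp < 0)) stop("tract lengths must be non-negative")
  if (patchiness < 0) stop("patchiness must be non-negative")
  if (timing == "G2") {
    if (length(tract_len_bp) != 1L)
      stop("G2 events take a single tract length")
    len <- c(tract_len_bp, 0)
  } else {
    if (!length(tract_len_bp) %in% c(1L, 2L))
      stop("G1 events take one or two tract lengths")
    len <- rep(as.numeric(tract_len_bp), length.out = 2L)
  }
  al <- attr(map, "alleles")
  H <- broken_homolog                      # lesion-bearing homolog
  D <- setdiff(c("A", "B"), H)             # donor homolog
  pos <- map$pos
  n <- length(pos)

  if (patchiness > 0) set_seed_checked(seed)
  # converted sub-intervals [start, end) for a tract ending at co_pos
  tract_pieces <- function(L) {
    if (L <= 0) return(cbind(start = numeric(0), end = numeric(0)))
    s <- co_pos - L
    if (patchiness <= 0) return(cbind(start = s, end = co_pos))
    # alternate converted / unconverted pieces, converted first at co_pos end
    brk <- sort(s + runif(stats::rpois(1L, patchiness * L), 0, L))
    edges <- c(s, brk, co_pos)
    k <- length(edges) - 1L
    keep <- rev(seq_len(k)) %% 2L == 1L    # piece touching co_pos converted
    cbind(start = edges[-length(edges)][keep], end = edges[-1L][keep])
  }

  p1 <- tract_pieces(len[1L])              # chromatid that crosses over
  p2 <- tract_pieces(len[2L])              # its sister (G1 only)
  in_pieces <- function(p) {
    hit <- rep(FALSE, n)
    for (i in seq_len(nrow(p)))
      hit <- hit | (pos >= p[i, 1L] & pos < p[i, 2L])
    hit
  }
  distal <- pos >= co_pos

  # red sector: crossover chromatid of the donor homolog + unbroken (G2) or
  # second repaired (G1) sister of the broken homolog
  # white sector: repaired crossover chromatid of the broken homolog + the
  # intact donor sister
  chrom_D_co <- ifelse(distal, H, D)
  chrom_H_sis <- ifelse(in_pieces(p2), D, H)
  chrom_H_co <- ifelse(distal, D, ifelse(in_pieces(p1), D, H))
  chrom_D_sis <- rep(D, n)
  chromatids <- cbind(red_1 = chrom_D_co, red_2 = chrom_H_sis,
                      white_1 = chrom_H_co, white_2 = chrom_D_sis)
  # map internal A/B onto the map's allele labels
  chromatids[] <- ifelse(chromatids == "A", al[1L], al[2L])

  tracts <- rbind(
    if (nrow(p1)) data.frame(chromatid = "white_1", start = p1[, 1L],
                             end = p1[, 2L], donor = D),
    if (nrow(p2)) data.frame(chromatid = "red_2", start = p2[, 1L],
                             end = p2[, 2L], donor = D))
  structure(list(map = map, timing = timing, broken_homolog = H, donor = D,
                 co_pos = co_pos, tract_len_bp = len,
                 patchiness = patchiness, chromatids = chromatids,
                 tracts = tracts),
            class = "rco_truth")
}

#' @export
print.rco_truth <- function(x, ...) {
  cat(sprintf(
    "rco_truth: %s lesion on homolog %s, crossover at %s bp, tracts %s bp\n",
    x$timing, x$broken_homolog,
    format(x$co_pos, big.mark = ",", scientific = FALSE),
    paste(format(x$tract_len_bp[x$tract_len_bp > 0 | seq_along(x$tract_len_bp) == 1L],
                 big.mark = ","), collapse = " / ")))
  invisible(x)
}

#' Simulate a cohort of sectored-colony crossover events
#'
#' Draws `n_events` independent reciprocal-crossover events on one map under
#' the study conditions: crossover positions uniform over the screened
#' interval; lesion timing G1 with probability `prob_g1` (G2 otherwise); a
#' fraction `prob_no_gc` of events with no detectable conversion (tract
#' length 0); tract lengths log-normal with median `tract_len_median_kb` kb
#' (G1 events draw two independent lengths for the two broken sister
#' chromatids, so pure 4:0 tracts — identical realized lengths — are rare
#' relative to hybrids, as observed); broken homolog chosen at random.
#'
#' @param map a [snp_map].
#' @param n_events number of sector pairs to simulate.
#' @param prob_g1 probability a lesion is G1-timed. Default 0.6.
#' @param prob_no_gc probability of a conversionless crossover. Default 0.12.
#' @param tract_len_median_kb median tract length, kb. Default 10.
#' @param tract_len_sdlog log-scale sd of the tract-length law. Default 0.6.
#' @param patchiness per-bp donor/recipient switch rate inside tracts
#'   (complex events); 0 disables.
#' @param seed integer seed.
#' @return List of `rco_truth` objects.
#' @export
simulate_rco_cohort <- function(map, n_events, prob_g1 = 0.6,
                                prob_no_gc = 0.12,
                                tract_len_median_kb = 10,
                                tract_len_sdlog = 0.6,
                                patchiness = 0, seed) {
  stopifnot(inherits(map, "snp_map"))
  if (prob_g1 < 0 || prob_g1 > 1 || prob_no_gc < 0 || prob_no_gc > 1)
    stop("probabilities must lie in [0, 1]")
  set_seed_checked(seed)
  span <- range(map$pos)
  lapply(seq_len(n_events), function(i) {
    timing <- if (stats::runif(1L) < prob_g1) "G1" else "G2"
    no_gc <- stats::runif(1L) < prob_no_gc
    n_len <- if (timing == "G1") 2L else 1L
    lens <- if (no_gc) rep(0, n_len) else
      stats::rlnorm(n_len, meanlog = log(tract_len_median_kb * 1000),
                    sdlog = tract_len_sdlog)
    simulate_rco_event(map, timing, lens,
                       co_pos = stats::runif(1L, span[1L], span[2L]),
                       broken_homolog = sample(c("A", "B"), 1L),
                       seed = sample.int(.Machine$integer.max, 1L),
                       patchiness = patchiness)
  })
}

#' Emit noisy allele-ratio profiles for a simulated sector pair
#'
#' Converts the four simulated chromatid genotypes of an [simulate_rco_event]
#' truth into per-sector normalized hybridization ratios: for each SNP and
#' each sector, the number of chromatids carrying each parental allele (0, 1
#' or 2) selects the noise-model mean (absent / het / present), and gaussian
#' noise is added. With `sd = 0` the profiles equal the means exactly.
#' Ratios are floored at 0 (hybridization signal cannot be negative).
#'
#' @param truth an `rco_truth`.
#' @param noise a [noise_model].
#' @param seed integer seed; required when `noise$sd > 0`.
#' @return A list with elements `red` and `white`, each a `ratio_profile`
#'   data frame (`chrom`, `pos`, `ratio_A`, `ratio_B`) carrying the map as an
#'   attribute.
#' @export
emit_ratio_profiles <- function(truth, noise = noise_model(), seed = 1L) {
  stopifnot(inherits(truth, "rco_truth"), inherits(noise, "noise_model"))
  map <- truth$map
  al <- attr(map, "alleles")
  if (noise$sd > 0) set_seed_checked(seed)
  mk <- function(cols) {
    nA <- rowSums(truth$chromatids[, cols, drop = FALSE] == al[1L])
    mean_A <- c(noise$absent, noise$het, noise$present)[nA + 1L]
    mean_B <- c(noise$absent, noise$het, noise$present)[(2L - nA) + 1L]
    n <- nrow(map)
    rA <- mean_A
    rB <- mean_B
    if (noise$sd > 0) {
      rA <- pmax(0, rA + stats::rnorm(n, 0, noise$sd))
      rB <- pmax(0, rB + stats::rnorm(n, 0, noise$sd))
    }
    ratio_profile(map, rA, rB)
  }
  list(red = mk(c("red_1", "red_2")), white = mk(c("white_1", "white_2")))
}

#' Construct a per-SNP allele-ratio profile
#'
#' @param map a [snp_map].
#' @param ratio_A,ratio_B finite, non-negative numeric vectors, one value per
#'   marker: the normalized hybridization ratio of each parental allele.
#' @return A `ratio_profile` data frame.
#' @export
ratio_profile <- function(map, ratio_A, ratio_B) {
  stopifnot(inherits(map, "snp_map"))
  if (length(ratio_A) != nrow(map) || length(ratio_B) != nrow(map))
    stop("ratio vectors must match the map length")
  if (!all(is.finite(ratio_A)) || !all(is.finite(ratio_B)) ||
      any(ratio_A < 0) || any(ratio_B < 0))
    stop("ratios must be finite and non-negative")
  out <- data.frame(chrom = map$chrom, pos = map$pos,
                    ratio_A = as.numeric(ratio_A),
                    ratio_B = as.numeric(ratio_B))
  attr(out, "map") <- map
  class(out) <- c("ratio_profile", "data.frame")
  out
}
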