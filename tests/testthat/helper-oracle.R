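# Independent oracles used across the suite. These re-derive expected
# results directly from first principles (truth chromatid genotypes,
# exhaustive enumeration, brute-force scans) without touching the package's
# segmentation/classification/test code paths.

# --- truth-level classification oracle -------------------------------------
# Derives the observable class/timing/donor of a simulated event straight
# from the four chromatid genotype vectors at marker resolution.
oracle_classify <- function(truth) {
  al <- attr(truth$map, "alleles")
  g <- truth$chromatids
  red_hom <- g[, "red_1"] == g[, "red_2"]
  white_hom <- g[, "white_1"] == g[, "white_2"]
  sym <- ifelse(!red_hom & !white_hom, "H",
         ifelse(red_hom & white_hom & g[, "red_1"] == g[, "white_1"], "F",
         ifelse(red_hom & white_hom, "R", "T")))
  nA <- rowSums(g == al[1L])
  donor <- ifelse(nA > 2L, "A", ifelse(nA < 2L, "B", ""))
  token <- paste0(sym, ifelse(sym %in% c("T", "F"), donor, ""))
  r <- rle(token)
  toks <- r$values
  k <- length(toks)
  # distal reciprocal zone = trailing run of R tokens
  if (substr(toks[k], 1, 1) != "R") return(NULL)  # not an observable RCO
  rs <- k
  while (rs > 1L && substr(toks[rs - 1L], 1, 1) == "R") rs <- rs - 1L
  zone <- toks[seq_len(rs - 1L)]
  if (length(zone) && zone[1L] == "H") zone <- zone[-1L]
  sym_z <- substr(zone, 1, 1)
  don_z <- unique(substr(zone[sym_z %in% c("T", "F")], 2, 2))
  cls <-
    if (length(zone) == 0L) "NO_GC"
    else if (any(sym_z %in% c("H", "R"))) "COMPLEX"
    else if (length(zone) == 1L && sym_z == "T") "SIMPLE_3_1"
    else if (length(zone) == 1L && sym_z == "F") "SIMPLE_4_0"
    else if (sum(sym_z == "F") == 1L && length(don_z) == 1L) "HYBRID_4_0_3_1"
    else "COMPLEX"
  timing <- switch(cls,
    NO_GC = "UNCLASSIFIED",
    SIMPLE_3_1 = "G2",
    SIMPLE_4_0 = ,
    HYBRID_4_0_3_1 = "G1",
    COMPLEX = if (any(sym_z == "F")) "G1" else "G2")
  donor_call <- if (length(don_z) == 0L) NA_character_
                else if (length(don_z) > 1L) "MIXED" else don_z
  list(class = cls, timing = timing, donor = donor_call)
}

# --- exact tests by enumeration --------------------------------------------
# Two-sided Fisher p: sum hypergeometric probabilities of all tables with
# the observed margins that are no more probable than the observed table.
brute_fisher <- function(tab) {
  r1 <- sum(tab[1L, ]); c1 <- sum(tab[, 1L]); n <- sum(tab)
  a_obs <- tab[1L, 1L]
  a_all <- max(0L, r1 + c1 - n):min(r1, c1)
  pr <- dhyper(a_all, c1, n - c1, r1)
  p_obs <- dhyper(a_obs, c1, n - c1, r1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Two-sided Mann-Whitney p by full enumeration of group assignments
# (untied data): doubled one-tail probability of the U statistic.
brute_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  rk <- rank(pooled)
  u_of <- function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2L, u_of)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# --- brute-force interval overlap ------------------------------------------
brute_overlap_pairs <- function(starts, ends, wl, wr) {
  n <- 0L
  for (i in seq_along(starts))
    for (j in seq_along(wl))
      if (starts[i] <= wr[j] && ends[i] >= wl[j]) n <- n + 1L
  n
}

# --- fixture builders -------------------------------------------------------
# noiseless sector-pair profiles for a truth
noiseless_pair <- function(truth) {
  emit_ratio_profiles(truth, noise_model(sd = 0), seed = 1L)
}

# build a conversion_event from explicit per-sector call vectors
event_from_calls <- function(red_calls, white_calls, map, min_run = 1L) {
  sr <- segment_profile(red_calls, map, min_run = min_run)
  sw <- segment_profile(white_calls, map, min_run = min_run)
  classify_event(combine_sectors(sr, sw, map))
}
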