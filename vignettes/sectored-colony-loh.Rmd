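---
title: "Mapping mitotic crossovers from sectored-colony LOH profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping mitotic crossovers from sectored-colony LOH profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sectorLOH)
```

## The assay and the model

A diploid yeast formed by mating two sequence-diverged haploids (a
W303-1A-like parent, called homolog **A**, and a YJM789-like parent,
homolog **B**) is heterozygous at tens of thousands of SNPs. A mitotic
reciprocal crossover (RCO) between the homologs, followed by segregation of
the recombinant chromatids into the two daughter cells, makes each daughter
homozygous — for opposite parents — at every marker distal to the exchange
point. When the strain also carries a color marker (one *SUP4-o* copy in an
*ade2-1/ade2-1* background), the two daughters found the red and white
halves of a sectored colony, so each sector reports the genotype of one
daughter cell and the pair jointly reports all four chromatids of the
mother cell at the moment of division.

Allele-specific hybridization gives, per SNP and per sector, a normalized
ratio for each parental allele: about 1 for one copy per genome
(heterozygous), between 1.5 and 2 for two copies, between 0 and 0.5 for
zero copies. The pipeline converts these ratios to per-SNP zygosity calls,
collapses each sector into segments of constant state, and overlays the
two sectors to count, region by region, how many of the four chromatids
carry each parental allele:

* **2:2 with both sectors heterozygous** — the unrearranged ground state;
* **2:2 with the sectors homozygous for opposite parents** — reciprocal
  LOH, the signature distal to the crossover;
* **3:1** — one sector homozygous, the other heterozygous: a gene
  conversion on a single chromatid. A single chromatid is broken only
  after DNA replication, so an uninterrupted 3:1 tract implies a **G2**
  lesion;
* **4:0** — both sectors homozygous for the same parent: both sister
  chromatids converted at the same place, which requires a lesion on the
  unreplicated chromosome, i.e. **G1** timing. Unequal repair tracts on
  the two broken sisters give a nested hybrid 4:0/3:1 tract, also G1.

Events whose conversion zone returns to heterozygosity internally, switches
donor, or contains reciprocal-pattern regions are **complex** — attributed
to patchy repair of heteroduplex DNA — and are assigned G1 timing if they
contain at least one 4:0 region, G2 otherwise. Crossovers with identical
transitions in the two sectors carry no conversion and no timing
information.

Tract lengths are bracketed by marker resolution: the minimum is the
distance between the outermost converted markers, the maximum the distance
between the closest flanking unconverted markers, and the reported length
is their average — exactly `(min + max) / 2`. Complex tracts use only
their first and last transitions; conversionless crossovers average a
minimal 1-bp tract with the width of the shared transition interval. All
coordinates are 1-based (SGD convention), distances are coordinate
differences (exclusive of endpoints), and a single-marker tract has its
minimum floored at 1 bp.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `het_lo`–`het_hi` | 0.7–1.3 | ratio band calling a SNP heterozygous |
| `hom_present` / `hom_absent` | 1.4 / 0.6 | homozygous call: retained allele above / lost allele below |
| `min_run` | 2 SNPs | shorter isolated state flips are absorbed by the flanking state |
| `smooth_window` | 3 SNPs | window a flip must fit inside to count as isolated |
| noise means | 0.25 / 1.0 / 1.75 | zero-, one-, two-copy hybridization means |
| noise `sd` | 0.12 | gaussian spread of simulated ratios |

The calling bands sit strictly inside the published two-copy (1.5–2) and
zero-copy (0–0.5) ranges, with unclaimed territory between the bands
yielding `AMBIGUOUS` calls rather than forced states; ambiguous markers are
skipped, never interpolated, so transition coordinates always sit on
observed SNPs. Smoothing is a transparent min-run rule rather than an HMM
for the same reason: event bookkeeping here is defined by flanking-SNP
coordinates, and a reassignment rule keeps those coordinates exact. The
homozygous-mean defaults (1.75 / 0.25) are the midpoints of the published
calling ranges, which state ranges rather than means.

## What the synthetic-data generator emulates

`generate_snp_map()` scatters markers uniformly; its defaults (2300
markers over 1.1 Mb) emulate the marker density of the screened
chromosome-IV right arm in a cross heterozygous for ~55,000 SNPs
genome-wide. `simulate_rco_event()` builds the four chromatid genotypes of
one sector pair from first principles — crossover position, lesion timing,
per-chromatid conversion tracts extending proximally from the exchange
point — and `emit_ratio_profiles()` inverts the calling convention to
produce noisy ratios. `simulate_rco_cohort()` fixes the study conditions:
crossover positions uniform over the interval, G1 lesions with probability
0.6 and conversionless crossovers with probability 0.12 (chosen to match
the reported preponderance of G1 events and the ~11–13% of crossovers
without detectable conversion), and tract lengths log-normal with median
10 kb and log-sd 0.6 (the published tract-length scale is a ~10 kb median;
the log-normal law and its spread are this package's modelling choice —
the source data report medians, not a generative law). G1 events draw two
independent lengths for the two broken sisters, so exactly equal realized
tracts (pure 4:0) are rare relative to hybrids, as observed in real data.
Complex tracts arise through `patchiness`, a per-bp rate at which a tract
alternates converted and unconverted pieces, emulating patchy mismatch
repair; it is off by default because no empirical switch-rate is
published.

The generator does **not** emulate probe-level microarray artifacts,
spatially correlated noise, segmental CNV other than the tandem-array
model, break-induced replication, or rDNA-internal events (the real arrays
carry no rDNA SNPs). Passing the round-trip tests therefore shows the
caller inverts this generative model exactly at noiseless settings and
robustly under gaussian noise — not that it reproduces every failure mode
of hybridization data.

`simulate_cup1_cnv()` models tandem-array instability as a per-subculture,
per-homolog Bernoulli event (probability `event_prob`) that deletes or
adds 1..`max_step` repeat units with truncated-geometric step sizes —
small changes more likely, magnitude distribution being a modelling choice
since only the deletion/addition counts are published. Copy counts floor
at 1. The parental arrays are 14 × 2.0 kb (fragment ~30 kb with a 2.0-kb
flank) and 7 × 1.2 kb (~12 kb with a 3.6-kb flank); the flank values are
back-solved so the fragment arithmetic reproduces the published sizes and
copy numbers exactly.

## Breakpoint-feature association

Each crossover contributes one window, from the last marker heterozygous
in both sectors to the first marker of the reciprocal zone — the region
most likely to have contained the initiating break, spanning the full
conversion tract. The fraction `f` of the screened space inside windows
(window lengths summed per event, overlapping windows *not* merged, since
each window belongs to a different sector; a merge flag exists for
sensitivity analysis) converts feature counts into expectations:
`expected = features_per_region x sectors x f`. Observed counts pair each
feature with each sector window it overlaps; large elements can be
collapsed to midpoints (`midpoint_rule`) so that size alone does not
inflate overlap. The comparison is a 1-df two-cell goodness-of-fit
chi-square without continuity correction (the variant is unstated in the
source; the uncorrected statistic is the score test whose null calibration
the test suite verifies). Feature classes are tested independently with
per-class reporting; Bonferroni correction is available but off by
default.

## Statistics

Proportions carry Wilson score intervals (Newcombe's Method 3, no
continuity correction), with exact 0/1 bounds at empty/full counts.
Fisher's exact test uses the minimum-likelihood two-sided convention;
the Mann-Whitney test is exact for small untied samples and uses the
tie-corrected normal approximation otherwise; the 2x2 chi-square is
uncorrected by default. Deletion/addition symmetry in tandem-array events
is tested as a two-sided exact binomial against 0.5 — the natural test of
the symmetry hypothesis, the original analysis not naming its test.

## Numerical and design choices

* Classification needs a distal reciprocal zone; sector pairs without one
  raise a "not a reciprocal crossover" error rather than guessing.
* The conversion zone is delimited by the *last* fully heterozygous region
  before any converted region and the start of the trailing reciprocal
  run; hybrids require their 3:1 flank(s) to share the 4:0 core's donor,
  donor-switching blocks being complex.
* Tracts reaching the map edge have no flanking marker; they are flagged
  `open_ended` with `NA` maximum rather than extrapolated.
* Round-trip tests disable smoothing (`min_run = 1`): profiles are
  noiseless there, and smoothing exists only to absorb miscalls, at the
  cost of erasing genuine single-marker tracts.
* Ground truth for recovery tests is the class *realized at marker
  resolution* (derived independently from the four chromatid genotype
  vectors), not the requested simulation parameters — a 10-kb tract
  falling between two markers is observationally conversionless.
* Seeds are mandatory for every stochastic entry point.

## Problem sizes in the shipped checks

The test suite and the acceptance script run: 500 simulated events on a
2300-marker map for the noiseless round trip (zero tolerated errors);
10,000 binomial replicates for Wilson coverage (required inside 93–97%);
1,000 null runs for enrichment p-value uniformity (Kolmogorov–Smirnov at
alpha 0.01); 10,000 seeds for the tandem-array altered-fraction closed
form 1 − (1 − p)^k; 200 replicate cohort pairs for type-I control of the
G1/G2 comparison; and exhaustive enumeration oracles for Fisher,
Mann-Whitney and interval overlap on small inputs.

## Known limitations

* Transition calls in manually curated datasets are made by eye; in noisy
  runs near a transition an automated boundary can differ by a marker.
* Complex-event timing uses only the ≥1-4:0-region criterion; the finer
  criteria used for some curated events are not published in
  reproducible form and are not guessed.
* Enrichment assumes features and windows on one chromosome arm and a
  uniform null; no correction is made for marker-density variation along
  the arm.
* The five-way class (plus timing and donor) is the endpoint; no attempt
  is made to reconstruct finer schematic subclasses of complex events.
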