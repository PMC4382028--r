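#' Sectoring rate with Wilson score confidence interval
#'
#' A red/white sectored colony records a reciprocal crossover at the
#' division that founded the colony, so the proportion of sectored colonies
#' among all colonies screened is a rate per division. The 95% confidence
#' interval is the Wilson score interval (Newcombe's Method 3, no
#' continuity correction).
#'
#' @param n_sectors number of sectored colonies observed.
#' @param n_colonies total colonies screened (> 0).
#' @param confidence confidence level, default 0.95.
#' @return A `rate_estimate` list: `n_events`, `n_trials`, `rate`, `ci95`.
#' @export
#' @examples
#' sectoring_rate(35, 1.3e6)
sectoring_rate <- function(n_sectors, n_colonies, confidence = 0.95) {
  if (n_colonies <= 0) stop("n_colonies must be positive")
  if (n_sectors < 0 || n_sectors > n_colonies)
    stop("n_sectors must lie in [0, n_colonies]")
  ci <- wilson_ci(n_sectors, n_colonies, confidence)
  structure(list(n_events = n_sectors, n_trials = n_colonies,
                 rate = n_sectors / n_colonies, ci95 = ci,
                 confidence = confidence),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("rate: %.3g per division (%d/%s), %g%% CI [%.3g, %.3g]\n",
              x$rate, x$n_events, format(x$n_trials, big.mark = ",",
                                         scientific = FALSE),
              100 * x$confidence, x$ci95[1L], x$ci95[2L]))
  invisible(x)
}

#' Wilson score interval for a binomial proportion
#'
#' The score interval without continuity correction (Newcombe's Method 3):
#' the set of p0 not rejected by the score test, with closed-form bounds
#' \deqn{(\hat p + z^2/2n \pm z\sqrt{\hat p(1-\hat p)/n + z^2/4n^2}) /
#'       (1 + z^2/n).}
#' The bounds are exactly 0 when no events are observed and exactly 1 when
#' every trial is an event.
#'
#' @param n_events events observed (0..n_trials).
#' @param n_trials trials (> 0).
#' @param confidence confidence level, default 0.95.
#' @return Numeric vector `c(low, high)`.
#' @export
wilson_ci <- function(n_events, n_trials, confidence = 0.95) {
  if (n_trials <= 0) stop("n_trials must be positive")
  if (n_events < 0 || n_events > n_trials)
    stop("n_events must lie in [0, n_trials]")
  if (confidence <= 0 || confidence >= 1)
    stop("confidence must be in (0, 1)")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- n_events / n_trials
  n <- n_trials
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  denom <- 1 + z^2 / n
  lo <- (centre - half) / denom
  hi <- (centre + half) / denom
  if (n_events == 0) lo <- 0
  if (n_events == n_trials) hi <- 1
  c(low = lo, high = hi)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact conditional test: the two-sided p-value sums the hypergeometric
#' probabilities of all tables (with the observed margins) no more probable
#' than the observed one (minimum-likelihood convention).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value. A table with an empty margin gives p = 1.
#' @export
#' @examples
#' fisher_exact(matrix(c(41, 37, 39, 82), 2, byrow = TRUE))
fisher_exact <- function(table) {
  table <- as_2x2(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  stats::fisher.test(table)$p.value
}

#' Pearson chi-square test on a 2x2 table
#'
#' One degree of freedom, without continuity correction by default (the
#' statistic then equals the square of the two-proportion z statistic).
#'
#' @param table 2x2 matrix of non-negative counts.
#' @param correct apply the Yates continuity correction.
#' @return List: `statistic`, `p_value`.
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  table <- as_2x2(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("chi-square test requires non-zero margins")
  res <- stats::chisq.test(table, correct = correct)
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

as_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop("a 2x2 table is required")
  if (any(table < 0) || anyNA(table))
    stop("table cells must be non-negative counts")
  table
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact p-value by enumeration for small untied samples (both n <= 20 and
#' no ties); otherwise the normal approximation with tie correction.
#'
#' @param x,y numeric samples (non-empty).
#' @return List: `statistic` (U for `x`), `p_value`, `exact`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty")
  exact <- length(x) <= 20L && length(y) <= 20L &&
    !anyDuplicated(c(x, y))
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = FALSE))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       exact = exact)
}

#' Fold change between two rate estimates
#'
#' @param rate_num,rate_den `rate_estimate` objects (or bare rates); the
#'   denominator rate must be positive.
#' @return Ratio of the point rates.
#' @export
fold_change <- function(rate_num, rate_den) {
  num <- if (inherits(rate_num, "rate_estimate")) rate_num$rate else rate_num
  den <- if (inherits(rate_den, "rate_estimate")) rate_den$rate else rate_den
  if (den <= 0) stop("denominator rate must be positive")
  num / den
}

#' Test for deletion bias in tandem-array copy-number events
#'
#' Two-sided exact binomial test of the hypothesis that deletions and
#' additions of repeat units are equally likely.
#'
#' @param n_deletions,n_additions observed event counts.
#' @return Two-sided p-value.
#' @export
deletion_bias_test <- function(n_deletions, n_additions) {
  if (n_deletions < 0 || n_additions < 0) stop("counts must be >= 0")
  n <- n_deletions + n_additions
  if (n == 0) stop("at least one event is required")
  stats::binom.test(n_deletions, n, p = 0.5)$p.value
}

#' Estimate tandem-array repeat copies from a restriction fragment
#'
#' Restriction enzymes cutting only in the array's flanking sequence release
#' a fragment of size `flank + unit * copies`; inverting gives
#' `copies = round((fragment - flank) / unit)`, floored at 0.
#'
#' @param fragment_kb observed fragment size, kb (>= `flank_kb`).
#' @param unit_kb repeat-unit size, kb (> 0).
#' @param flank_kb flanking sequence inside the fragment, kb.
#' @return Integer copy number.
#' @export
#' @examples
#' estimate_repeat_copies(30, 2, 2)    # the 14-copy parental array
#' estimate_repeat_copies(12, 1.2, 3.6)
estimate_repeat_copies <- function(fragment_kb, unit_kb, flank_kb) {
  if (unit_kb <= 0) stop("unit_kb must be positive")
  if (fragment_kb < flank_kb) stop("fragment_kb must be >= flank_kb")
  max(0L, as.integer(round((fragment_kb - flank_kb) / unit_kb)))
}

#' Classify a SpeI restriction genotype from fragment sizes
#'
#' The assayed polymorphism is a SpeI site present on the YJM789 allele
#' only, inside a ~750 bp PCR product: digestion yields 500 + 250 bp
#' fragments from the YJM789 allele and an uncut 750 bp fragment from the
#' W303-1A allele. A heterozygote shows all three fragments.
#'
#' @param fragment_sizes numeric vector of observed fragment sizes, bp.
#' @param tolerance size-matching tolerance, bp (default 30).
#' @return A `spei_genotype` list: `call` in
#'   `c("HET", "HOM_W303", "HOM_YJM789", "UNRESOLVED")` and the observed
#'   sizes.
#' @export
#' @examples
#' classify_spei_genotype(c(750, 500, 250))$call
classify_spei_genotype <- function(fragment_sizes, tolerance = 30) {
  if (length(fragment_sizes) == 0L)
    stop("at least one fragment size is required")
  near <- function(target) any(abs(fragment_sizes - target) <= tolerance)
  matched <- vapply(fragment_sizes, function(s)
    any(abs(s - c(750, 500, 250)) <= tolerance), TRUE)
  call <- if (!all(matched)) {
    "UNRESOLVED"
  } else if (near(750) && near(500) && near(250)) {
    "HET"
  } else if (near(500) && near(250) && !near(750)) {
    "HOM_YJM789"
  } else if (near(750) && !near(500) && !near(250)) {
    "HOM_W303"
  } else "UNRESOLVED"
  structure(list(call = call, fragment_sizes = fragment_sizes,
                 tolerance = tolerance),
            class = "spei_genotype")
}
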