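# Chromosome enrichment-bias statistic for retained methylation, with
# hypergeometric significance testing.
#
# Bookkeeping per chromosome, with the population restricted to probes
# highly methylated in the parental sample:
#   q = retained-high probes on the chromosome in the compromised sample
#   m = parental-high probes on the chromosome
#   n = parental-high probes NOT on the chromosome
#   k = genome-wide retained-high probes in the compromised sample
# Expected retained count by chance: e = (m / (m + n)) * k.
# Percent enrichment bias: 100 * (q - e) / k; positive means more retention
# than chance, negative less. Because the chromosomes partition the
# population, sum(q) = k, sum(e) = k, and the biases sum to zero.

#' Expected retained count under random allocation
#'
#' `e = (m / (m + n)) * k`: the number of retained-high probes a chromosome
#' would receive if retention ignored chromosome identity.
#'
#' @param m parental-high probes on the chromosome.
#' @param n parental-high probes elsewhere.
#' @param k genome-wide retained-high probes.
#' @return Expected count (real valued). Vectorized over its arguments.
#' @export
expected_retained <- function(m, n, k) {
  if (any(m < 0) || any(n < 0) || any(k < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(m + n == 0)) {
    stop("m + n must be positive (no parental-high probes at all)",
         call. = FALSE)
  }
  (m / (m + n)) * k
}

#' Percent enrichment bias
#'
#' `100 * (q - e) / k`. Positive values mean the chromosome retained more
#' methylation than expected by chance, negative values less.
#'
#' @param q observed retained count on the chromosome.
#' @param e expected count from [expected_retained()].
#' @param k genome-wide retained count; must be positive.
#' @return Percent bias. Vectorized.
#' @export
percent_enrichment_bias <- function(q, e, k) {
  if (any(k <= 0)) {
    stop("k must be positive to compute a percent bias", call. = FALSE)
  }
  100 * (q - e) / k
}

#' Direction-matched hypergeometric tail probability
#'
#' Models the retained set as `k` draws without replacement from a
#' population of `m + n` parental-high probes of which `m` sit on the
#' chromosome. Reports the upper tail `P(X >= q)` when `q >= e` (testing
#' enrichment) and the lower tail `P(X <= q)` when `q < e` (testing
#' depletion). The upper tail is computed as the survival function at
#' `q - 1`, so the observed count itself is included in the tail.
#'
#' @param q observed retained count on the chromosome.
#' @param m,n,k hypergeometric bookkeeping counts (see
#'   [expected_retained()]).
#' @return List with numeric `p_value` and character `tail` ("upper" or
#'   "lower"), each vectorized along the inputs.
#' @export
hypergeom_tail <- function(q, m, n, k) {
  if (any(q < 0) || any(m < 0) || any(n < 0) || any(k < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(q > m)) {
    stop("inconsistent counts: q cannot exceed m", call. = FALSE)
  }
  if (any(q > k)) {
    stop("inconsistent counts: q cannot exceed k", call. = FALSE)
  }
  if (any(k > m + n)) {
    stop("inconsistent counts: k cannot exceed the population m + n",
         call. = FALSE)
  }
  e <- expected_retained(m, n, k)
  upper <- q >= e
  p <- ifelse(upper,
              stats::phyper(q - 1, m, n, k, lower.tail = FALSE),
              stats::phyper(q, m, n, k, lower.tail = TRUE))
  list(p_value = as.numeric(p), tail = ifelse(upper, "upper", "lower"))
}

#' Per-chromosome enrichment-bias analysis of retained methylation
#'
#' Assembles the q/m/n/k bookkeeping from high-methylation calls at
#' `cutoff` in the parental and compromised samples, then computes the
#' expected count, percent enrichment bias, direction-matched
#' hypergeometric p-value and a significance flag at `alpha` for every
#' chromosome carrying parental-high probes. A Bonferroni-adjusted p-value
#' over the tested chromosomes is included as an extra labeled column; the
#' significance flag uses the raw p-value against the fixed `alpha`.
#'
#' @param betas beta matrix containing both samples.
#' @param manifest validated manifest.
#' @param parental_id,compromised_id sample ids.
#' @param cutoff high-methylation beta cutoff (default 0.7).
#' @param alpha significance threshold on the raw p-value (default 1e-6).
#' @param include_chrY keep chrY probes in the population (default FALSE;
#'   chrY is reported separately from the autosome + chrX analysis).
#' @return data.frame with columns `chromosome`, `q`, `m`, `n`, `k`, `e`,
#'   `pct_bias`, `p_value`, `tail`, `significant`, `p_bonferroni`, sorted
#'   by decreasing `pct_bias`.
#' @export
enrichment_analysis <- function(betas, manifest, parental_id, compromised_id,
                                cutoff = 0.7, alpha = 1e-6,
                                include_chrY = FALSE) {
  if (!all(rownames(betas) %in% manifest$probe_id)) {
    stop("manifest does not cover every probe in the beta matrix",
         call. = FALSE)
  }
  chrom <- manifest$chromosome[match(rownames(betas), manifest$probe_id)]
  keep <- if (include_chrY) rep(TRUE, length(chrom)) else chrom != "chrY"

  high_p <- call_high(betas, parental_id, cutoff) & keep
  retained <- high_p & call_high(betas, compromised_id, cutoff)
  total_high <- sum(high_p)
  if (total_high == 0) {
    stop("no parental-high probes at cutoff ", cutoff,
         "; enrichment analysis is undefined", call. = FALSE)
  }
  k <- sum(retained)

  chroms <- intersect(methret_chromosomes(), unique(chrom[high_p]))
  m <- vapply(chroms, function(ch) sum(high_p[chrom == ch]), integer(1))
  q <- vapply(chroms, function(ch) sum(retained[chrom == ch]), integer(1))
  n <- total_high - m
  e <- expected_retained(m, n, k)
  pct_bias <- if (k > 0) percent_enrichment_bias(q, e, k) else rep(NA_real_, length(q))
  ht <- hypergeom_tail(q, m, n, k)

  # partition identities hold analytically; guard against bookkeeping bugs
  stopifnot(sum(q) == k, isTRUE(all.equal(sum(e), k)))
  if (k > 0) stopifnot(abs(sum(pct_bias)) <= 1e-9 * max(1, abs(k)))

  out <- data.frame(chromosome = chroms, q = q, m = m, n = n, k = k, e = e,
                    pct_bias = pct_bias, p_value = ht$p_value, tail = ht$tail,
                    significant = ht$p_value <= alpha,
                    p_bonferroni = pmin(1, ht$p_value * length(chroms)),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$pct_bias), , drop = FALSE]
}
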