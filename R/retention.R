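# Per-chromosome quantification of retained high methylation between a
# parental sample and a DNMT-compromised sample.

#' Call high methylation in one sample
#'
#' A probe is called high when its beta value is at or above `cutoff`
#' (inclusive). Missing values are never called high: a masked probe carries
#' no evidence of methylation.
#'
#' @param betas beta matrix.
#' @param sample_id sample to call.
#' @param cutoff beta cutoff in (0,1); conventional choices are 0.6, 0.7
#'   and 0.85.
#' @return Named logical vector over probes.
#' @export
call_high <- function(betas, sample_id, cutoff) {
  if (!sample_id %in% colnames(betas)) {
    stop("unknown sample: ", sample_id, call. = FALSE)
  }
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0 || cutoff >= 1) {
    stop("cutoff must be a single value in (0,1)", call. = FALSE)
  }
  v <- betas[, sample_id]
  out <- !is.na(v) & v >= cutoff
  names(out) <- rownames(betas)
  out
}

#' Per-chromosome retention of high methylation
#'
#' For each chromosome and each beta cutoff, counts the probes highly
#' methylated in the parental sample (`n_parental_high`), the subset of
#' those still highly methylated in the compromised sample at the same
#' cutoff (`n_retained`; retention requires high calls in BOTH samples),
#' and the retention percentage `100 * n_retained / n_parental_high`.
#' `pct_retained` is `NA` (undefined, not zero) for a chromosome with no
#' parental-high probe. A `rank` column orders chromosomes from least to
#' most retained at `reference_cutoff`.
#'
#' @param betas beta matrix containing both samples.
#' @param manifest validated manifest covering all probes in `betas`.
#' @param parental_id,compromised_id sample ids.
#' @param cutoffs beta cutoffs (default `c(0.6, 0.7, 0.85)`).
#' @param reference_cutoff cutoff used for the chromosome ranking (default
#'   0.7); must be among `cutoffs`.
#' @return data.frame with columns `chromosome`, `cutoff`,
#'   `n_parental_high`, `n_retained`, `pct_retained`, `rank`.
#' @export
retention_table <- function(betas, manifest, parental_id, compromised_id,
                            cutoffs = c(0.6, 0.7, 0.85),
                            reference_cutoff = 0.7) {
  if (!all(rownames(betas) %in% manifest$probe_id)) {
    stop("manifest does not cover every probe in the beta matrix",
         call. = FALSE)
  }
  if (!reference_cutoff %in% cutoffs) {
    stop("reference_cutoff must be one of the requested cutoffs",
         call. = FALSE)
  }
  chrom <- manifest$chromosome[match(rownames(betas), manifest$probe_id)]
  chroms <- intersect(methret_chromosomes(), unique(manifest$chromosome))
  rows <- lapply(cutoffs, function(ct) {
    high_p <- call_high(betas, parental_id, ct)
    high_c <- call_high(betas, compromised_id, ct)
    retained <- high_p & high_c
    n_high <- vapply(chroms, function(ch) sum(high_p[chrom == ch]), integer(1))
    n_ret <- vapply(chroms, function(ch) sum(retained[chrom == ch]), integer(1))
    data.frame(chromosome = chroms, cutoff = ct,
               n_parental_high = n_high, n_retained = n_ret,
               pct_retained = ifelse(n_high > 0, 100 * n_ret / n_high, NA_real_),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ordered <- rank_chromosomes(tab, reference_cutoff)
  tab$rank <- match(tab$chromosome, ordered)
  tab
}

#' Rank chromosomes from least to most retained methylation
#'
#' Ascending order of `pct_retained` at `reference_cutoff`; ties broken by
#' chromosome label (lexicographic); chromosomes with undefined retention
#' (no parental-high probe) sort last, with a warning naming them.
#'
#' @param table a [retention_table()] result.
#' @param reference_cutoff cutoff at which to rank.
#' @return Character vector of chromosome labels, least retained first.
#' @export
rank_chromosomes <- function(table, reference_cutoff = 0.7) {
  ref <- table[table$cutoff == reference_cutoff, , drop = FALSE]
  if (nrow(ref) == 0) {
    stop("reference cutoff ", reference_cutoff, " not present in table",
         call. = FALSE)
  }
  undef <- ref$chromosome[is.na(ref$pct_retained)]
  if (length(undef) > 0) {
    warning("chromosome(s) with undefined retention ranked last: ",
            paste(undef, collapse = ", "), call. = FALSE)
  }
  ord <- order(is.na(ref$pct_retained), ref$pct_retained, ref$chromosome)
  ref$chromosome[ord]
}

#' Per-chromosome fraction of probes highly methylated in one sample
#'
#' The baseline-methylation check: the fraction of all (filtered) probes on
#' each chromosome whose beta is at or above `cutoff` in the given sample.
#' Parental lines show a roughly uniform fraction (~0.6) across
#' chromosomes, ruling out baseline bias as an explanation for differential
#' retention. Chromosomes with no probes get `NA`.
#'
#' @inheritParams retention_table
#' @param sample_id sample to profile.
#' @param cutoff beta cutoff (default 0.7).
#' @return data.frame with `chromosome`, `n_probes`, `n_high`, `fraction`.
#' @export
parental_high_fraction <- function(betas, manifest, sample_id, cutoff = 0.7) {
  if (!all(rownames(betas) %in% manifest$probe_id)) {
    stop("manifest does not cover every probe in the beta matrix",
         call. = FALSE)
  }
  chrom <- manifest$chromosome[match(rownames(betas), manifest$probe_id)]
  high <- call_high(betas, sample_id, cutoff)
  chroms <- intersect(methret_chromosomes(), unique(manifest$chromosome))
  n_probes <- vapply(chroms, function(ch) sum(chrom == ch), integer(1))
  n_high <- vapply(chroms, function(ch) sum(high[chrom == ch]), integer(1))
  data.frame(chromosome = chroms, n_probes = n_probes, n_high = n_high,
             fraction = ifelse(n_probes > 0, n_high / n_probes, NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}
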