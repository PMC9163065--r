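# Classification of demethylation-resistant promoter probes by their
# methylation status in non-cancer tissues.
#
# The point of the classification: a probe that stays highly methylated in
# both the parental cancer line and the DNMT1-compromised derivative is
# either (a) constitutively methylated in normal tissue, or (b) a site of
# cancer-acquired (de novo) hypermethylation. On the X chromosome the
# normal-tissue signature of an unmethylated CpG island differs by sex:
# males (one active X) are unmethylated, females show monoallelic
# methylation near 0.5 from X inactivation. The classifier therefore
# evaluates per-sex normal-tissue means under a chromosome-aware rule.

#' Classification thresholds
#'
#' `t_low` bounds "unmethylated" from above; `t_mono_low`/`t_mono_high`
#' bound the female monoallelic band around 0.5; `t_high` bounds
#' "methylated" from below (0.7, the same cutoff used for retention calls).
#'
#' @param t_low upper bound for an unmethylated mean beta (default 0.3).
#' @param t_mono_low,t_mono_high female monoallelic band (default
#'   \[0.3, 0.7\]).
#' @param t_high lower bound for a methylated mean beta (default 0.7).
#' @return Named list of thresholds.
#' @export
classification_thresholds <- function(t_low = 0.3, t_mono_low = 0.3,
                                      t_mono_high = 0.7, t_high = 0.7) {
  th <- list(t_low = t_low, t_mono_low = t_mono_low,
             t_mono_high = t_mono_high, t_high = t_high)
  vals <- unlist(th)
  if (any(vals < 0 | vals > 1) || t_mono_low > t_mono_high) {
    stop("thresholds must lie in [0,1] with t_mono_low <= t_mono_high",
         call. = FALSE)
  }
  th
}

#' Select promoter probes that resist demethylation
#'
#' Probes annotated as promoter-proximal whose beta value is at or above
#' `cutoff` in BOTH the parental and the resistant sample.
#'
#' @param betas beta matrix.
#' @param manifest validated manifest.
#' @param parental_id,resistant_id sample ids.
#' @param cutoff retention beta cutoff (default 0.7).
#' @return Character vector of probe ids (empty with a warning if none
#'   qualify).
#' @export
select_retained_promoter_probes <- function(betas, manifest, parental_id,
                                            resistant_id, cutoff = 0.7) {
  promoter <- manifest$is_promoter[match(rownames(betas), manifest$probe_id)]
  sel <- promoter & call_high(betas, parental_id, cutoff) &
    call_high(betas, resistant_id, cutoff)
  ids <- rownames(betas)[sel]
  if (length(ids) == 0) {
    warning("no promoter probe retains methylation at cutoff ", cutoff,
            call. = FALSE)
  }
  ids
}

#' Classify retained probes by normal-tissue methylation status
#'
#' For each probe, computes the mean beta across the non-cancer male panel
#' and the non-cancer female panel (samples with group `normal_tissue`),
#' then applies:
#'
#' * `methylated_in_normal`: both sex means at or above `t_high` — the site
#'   is constitutively methylated and its cancer methylation is not de novo.
#' * `unmethylated_in_normal` (de novo in cancer), chrX: male mean at or
#'   below `t_low` and female mean at or below `t_mono_high` — covering
#'   both the X-inactivation signature (female monoallelic, near 0.5) and
#'   X-inactivation-escaping sites (female unmethylated); the male mean
#'   anchors the call because the cell lines carry a single active X.
#' * `unmethylated_in_normal`, autosomes: both sex means at or below
#'   `t_low`.
#' * anything else: `unclassified`.
#'
#' @param betas beta matrix holding cell-line and normal-tissue samples.
#' @param manifest validated manifest.
#' @param sample_sheet sample sheet labelling groups and sexes.
#' @param probe_ids probes to classify (typically from
#'   [select_retained_promoter_probes()]).
#' @param parental_id,resistant_id cell-line sample ids (evidence columns).
#' @param thresholds a [classification_thresholds()] list.
#' @return data.frame with `probe_id`, `chromosome`, `position`,
#'   `category`, `male_mean`, `female_mean`, `parental_beta`,
#'   `resistant_beta`.
#' @export
classify_probes <- function(betas, manifest, sample_sheet, probe_ids,
                            parental_id, resistant_id,
                            thresholds = classification_thresholds()) {
  if (length(probe_ids) == 0) {
    stop("no probes to classify", call. = FALSE)
  }
  if (!all(probe_ids %in% rownames(betas))) {
    stop("probe_ids contains probes absent from the beta matrix",
         call. = FALSE)
  }
  male_ids <- sample_sheet$sample_id[sample_sheet$group == "normal_tissue" &
                                       sample_sheet$sex == "male"]
  female_ids <- sample_sheet$sample_id[sample_sheet$group == "normal_tissue" &
                                         sample_sheet$sex == "female"]
  if (length(male_ids) == 0 || length(female_ids) == 0) {
    stop("classification requires at least one normal-tissue sample of each sex",
         call. = FALSE)
  }
  sub <- betas[probe_ids, , drop = FALSE]
  male_mean <- rowMeans(sub[, male_ids, drop = FALSE], na.rm = TRUE)
  female_mean <- rowMeans(sub[, female_ids, drop = FALSE], na.rm = TRUE)
  chrom <- manifest$chromosome[match(probe_ids, manifest$probe_id)]
  pos <- manifest$position[match(probe_ids, manifest$probe_id)]
  th <- thresholds

  methylated <- male_mean >= th$t_high & female_mean >= th$t_high
  on_x <- chrom == "chrX"
  unmeth <- ifelse(on_x,
                   male_mean <= th$t_low & female_mean <= th$t_mono_high,
                   male_mean <= th$t_low & female_mean <= th$t_low)
  category <- rep("unclassified", length(probe_ids))
  category[unmeth] <- "unmethylated_in_normal"
  category[methylated] <- "methylated_in_normal"

  data.frame(probe_id = probe_ids, chromosome = chrom, position = pos,
             category = category, male_mean = male_mean,
             female_mean = female_mean,
             parental_beta = sub[, parental_id],
             resistant_beta = sub[, resistant_id],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarize classification calls
#'
#' Counts per category and the de novo percentage
#' `100 * n_de_novo / (n_de_novo + n_methylated_normal)` (unclassified
#' probes are excluded from that denominator), either genome-wide or
#' restricted to chrX. Genome-wide summaries also report which share of the
#' de novo probes sit on chrX.
#'
#' @param calls a [classify_probes()] result (or any data.frame with
#'   `probe_id`, `chromosome`, `category`).
#' @param scope `"genome_wide"` or `"chrX_only"`.
#' @return One-row data.frame with `scope`, `n_total`, `n_de_novo`,
#'   `n_methylated_normal`, `n_unclassified`, `pct_de_novo` and (genome-wide
#'   scope only) `pct_de_novo_on_chrX`.
#' @export
classification_summary <- function(calls, scope = c("genome_wide", "chrX_only")) {
  scope <- match.arg(scope)
  if (nrow(calls) == 0) stop("calls must be nonempty", call. = FALSE)
  sub <- if (scope == "chrX_only") {
    calls[calls$chromosome == "chrX", , drop = FALSE]
  } else {
    calls
  }
  n_de_novo <- sum(sub$category == "unmethylated_in_normal")
  n_meth <- sum(sub$category == "methylated_in_normal")
  n_uncl <- sum(sub$category == "unclassified")
  denom <- n_de_novo + n_meth
  pct_x_share <- if (scope == "genome_wide") {
    n_x <- sum(calls$category == "unmethylated_in_normal" &
                 calls$chromosome == "chrX")
    if (n_de_novo > 0) 100 * n_x / n_de_novo else NA_real_
  } else {
    NA_real_
  }
  data.frame(scope = scope, n_total = nrow(sub), n_de_novo = n_de_novo,
             n_methylated_normal = n_meth, n_unclassified = n_uncl,
             pct_de_novo = if (denom > 0) 100 * n_de_novo / denom else NA_real_,
             pct_de_novo_on_chrX = pct_x_share,
             stringsAsFactors = FALSE)
}

#' Extract a locus-level beta profile
#'
#' Returns, for all probes inside a genomic interval, their beta values
#' across samples ordered by genomic position, plus per-group means when a
#' sample sheet is supplied — the data layer behind flanking-probe heatmaps
#' around a locus of interest. Reversed coordinates are normalized
#' (`start > end` is swapped); the interval is closed on both ends in
#' 1-based coordinates.
#'
#' @param betas beta matrix.
#' @param manifest validated manifest.
#' @param chromosome chromosome label.
#' @param start,end interval bounds (1-based, inclusive).
#' @param sample_sheet optional sample sheet; when given, group means are
#'   attached.
#' @return List with `probes` (data.frame `probe_id`, `position`), `beta`
#'   (matrix, probes x samples, position-ordered) and `group_means`
#'   (matrix probes x groups, or NULL). Empty interval yields zero-row
#'   components with a warning.
#' @export
locus_profile <- function(betas, manifest, chromosome, start, end,
                          sample_sheet = NULL) {
  if (start > end) {
    tmp <- start; start <- end; end <- tmp
  }
  rows <- manifest[manifest$chromosome == chromosome &
                     manifest$position >= start & manifest$position <= end &
                     manifest$probe_id %in% rownames(betas), , drop = FALSE]
  rows <- rows[order(rows$position), , drop = FALSE]
  if (nrow(rows) == 0) {
    warning("no probes in ", chromosome, ":", start, "-", end, call. = FALSE)
  }
  beta <- betas[rows$probe_id, , drop = FALSE]
  group_means <- NULL
  if (!is.null(sample_sheet) && nrow(rows) > 0) {
    groups <- unique(sample_sheet$group)
    group_means <- vapply(groups, function(g) {
      ids <- intersect(sample_sheet$sample_id[sample_sheet$group == g],
                       colnames(beta))
      if (length(ids) == 0) return(rep(NA_real_, nrow(beta)))
      rowMeans(beta[, ids, drop = FALSE], na.rm = TRUE)
    }, numeric(nrow(beta)))
    if (nrow(beta) == 1) group_means <- matrix(group_means, nrow = 1,
                                               dimnames = list(rows$probe_id,
                                                               groups))
    rownames(group_means) <- rows$probe_id
  }
  list(probes = rows[, c("probe_id", "position")], beta = beta,
       group_means = group_means)
}
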