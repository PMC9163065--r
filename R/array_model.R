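# Domain types and I/O shared by all pipeline stages.
#
# A beta matrix is represented as a plain numeric matrix (probes x samples)
# with probe ids as rownames and sample ids as colnames; NA marks a masked
# (missing) value. A probe manifest and a sample sheet are data.frames.
# Validators are exposed so matrices built in code get the same checks as
# matrices read from disk.

#' Chromosome labels accepted in a probe manifest
#'
#' Autosomes `chr1`..`chr22` plus the sex chromosomes. Probes on any other
#' label are rejected at read time.
#'
#' @export
methret_chromosomes <- function() paste0("chr", c(1:22, "X", "Y"))

#' Genomic context labels and the promoter subset
#'
#' Infinium-style probe annotation contexts. By convention probes annotated
#' `TSS200`, `TSS1500` or `5UTR` are treated as promoter-proximal; this is
#' the usual reading of "vicinity of a promoter" for these arrays and can be
#' overridden via the `promoter_contexts` argument of [read_manifest()].
#'
#' @export
methret_contexts <- function() {
  c("TSS200", "TSS1500", "5UTR", "body", "3UTR", "intergenic")
}

#' @rdname methret_contexts
#' @export
methret_promoter_contexts <- function() c("TSS200", "TSS1500", "5UTR")

#' Validate a probe manifest data.frame
#'
#' Checks column presence, chromosome labels, 1-based positions, genomic
#' contexts, strand labels and probe-id uniqueness, and (re)derives the
#' `is_promoter` column from `genomic_context`.
#'
#' @param manifest data.frame with columns `probe_id`, `chromosome`,
#'   `position`, `genomic_context` and optionally `strand`.
#' @param promoter_contexts character vector of contexts flagged as promoter.
#' @return The validated manifest with columns `probe_id`, `chromosome`,
#'   `position`, `genomic_context`, `strand`, `is_promoter`.
#' @export
validate_manifest <- function(manifest,
                              promoter_contexts = methret_promoter_contexts()) {
  required <- c("probe_id", "chromosome", "position", "genomic_context")
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols) > 0) {
    stop("manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  manifest$probe_id <- as.character(manifest$probe_id)
  dup <- unique(manifest$probe_id[duplicated(manifest$probe_id)])
  if (length(dup) > 0) {
    stop("duplicate probe_id in manifest: ",
         paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  }
  bad_chr <- setdiff(unique(manifest$chromosome), methret_chromosomes())
  if (length(bad_chr) > 0) {
    stop("unknown chromosome label(s) in manifest: ",
         paste(bad_chr, collapse = ", "), call. = FALSE)
  }
  manifest$position <- as.integer(manifest$position)
  if (anyNA(manifest$position) || any(manifest$position < 1L)) {
    stop("manifest positions must be integers >= 1 (1-based coordinates)",
         call. = FALSE)
  }
  bad_ctx <- setdiff(unique(manifest$genomic_context), methret_contexts())
  if (length(bad_ctx) > 0) {
    stop("unknown genomic_context label(s): ",
         paste(bad_ctx, collapse = ", "), call. = FALSE)
  }
  if (is.null(manifest$strand)) manifest$strand <- "unknown"
  bad_strand <- setdiff(unique(manifest$strand), c("+", "-", "unknown"))
  if (length(bad_strand) > 0) {
    stop("strand must be one of '+', '-', 'unknown'; got: ",
         paste(bad_strand, collapse = ", "), call. = FALSE)
  }
  manifest$is_promoter <- manifest$genomic_context %in% promoter_contexts
  rownames(manifest) <- NULL
  manifest[, c("probe_id", "chromosome", "position", "genomic_context",
               "strand", "is_promoter")]
}

#' Read a probe manifest from CSV
#'
#' The file must have a header row with at least `probe_id`, `chromosome`,
#' `position` and `genomic_context`; a `strand` column is optional. The
#' `is_promoter` flag is derived from `genomic_context`.
#'
#' @inheritParams validate_manifest
#' @param path path to a CSV file.
#' @return Validated manifest data.frame (see [validate_manifest()]).
#' @export
read_manifest <- function(path, promoter_contexts = methret_promoter_contexts()) {
  manifest <- utils::read.csv(path, stringsAsFactors = FALSE,
                              comment.char = "#")
  validate_manifest(manifest, promoter_contexts = promoter_contexts)
}

#' Write a probe manifest to CSV
#'
#' @param manifest validated manifest data.frame.
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest[, c("probe_id", "chromosome", "position",
                                "genomic_context", "strand")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a beta-value matrix
#'
#' @param betas numeric matrix, probes as rows, samples as columns, with
#'   unique rownames (probe ids) and colnames (sample ids). NA marks missing.
#' @return The matrix, invisibly unchanged, after validation.
#' @export
validate_beta_matrix <- function(betas) {
  if (!is.matrix(betas) || !is.numeric(betas)) {
    stop("beta matrix must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(betas)) || is.null(colnames(betas))) {
    stop("beta matrix must carry probe ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(betas)) || anyDuplicated(colnames(betas))) {
    stop("beta matrix probe and sample ids must be unique", call. = FALSE)
  }
  bad <- which(!is.na(betas) & (betas < 0 | betas > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("beta value out of [0,1] at probe '%s', sample '%s' (value %g)",
                 rownames(betas)[bad[1, 1]], colnames(betas)[bad[1, 2]],
                 betas[bad[1, 1], bad[1, 2]]), call. = FALSE)
  }
  betas
}

#' Read a beta-value (or detection p-value) matrix from TSV
#'
#' First column is `probe_id`; each remaining column is one sample. Empty
#' cells and the literal `NA` are treated as missing. Values are validated
#' to lie in \[0,1\].
#'
#' @param path path to a tab-separated file.
#' @return Numeric matrix with probe rownames and sample colnames.
#' @export
read_beta_matrix <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""), comment.char = "#")
  if (ncol(tab) < 2) {
    stop("beta matrix file needs a probe_id column plus at least one sample column",
         call. = FALSE)
  }
  probe_ids <- as.character(tab[[1]])
  values <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- probe_ids
  validate_beta_matrix(values)
}

#' Write a beta-value matrix to TSV
#'
#' Inverse of [read_beta_matrix()] up to floating-point formatting (15
#' significant digits, so round trips are exact for practical purposes).
#'
#' @param betas validated beta matrix.
#' @param path output path.
#' @export
write_beta_matrix <- function(betas, path) {
  validate_beta_matrix(betas)
  df <- data.frame(probe_id = rownames(betas),
                   format(betas, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a sample sheet from CSV
#'
#' Requires columns `sample_id`, `group`, `sex`, `tissue`. Groups come from
#' the fixed vocabulary `parental`, `resistant`, `dko`, `normal_tissue`,
#' `tumor`, `adjacent_normal`.
#'
#' @param path path to a CSV file.
#' @return Validated sample sheet data.frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  validate_sample_sheet(sheet)
}

#' @rdname read_sample_sheet
#' @param sheet data.frame to validate in place of a file.
#' @export
validate_sample_sheet <- function(sheet) {
  required <- c("sample_id", "group", "sex", "tissue")
  missing_cols <- setdiff(required, names(sheet))
  if (length(missing_cols) > 0) {
    stop("sample sheet is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicate sample_id in sample sheet", call. = FALSE)
  }
  groups <- c("parental", "resistant", "dko", "normal_tissue", "tumor",
              "adjacent_normal")
  bad <- setdiff(unique(sheet$group), groups)
  if (length(bad) > 0) {
    stop("unknown sample group(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad_sex <- setdiff(unique(sheet$sex), c("male", "female"))
  if (length(bad_sex) > 0) {
    stop("sex must be 'male' or 'female'; got: ",
         paste(bad_sex, collapse = ", "), call. = FALSE)
  }
  rownames(sheet) <- NULL
  sheet
}

#' Write a sample sheet to CSV
#'
#' @param sheet validated sample sheet.
#' @param path output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remove probes failing the detection p-value check in any sample
#'
#' A probe is kept only if its detection p-value is at or below `threshold`
#' in every sample; a probe failing in any single sample is removed. Missing
#' detection p-values count as failures, since the probe's reliability cannot
#' be established. Surviving probes keep their original order. The number of
#' probes removed is attached as attribute `n_removed`.
#'
#' @param betas beta matrix (probes x samples).
#' @param detection_p detection p-value matrix of identical shape and
#'   dimnames.
#' @param threshold maximum acceptable detection p-value, in (0,1).
#'   Defaults to 0.05.
#' @return Filtered beta matrix with attribute `n_removed`.
#' @export
apply_detection_filter <- function(betas, detection_p, threshold = 0.05) {
  validate_beta_matrix(betas)
  if (!is.matrix(detection_p) ||
      !identical(dim(betas), dim(detection_p)) ||
      !identical(rownames(betas), rownames(detection_p)) ||
      !identical(colnames(betas), colnames(detection_p))) {
    stop("detection p matrix must match the beta matrix in shape and dimnames",
         call. = FALSE)
  }
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1) {
    stop("threshold must be a single probability in (0,1)", call. = FALSE)
  }
  fails <- is.na(detection_p) | detection_p > threshold
  keep <- rowSums(fails) == 0L
  out <- betas[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Order-statistic summary of one sample's beta values
#'
#' Mean, median, quartiles and the 5th/95th percentiles over the non-missing
#' probe values of a sample, the statistics used for box-and-whisker style
#' summaries of array-wide methylation. Quantiles use linear interpolation
#' between order statistics ([stats::quantile()] type 7).
#'
#' @param betas beta matrix.
#' @param sample_id a sample present in `colnames(betas)`.
#' @return One-row data.frame with `sample_id`, `mean`, `median`, `q25`,
#'   `q75`, `p5`, `p95`, `n_probes_used`.
#' @export
summarize_beta <- function(betas, sample_id) {
  validate_beta_matrix(betas)
  if (!sample_id %in% colnames(betas)) {
    stop("unknown sample: ", sample_id, call. = FALSE)
  }
  v <- betas[, sample_id]
  v <- v[!is.na(v)]
  if (length(v) == 0) {
    stop("sample '", sample_id, "' has no non-missing beta values",
         call. = FALSE)
  }
  qs <- stats::quantile(v, probs = c(0.05, 0.25, 0.5, 0.75, 0.95),
                        names = FALSE, type = 7)
  data.frame(sample_id = sample_id, mean = mean(v), median = qs[3],
             q25 = qs[2], q75 = qs[4], p5 = qs[1], p95 = qs[5],
             n_probes_used = length(v), stringsAsFactors = FALSE)
}

#' Export a probe set as BED
#'
#' Point probes are written as 0-based half-open single-base intervals
#' `[position - 1, position)`, converting from the 1-based manifest
#' convention.
#'
#' @param manifest validated manifest.
#' @param probe_ids probes to export (default: all).
#' @param path output path.
#' @export
probes_to_bed <- function(manifest, path, probe_ids = manifest$probe_id) {
  rows <- manifest[manifest$probe_id %in% probe_ids, , drop = FALSE]
  bed <- data.frame(chrom = rows$chromosome,
                    start = rows$position - 1L,
                    end = rows$position,
                    name = rows$probe_id,
                    score = 0L,
                    strand = ifelse(rows$strand == "unknown", ".", rows$strand))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
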