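# Full-pipeline entry point: QC filter -> per-sample summaries -> retention
# -> enrichment -> classification (-> cohort), with a run manifest for
# reproducibility. All stage outputs are plain TSV with '#' header comments
# recording the generating parameters.

pipeline_fields <- c(
  "manifest", "betas", "detection_p", "samples", "outdir",
  "parental_id", "compromised_id", "resistant_id",
  "cohort_betas", "cohort_samples", "cohort_probes",
  "detection_threshold", "cutoffs", "reference_cutoff",
  "enrichment_cutoff", "alpha", "classification", "seed"
)

#' Build a validated pipeline configuration
#'
#' Paths point at the file dialects the readers expect (manifest CSV, beta
#' and detection-p TSV, sample-sheet CSV). Parameter defaults are the
#' analysis' standard operating values: detection threshold 0.05, retention
#' cutoffs 0.6 / 0.7 / 0.85, enrichment cutoff 0.7, significance threshold
#' 1e-6. Unknown arguments are rejected by name, so a mistyped parameter
#' cannot silently fall back to a default.
#'
#' @param manifest,betas,samples input file paths (required).
#' @param detection_p optional detection p-value matrix path; when absent
#'   the QC stage is skipped.
#' @param outdir output directory.
#' @param parental_id,compromised_id sample ids for retention/enrichment.
#' @param resistant_id sample id for classification (defaults to
#'   `compromised_id`).
#' @param cohort_betas,cohort_samples optional cohort stage inputs.
#' @param cohort_probes optional path to a text file of probe ids for the
#'   cohort stage (default: the de novo probes from classification).
#' @param detection_threshold,cutoffs,reference_cutoff,enrichment_cutoff,alpha
#'   stage parameters.
#' @param classification a [classification_thresholds()] list.
#' @param seed integer recorded in the run manifest (the pipeline itself is
#'   deterministic; the seed documents any upstream simulation).
#' @param ... rejected; present so unknown keys raise an error naming them.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest, betas, samples, outdir,
                            parental_id, compromised_id,
                            resistant_id = compromised_id,
                            detection_p = NULL,
                            cohort_betas = NULL, cohort_samples = NULL,
                            cohort_probes = NULL,
                            detection_threshold = 0.05,
                            cutoffs = c(0.6, 0.7, 0.85),
                            reference_cutoff = 0.7,
                            enrichment_cutoff = 0.7,
                            alpha = 1e-6,
                            classification = classification_thresholds(),
                            seed = 1L, ...) {
  extra <- list(...)
  if (length(extra) > 0) {
    nm <- names(extra)
    nm[nm == ""] <- "<unnamed>"
    stop("unknown pipeline config key(s): ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  cfg <- list(manifest = manifest, betas = betas, samples = samples,
              outdir = outdir, parental_id = parental_id,
              compromised_id = compromised_id, resistant_id = resistant_id,
              detection_p = detection_p, cohort_betas = cohort_betas,
              cohort_samples = cohort_samples, cohort_probes = cohort_probes,
              detection_threshold = detection_threshold, cutoffs = cutoffs,
              reference_cutoff = reference_cutoff,
              enrichment_cutoff = enrichment_cutoff, alpha = alpha,
              classification = classification, seed = as.integer(seed))
  for (f in c("manifest", "betas", "samples")) {
    if (!file.exists(cfg[[f]])) {
      stop("pipeline input '", f, "' not found: ", cfg[[f]], call. = FALSE)
    }
  }
  structure(cfg, class = "pipeline_config")
}

write_stage_tsv <- function(df, path, params) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(params)) {
    writeLines(sprintf("# %s=%s", nm,
                       paste(format(params[[nm]]), collapse = ",")), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Run the full retained-methylation pipeline
#'
#' Executes, in order: detection-p QC filtering (when a detection matrix is
#' configured), per-sample beta summaries, the per-chromosome retention
#' table, the chromosome enrichment-bias analysis, classification of
#' retained promoter probes against the normal-tissue panel, and (when
#' cohort inputs are configured) the tumor/adjacent-normal cohort summary.
#' Each stage writes a TSV under `outdir`; a `run_manifest.json` records
#' package version, parameters, input checksums and seed. Any stage error
#' aborts with a stage-named message and leaves an `INCOMPLETE` marker file
#' in `outdir`.
#'
#' @param config a [pipeline_config()].
#' @return Invisible list of the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  marker <- file.path(outdir, "INCOMPLETE")
  file.create(marker)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  manifest <- stage("read_inputs", read_manifest(config$manifest))
  betas <- stage("read_inputs", read_beta_matrix(config$betas))
  samples <- stage("read_inputs", read_sample_sheet(config$samples))

  n_removed <- 0L
  if (!is.null(config$detection_p)) {
    detection_p <- stage("qc", read_beta_matrix(config$detection_p))
    betas <- stage("qc", apply_detection_filter(betas, detection_p,
                                                config$detection_threshold))
    n_removed <- attr(betas, "n_removed")
  }
  write_stage_tsv(data.frame(n_probes = nrow(betas), n_removed = n_removed,
                             threshold = config$detection_threshold),
                  file.path(outdir, "qc.tsv"),
                  list(stage = "qc",
                       detection_threshold = config$detection_threshold,
                       filtered = !is.null(config$detection_p)))

  summaries <- stage("summarize", do.call(rbind, lapply(
    colnames(betas), function(s) summarize_beta(betas, s))))
  write_stage_tsv(summaries, file.path(outdir, "beta_summary.tsv"),
                  list(stage = "summarize"))

  retention <- stage("retention", retention_table(
    betas, manifest, config$parental_id, config$compromised_id,
    cutoffs = config$cutoffs, reference_cutoff = config$reference_cutoff))
  write_stage_tsv(retention, file.path(outdir, "retention.tsv"),
                  list(stage = "retention", parental = config$parental_id,
                       compromised = config$compromised_id,
                       cutoffs = config$cutoffs,
                       reference_cutoff = config$reference_cutoff))

  enrichment <- stage("enrichment", enrichment_analysis(
    betas, manifest, config$parental_id, config$compromised_id,
    cutoff = config$enrichment_cutoff, alpha = config$alpha))
  write_stage_tsv(enrichment, file.path(outdir, "enrichment.tsv"),
                  list(stage = "enrichment", cutoff = config$enrichment_cutoff,
                       alpha = config$alpha))

  selected <- stage("classification", select_retained_promoter_probes(
    betas, manifest, config$parental_id, config$resistant_id,
    cutoff = config$enrichment_cutoff))
  classification <- NULL
  if (length(selected) > 0) {
    classification <- stage("classification", classify_probes(
      betas, manifest, samples, selected, config$parental_id,
      config$resistant_id, thresholds = config$classification))
    write_stage_tsv(classification, file.path(outdir, "classification.tsv"),
                    list(stage = "classification",
                         cutoff = config$enrichment_cutoff,
                         thresholds = unlist(config$classification)))
    summary_rows <- rbind(classification_summary(classification, "genome_wide"),
                          classification_summary(classification, "chrX_only"))
    write_stage_tsv(summary_rows,
                    file.path(outdir, "classification_summary.tsv"),
                    list(stage = "classification_summary"))
  }

  cohort <- NULL
  if (!is.null(config$cohort_betas) && !is.null(config$cohort_samples)) {
    cohort_betas <- stage("cohort", read_beta_matrix(config$cohort_betas))
    cohort_samples <- stage("cohort", read_sample_sheet(config$cohort_samples))
    probe_set <- if (!is.null(config$cohort_probes)) {
      readLines(config$cohort_probes)
    } else if (!is.null(classification)) {
      classification$probe_id[classification$category == "unmethylated_in_normal"]
    } else {
      character(0)
    }
    probe_set <- intersect(probe_set, rownames(cohort_betas))
    if (length(probe_set) > 0) {
      cohort <- stage("cohort", cohort_summary(cohort_betas, cohort_samples,
                                               probe_set))
      write_stage_tsv(cohort, file.path(outdir, "cohort.tsv"),
                      list(stage = "cohort",
                           sample_order = attr(cohort, "sample_order")))
    }
  }

  run_manifest <- list(
    package = "methretain",
    version = as.character(utils::packageVersion("methretain")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    parameters = list(
      detection_threshold = config$detection_threshold,
      cutoffs = config$cutoffs,
      reference_cutoff = config$reference_cutoff,
      enrichment_cutoff = config$enrichment_cutoff,
      alpha = config$alpha,
      classification = config$classification
    ),
    inputs = {
      paths <- Filter(Negate(is.null),
                      config[c("manifest", "betas", "detection_p", "samples",
                               "cohort_betas", "cohort_samples")])
      lapply(paths, function(p) list(path = p,
                                     md5 = unname(tools::md5sum(p))))
    }
  )
  jsonlite::write_json(run_manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  file.remove(marker)
  invisible(list(betas = betas, summaries = summaries, retention = retention,
                 enrichment = enrichment, classification = classification,
                 cohort = cohort))
}
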