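# Descriptive cross-cohort validation: per-probe methylation summarized by
# sex and tissue type in a tumor / adjacent-normal cohort.

#' Intersect a probe set with another platform's manifest
#'
#' Used when carrying probes identified on one array platform (e.g. EPIC)
#' into a cohort profiled on another (e.g. HM450): only the shared probes
#' can be queried.
#'
#' @param query_probes character vector of probe ids.
#' @param target_manifest validated manifest of the target platform (or any
#'   data.frame with a `probe_id` column).
#' @return List with `n_query`, `n_target`, `n_shared` and `shared` (the
#'   probe ids present on both platforms, in query order). Zero overlap
#'   warns and returns an empty set.
#' @export
intersect_probe_sets <- function(query_probes, target_manifest) {
  if (length(query_probes) == 0 || nrow(target_manifest) == 0) {
    stop("both probe sets must be nonempty", call. = FALSE)
  }
  shared <- query_probes[query_probes %in% target_manifest$probe_id]
  if (length(shared) == 0) {
    warning("no probes shared between the query set and the target manifest",
            call. = FALSE)
  }
  list(n_query = length(query_probes), n_target = nrow(target_manifest),
       n_shared = length(shared), shared = shared)
}

#' Summarize a tumor / adjacent-normal cohort at selected probes
#'
#' Per probe: mean beta and sample count in each (sex x tissue-type) cell;
#' the fraction of tumor samples called hypermethylated
#' (`tumor_hyper_fraction`); and the tumor-minus-adjacent-normal mean
#' difference per sex (`delta_mean_female`, `delta_mean_male`). Deltas are
#' sex-stratified because baseline X methylation differs by sex. Cells with
#' no samples are `NA`.
#'
#' The hyper call is relative by default: a tumor sample is hypermethylated
#' at a probe when its beta exceeds the sex-matched adjacent-normal mean by
#' at least `hyper_margin`. Passing `hyper_cutoff` switches to an absolute
#' call (beta >= cutoff) that ignores the adjacent normals.
#'
#' Rows are ordered by `tumor_hyper_fraction` descending. The attribute
#' `sample_order` gives a plot-ready column ordering: samples arranged
#' first by biological sex (female, then male) and within sex by tissue
#' type (tumor, then adjacent normal).
#'
#' @param betas cohort beta matrix (probes x samples).
#' @param sample_sheet sample sheet with groups `tumor` /
#'   `adjacent_normal` and sexes.
#' @param probe_set probes to summarize; must be present in `betas`.
#' @param hyper_margin beta increment over the sex-matched adjacent-normal
#'   mean for the relative hyper call (default 0.3).
#' @param hyper_cutoff optional absolute beta cutoff replacing the relative
#'   call (e.g. 0.7).
#' @return data.frame, one row per probe, with per-cell means/counts,
#'   `tumor_hyper_fraction` and per-sex deltas; attribute `sample_order`.
#' @export
cohort_summary <- function(betas, sample_sheet, probe_set,
                           hyper_margin = 0.3, hyper_cutoff = NULL) {
  if (length(probe_set) == 0) stop("probe_set must be nonempty", call. = FALSE)
  if (!all(probe_set %in% rownames(betas))) {
    stop("probe_set contains probes absent from the beta matrix",
         call. = FALSE)
  }
  sheet <- sample_sheet[sample_sheet$sample_id %in% colnames(betas), ,
                        drop = FALSE]
  sub <- betas[probe_set, , drop = FALSE]

  cell_ids <- function(sex, group) {
    sheet$sample_id[sheet$sex == sex & sheet$group == group]
  }
  cells <- expand.grid(sex = c("female", "male"),
                       group = c("tumor", "adjacent_normal"),
                       stringsAsFactors = FALSE)
  out <- data.frame(probe_id = probe_set, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cells))) {
    ids <- cell_ids(cells$sex[i], cells$group[i])
    label <- paste0(cells$sex[i], "_",
                    ifelse(cells$group[i] == "tumor", "tumor", "normal"))
    if (length(ids) == 0) {
      out[[paste0("mean_", label)]] <- NA_real_
      out[[paste0("n_", label)]] <- 0L
    } else {
      out[[paste0("mean_", label)]] <-
        rowMeans(sub[, ids, drop = FALSE], na.rm = TRUE)
      out[[paste0("n_", label)]] <- length(ids)
    }
  }

  tumor_ids <- sheet$sample_id[sheet$group == "tumor"]
  if (length(tumor_ids) == 0) {
    out$tumor_hyper_fraction <- NA_real_
  } else {
    tumor_sex <- sheet$sex[match(tumor_ids, sheet$sample_id)]
    if (is.null(hyper_cutoff)) {
      hyper <- vapply(seq_along(probe_set), function(j) {
        base_f <- out$mean_female_normal[j]
        base_m <- out$mean_male_normal[j]
        base <- ifelse(tumor_sex == "female", base_f, base_m)
        calls <- sub[j, tumor_ids] >= base + hyper_margin
        mean(calls, na.rm = TRUE)
      }, numeric(1))
    } else {
      hyper <- rowMeans(sub[, tumor_ids, drop = FALSE] >= hyper_cutoff,
                        na.rm = TRUE)
    }
    out$tumor_hyper_fraction <- as.numeric(hyper)
  }

  out$delta_mean_female <- out$mean_female_tumor - out$mean_female_normal
  out$delta_mean_male <- out$mean_male_tumor - out$mean_male_normal

  out <- out[order(-out$tumor_hyper_fraction), , drop = FALSE]
  rownames(out) <- NULL

  ord <- order(factor(sheet$sex, levels = c("female", "male")),
               factor(sheet$group, levels = c("tumor", "adjacent_normal")),
               sheet$sample_id)
  attr(out, "sample_order") <- sheet$sample_id[ord]
  out
}
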