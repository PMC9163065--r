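# Shared fixture builders. Everything is generated in code; the one large
# simulated dataset is built once per test run and cached.

make_manifest <- function(n_per_chrom = c(chr1 = 4, chr2 = 4, chrX = 4)) {
  chrom <- rep(names(n_per_chrom), n_per_chrom)
  n <- length(chrom)
  validate_manifest(data.frame(
    probe_id = sprintf("cg%07d", seq_len(n)),
    chromosome = chrom,
    position = rep(seq(1000, by = 1000, length.out = max(n_per_chrom)),
                   length(n_per_chrom))[seq_len(n)],
    genomic_context = rep(c("TSS200", "body"), length.out = n),
    strand = "+",
    stringsAsFactors = FALSE
  ))
}

make_betas <- function(values, probe_ids = NULL, sample_ids = NULL) {
  m <- as.matrix(values)
  if (!is.null(probe_ids)) rownames(m) <- probe_ids
  if (is.null(rownames(m))) rownames(m) <- sprintf("cg%07d", seq_len(nrow(m)))
  if (!is.null(sample_ids)) colnames(m) <- sample_ids
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  validate_beta_matrix(m)
}

normal_sheet <- function(n_male = 2, n_female = 2) {
  validate_sample_sheet(data.frame(
    sample_id = c("parental", "resistant",
                  sprintf("nm%d", seq_len(n_male)),
                  sprintf("nf%d", seq_len(n_female))),
    group = c("parental", "resistant", rep("normal_tissue", n_male + n_female)),
    sex = c("male", "male", rep("male", n_male), rep("female", n_female)),
    tissue = c("cell_line", "cell_line", rep("colon", n_male + n_female)),
    stringsAsFactors = FALSE
  ))
}

# One full-size simulated dataset shared across test files.
.fixture_env <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_dataset(simulation_config(seed = 20231L))
  }
  .fixture_env$sim
}

small_sim <- function(seed = 42L, total = 3000, ...) {
  simulate_dataset(simulation_config(
    seed = seed, probes_per_chromosome = default_probe_counts(total), ...))
}

# Map generator ground truth to the expected classification category.
truth_category <- function(truth) {
  ifelse(truth$normal_state == "normal_methylated",
         "methylated_in_normal", "unmethylated_in_normal")
}
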