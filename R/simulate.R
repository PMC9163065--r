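# Synthetic EPIC-like methylome generator.
#
# The simulator emulates the statistical structure the downstream analysis
# assumes: bimodal parental beta distributions; global demethylation in
# DNMT1-compromised lines with chromosome-specific retention probabilities
# (chrX strongly retained, chr16/17/19/22 depleted); X-inactivation
# methylation in normal tissues (females monoallelic near 0.5, males
# unmethylated); and tumor-cohort de novo hypermethylation at selected
# probes. All randomness flows through one RNG stream seeded once, with
# draws consumed in a fixed documented order (manifest, latent probe states,
# beta values sample by sample in sample-sheet order, detection p-values),
# so identical configs give bit-identical output.

#' Default per-chromosome probe counts
#'
#' Probe counts proportional to approximate EPIC array per-chromosome probe
#' densities (chr1..chr22 and chrX; chrY probes are so few on the real array
#' that they are omitted by default), scaled to `total` probes for
#' desk-scale simulation.
#'
#' @param total total number of probes to distribute (default 20000).
#' @return Named integer vector, chromosome -> probe count.
#' @export
default_probe_counts <- function(total = 20000) {
  # rough EPIC probe shares (thousands of probes on the real array)
  weights <- c(chr1 = 82, chr2 = 71, chr3 = 53, chr4 = 42, chr5 = 50,
               chr6 = 59, chr7 = 49, chr8 = 41, chr9 = 25, chr10 = 43,
               chr11 = 49, chr12 = 45, chr13 = 21, chr14 = 27, chr15 = 26,
               chr16 = 37, chr17 = 47, chr18 = 17, chr19 = 43, chr20 = 19,
               chr21 = 11, chr22 = 18, chrX = 17)
  counts <- round(weights / sum(weights) * total)
  counts[1] <- counts[1] + (total - sum(counts))   # absorb rounding residue
  storage.mode(counts) <- "integer"
  counts
}

#' Default per-chromosome retention probabilities
#'
#' Probability that a parental-high probe stays highly methylated after
#' DNMT1 compromise: strongly elevated on chrX, depressed on the
#' retention-poor chromosomes 16, 17, 19 and 22, baseline elsewhere.
#'
#' @param base baseline autosomal retention probability.
#' @param depleted retention probability on chr16/17/19/22.
#' @param chrX retention probability on the X chromosome.
#' @return Named numeric vector over chr1..chr22, chrX.
#' @export
default_retention_prob <- function(base = 0.05, depleted = 0.02, chrX = 0.25) {
  chroms <- paste0("chr", c(1:22, "X"))
  p <- stats::setNames(rep(base, length(chroms)), chroms)
  p[c("chr16", "chr17", "chr19", "chr22")] <- depleted
  p["chrX"] <- chrX
  p
}

#' Build a validated simulation configuration
#'
#' Shape-parameter pairs define the three beta-generating mixture
#' components: `beta_shape_low` (2,18), mean 0.1, the unmethylated peak;
#' `beta_shape_high` (18,2), mean 0.9, the methylated peak;
#' `beta_shape_mono` (12,12), mean 0.5, the female X-inactivation
#' monoallelic component. Resistant lines additionally draw a fraction
#' `intermediate_shoulder_prob` of their demethylated probes from an
#' intermediate component `beta_shape_intermediate` (6,6), reproducing the
#' intermediate-methylation shoulder seen after drug (but not genetic)
#' DNMT1 compromise.
#'
#' @param seed integer RNG seed.
#' @param probes_per_chromosome named integer vector, chromosome -> count.
#' @param promoter_fraction fraction of probes annotated to promoter
#'   contexts.
#' @param parental_methylated_fraction per-chromosome fraction of probes
#'   highly methylated in the parental line; scalar recycled over
#'   chromosomes (about 0.6 on every chromosome in real parental lines).
#' @param normal_methylated_fraction fraction of probes constitutively
#'   methylated in non-cancer tissue (both sexes); must not exceed
#'   `parental_methylated_fraction`.
#' @param x_inactivation_fraction among chrX probes not constitutively
#'   methylated, the fraction subject to X inactivation (female monoallelic
#'   methylation); the remainder escape and look autosomal-unmethylated.
#' @param retention_prob named numeric vector, chromosome -> probability a
#'   parental-high probe stays high after DNMT1 compromise.
#' @param beta_shape_low,beta_shape_high,beta_shape_mono,beta_shape_intermediate
#'   length-2 positive shape pairs for the mixture components.
#' @param intermediate_shoulder_prob probability a demethylated probe in the
#'   resistant (drug) line lands in the intermediate component; the dko
#'   (genetic) line always uses 0.
#' @param detection_fail_prob per-probe probability of failing detection in
#'   one random sample.
#' @param n_normal_male,n_normal_female non-cancer tissue panel sizes.
#' @param n_tumor,n_adjacent tumor-cohort sample counts used by
#'   [simulate_cohort()].
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              probes_per_chromosome = default_probe_counts(),
                              promoter_fraction = 0.35,
                              parental_methylated_fraction = 0.6,
                              normal_methylated_fraction = 0.45,
                              x_inactivation_fraction = 0.8,
                              retention_prob = default_retention_prob(),
                              beta_shape_low = c(2, 18),
                              beta_shape_high = c(18, 2),
                              beta_shape_mono = c(12, 12),
                              beta_shape_intermediate = c(6, 6),
                              intermediate_shoulder_prob = 0.15,
                              detection_fail_prob = 0.005,
                              n_normal_male = 5L,
                              n_normal_female = 5L,
                              n_tumor = 20L,
                              n_adjacent = 10L) {
  if (length(probes_per_chromosome) == 0) {
    stop("probes_per_chromosome must name at least one chromosome",
         call. = FALSE)
  }
  chroms <- names(probes_per_chromosome)
  if (is.null(chroms) || !all(chroms %in% methret_chromosomes())) {
    stop("probes_per_chromosome must be named with valid chromosome labels",
         call. = FALSE)
  }
  if (any(probes_per_chromosome < 0)) {
    stop("probe counts must be >= 0", call. = FALSE)
  }
  pm <- parental_methylated_fraction
  if (length(pm) == 1) pm <- stats::setNames(rep(pm, length(chroms)), chroms)
  if (!all(chroms %in% names(pm))) {
    stop("parental_methylated_fraction must cover every simulated chromosome",
         call. = FALSE)
  }
  if (!all(chroms %in% names(retention_prob))) {
    stop("retention_prob must cover every simulated chromosome", call. = FALSE)
  }
  probs <- c(pm, retention_prob[chroms], promoter_fraction,
             normal_methylated_fraction, x_inactivation_fraction,
             intermediate_shoulder_prob, detection_fail_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities and fractions must lie in [0,1]", call. = FALSE)
  }
  if (any(normal_methylated_fraction > pm)) {
    stop("normal_methylated_fraction cannot exceed parental_methylated_fraction",
         call. = FALSE)
  }
  shapes <- list(low = beta_shape_low, high = beta_shape_high,
                 mono = beta_shape_mono, intermediate = beta_shape_intermediate)
  for (nm in names(shapes)) {
    s <- shapes[[nm]]
    if (length(s) != 2 || any(s <= 0)) {
      stop("beta_shape_", nm, " must be two positive shape parameters",
           call. = FALSE)
    }
  }
  counts <- c(n_normal_male, n_normal_female, n_tumor, n_adjacent)
  if (any(counts < 0)) stop("sample counts must be >= 0", call. = FALSE)
  structure(list(
    seed = as.integer(seed),
    probes_per_chromosome = probes_per_chromosome,
    promoter_fraction = promoter_fraction,
    parental_methylated_fraction = pm,
    normal_methylated_fraction = normal_methylated_fraction,
    x_inactivation_fraction = x_inactivation_fraction,
    retention_prob = retention_prob[chroms],
    beta_shape_low = beta_shape_low,
    beta_shape_high = beta_shape_high,
    beta_shape_mono = beta_shape_mono,
    beta_shape_intermediate = beta_shape_intermediate,
    intermediate_shoulder_prob = intermediate_shoulder_prob,
    detection_fail_prob = detection_fail_prob,
    n_normal_male = as.integer(n_normal_male),
    n_normal_female = as.integer(n_normal_female),
    n_tumor = as.integer(n_tumor),
    n_adjacent = as.integer(n_adjacent)
  ), class = "simulation_config")
}

draw_component <- function(n, shape) {
  if (n == 0) return(numeric(0))
  stats::rbeta(n, shape[1], shape[2])
}

# Draw one sample's beta vector from per-probe component labels
# ("low", "high", "mono", "intermediate"). Draws happen probe-major in
# manifest order for reproducibility.
draw_betas <- function(component, config) {
  out <- numeric(length(component))
  shapes <- list(low = config$beta_shape_low, high = config$beta_shape_high,
                 mono = config$beta_shape_mono,
                 intermediate = config$beta_shape_intermediate)
  for (nm in names(shapes)) {
    idx <- which(component == nm)
    out[idx] <- draw_component(length(idx), shapes[[nm]])
  }
  out
}

# Per-sample component assignment given the latent probe states.
normal_component <- function(truth, sex) {
  comp <- rep("low", nrow(truth))
  comp[truth$normal_state == "normal_methylated"] <- "high"
  if (sex == "female") {
    comp[truth$normal_state == "x_inactivation_pattern"] <- "mono"
  }
  comp
}

#' Simulate a full EPIC-like dataset
#'
#' Generates a probe manifest, a beta matrix covering a parental line, a
#' drug-resistant line, a genetic double-compromised (dko) line and panels
#' of non-cancer male and female tissues, a matching detection p-value
#' matrix, a sample sheet, and the latent ground truth used to generate each
#' probe.
#'
#' Latent states per probe: `normal_state` is one of `normal_methylated`
#' (constitutively methylated in tissue, both sexes), `x_inactivation_pattern`
#' (chrX only: female monoallelic ~0.5, male unmethylated) or
#' `normal_unmethylated`. `cancer_state` is `stays_methylated`
#' (normal-methylated probes, which are also methylated in the parental
#' line), `de_novo_methylated` (unmethylated in tissue, methylated in the
#' parental cancer line) or `stays_unmethylated`; de novo draws are
#' calibrated per chromosome so the parental-high fraction hits
#' `parental_methylated_fraction`. `retained` (parental-high probes only)
#' says whether the probe keeps high methylation after DNMT1 compromise.
#'
#' @param config a [simulation_config()] object.
#' @return List of class `meth_simulation` with elements `manifest`,
#'   `betas`, `detection_p`, `samples`, `truth`, `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  counts <- config$probes_per_chromosome
  chroms <- names(counts)
  n <- sum(counts)
  if (n == 0) stop("configuration yields zero probes", call. = FALSE)

  ## 1. manifest
  chromosome <- rep(chroms, counts)
  position <- unlist(lapply(counts, function(k) {
    sort(sample.int(200000000L, k))
  }), use.names = FALSE)
  pf <- config$promoter_fraction
  ctx <- sample(methret_contexts(), n, replace = TRUE,
                prob = c(pf * c(0.4, 0.4, 0.2),
                         (1 - pf) * c(0.6, 0.15, 0.25)))
  manifest <- validate_manifest(data.frame(
    probe_id = sprintf("cg%07d", seq_len(n)),
    chromosome = chromosome,
    position = position,
    genomic_context = ctx,
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE
  ))

  ## 2. latent states
  p_nm <- config$normal_methylated_fraction
  normal_state <- ifelse(stats::runif(n) < p_nm, "normal_methylated",
                         "normal_unmethylated")
  on_x <- chromosome == "chrX"
  xi <- on_x & normal_state == "normal_unmethylated" &
    stats::runif(n) < config$x_inactivation_fraction
  normal_state[xi] <- "x_inactivation_pattern"

  # calibrate de novo rate per chromosome so P(parental high) hits target
  p_high <- config$parental_methylated_fraction[chromosome]
  p_denovo <- pmin(1, pmax(0, (p_high - p_nm) / (1 - p_nm)))
  cancer_state <- rep("stays_unmethylated", n)
  cancer_state[normal_state == "normal_methylated"] <- "stays_methylated"
  unmeth <- normal_state != "normal_methylated"
  de_novo <- unmeth & stats::runif(n) < p_denovo
  cancer_state[de_novo] <- "de_novo_methylated"

  parental_high <- cancer_state %in% c("stays_methylated", "de_novo_methylated")
  retained <- rep(NA, n)
  retained[parental_high] <-
    stats::runif(sum(parental_high)) < config$retention_prob[chromosome[parental_high]]

  truth <- data.frame(probe_id = manifest$probe_id,
                      chromosome = chromosome,
                      normal_state = normal_state,
                      cancer_state = cancer_state,
                      retained = retained,
                      stringsAsFactors = FALSE)

  ## 3. sample sheet (cell lines derived from a male donor)
  samples <- data.frame(
    sample_id = c("parental", "resistant", "dko",
                  sprintf("normal_male_%02d", seq_len(config$n_normal_male)),
                  sprintf("normal_female_%02d", seq_len(config$n_normal_female))),
    group = c("parental", "resistant", "dko",
              rep("normal_tissue", config$n_normal_male + config$n_normal_female)),
    sex = c("male", "male", "male",
            rep("male", config$n_normal_male),
            rep("female", config$n_normal_female)),
    tissue = c(rep("cell_line", 3),
               rep("colon", config$n_normal_male + config$n_normal_female)),
    stringsAsFactors = FALSE
  )
  samples <- validate_sample_sheet(samples)

  ## 4. beta values, sample by sample in sheet order
  betas <- matrix(NA_real_, n, nrow(samples),
                  dimnames = list(manifest$probe_id, samples$sample_id))
  comp_parental <- ifelse(parental_high, "high", "low")

  compromised_component <- function(shoulder_prob) {
    comp <- rep("low", n)
    kept <- parental_high & retained %in% TRUE
    comp[kept] <- "high"
    lost <- parental_high & retained %in% FALSE
    if (shoulder_prob > 0) {
      sh <- lost & stats::runif(n) < shoulder_prob
      comp[sh] <- "intermediate"
    }
    comp
  }

  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    comp <- switch(samples$group[i],
      parental = comp_parental,
      resistant = compromised_component(config$intermediate_shoulder_prob),
      dko = compromised_component(0),
      normal_tissue = normal_component(truth, samples$sex[i]),
      stop("unhandled group in simulation: ", samples$group[i])
    )
    betas[, sid] <- draw_betas(comp, config)
  }

  ## 5. detection p-values: passing draws uniform on (0, 0.04]; failing
  ##    probes get one random sample pushed above 0.05
  detection_p <- matrix(stats::runif(n * nrow(samples), 0, 0.04), n,
                        dimnames = dimnames(betas))
  failing <- which(stats::runif(n) < config$detection_fail_prob)
  if (length(failing) > 0) {
    cols <- sample.int(nrow(samples), length(failing), replace = TRUE)
    detection_p[cbind(failing, cols)] <- stats::runif(length(failing), 0.051, 0.5)
  }

  structure(list(manifest = manifest, betas = validate_beta_matrix(betas),
                 detection_p = detection_p, samples = samples, truth = truth,
                 config = config),
            class = "meth_simulation")
}

#' Simulate a tumor / adjacent-normal cohort
#'
#' Given a simulated dataset and a probe set of interest, draws a cohort of
#' tumor and adjacent-normal samples. Each tumor methylates each selected
#' probe independently with a per-probe penetrance; at unselected probes and
#' in adjacent normals, values follow the sex-specific non-cancer pattern
#' (chrX X-inactivation probes monoallelic in females, unmethylated in
#' males). Sexes alternate across samples so both strata are populated.
#'
#' @param sim a `meth_simulation` from [simulate_dataset()].
#' @param probe_set character vector of probes to receive tumor de novo
#'   methylation; must be drawn from the simulated manifest and nonempty.
#' @param penetrance per-probe probability a tumor sample is methylated at a
#'   selected probe; scalar or vector along `probe_set`. Default draws each
#'   probe's penetrance uniformly on (0.3, 0.95), mimicking the gradient
#'   from near-universal to sporadic tumor methylation.
#' @param seed RNG seed for the cohort draw (default derives from the
#'   dataset config so dataset and cohort remain jointly reproducible).
#' @return List with `betas` (probes x cohort samples), `samples` (sample
#'   sheet rows for the cohort) and `penetrance` (named per-probe vector).
#' @export
simulate_cohort <- function(sim, probe_set, penetrance = NULL,
                            seed = sim$config$seed + 1L) {
  stopifnot(inherits(sim, "meth_simulation"))
  if (length(probe_set) == 0) {
    stop("probe_set must contain at least one probe", call. = FALSE)
  }
  if (!all(probe_set %in% sim$manifest$probe_id)) {
    stop("probe_set contains probes absent from the manifest", call. = FALSE)
  }
  config <- sim$config
  set.seed(seed)
  if (is.null(penetrance)) {
    penetrance <- stats::runif(length(probe_set), 0.3, 0.95)
  } else if (length(penetrance) == 1) {
    penetrance <- rep(penetrance, length(probe_set))
  }
  if (length(penetrance) != length(probe_set) ||
      any(penetrance < 0 | penetrance > 1)) {
    stop("penetrance must be a probability (scalar or one per probe)",
         call. = FALSE)
  }
  names(penetrance) <- probe_set

  n_tumor <- config$n_tumor
  n_adjacent <- config$n_adjacent
  mk_samples <- function(prefix, k, group) {
    if (k == 0) return(NULL)
    data.frame(sample_id = sprintf("%s_%03d", prefix, seq_len(k)),
               group = group,
               sex = rep(c("female", "male"), length.out = k),
               tissue = "colon", stringsAsFactors = FALSE)
  }
  samples <- rbind(mk_samples("tumor", n_tumor, "tumor"),
                   mk_samples("adjnorm", n_adjacent, "adjacent_normal"))
  if (is.null(samples)) {
    stop("cohort needs at least one tumor or adjacent-normal sample",
         call. = FALSE)
  }
  samples <- validate_sample_sheet(samples)

  n <- nrow(sim$manifest)
  sel_idx <- match(probe_set, sim$manifest$probe_id)
  betas <- matrix(NA_real_, n, nrow(samples),
                  dimnames = list(sim$manifest$probe_id, samples$sample_id))
  for (i in seq_len(nrow(samples))) {
    comp <- normal_component(sim$truth, samples$sex[i])
    if (samples$group[i] == "tumor") {
      hit <- stats::runif(length(sel_idx)) < penetrance
      comp[sel_idx[hit]] <- "high"
    }
    betas[, samples$sample_id[i]] <- draw_betas(comp, config)
  }
  list(betas = validate_beta_matrix(betas), samples = samples,
       penetrance = penetrance)
}

#' Write a simulated dataset to disk in the pipeline's file dialects
#'
#' Emits `manifest.csv`, `betas.tsv`, `detection_p.tsv`, `samples.csv` and
#' `truth.tsv` under `dir`.
#'
#' @param sim a `meth_simulation`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "meth_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_manifest(sim$manifest, file.path(dir, "manifest.csv"))
  write_beta_matrix(sim$betas, file.path(dir, "betas.tsv"))
  write_beta_matrix(sim$detection_p, file.path(dir, "detection_p.tsv"))
  write_sample_sheet(sim$samples, file.path(dir, "samples.csv"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
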