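# Classification of retained promoter probes against non-cancer tissues.

# A tiny hand-built dataset: 6 probes across chr1/chrX with controlled
# normal-tissue means.
toy_classification <- function() {
  manifest <- validate_manifest(data.frame(
    probe_id = paste0("cg", 1:6),
    chromosome = c("chr1", "chr1", "chrX", "chrX", "chrX", "chr1"),
    position = c(100, 200, 100, 200, 300, 300),
    genomic_context = c("TSS200", "body", "TSS1500", "TSS200", "5UTR",
                        "TSS200"),
    strand = "+", stringsAsFactors = FALSE))
  betas <- make_betas(rbind(
    cg1 = c(0.90, 0.85, 0.05, 0.06, 0.04, 0.05),   # autosomal de novo
    cg2 = c(0.90, 0.90, 0.05, 0.05, 0.05, 0.05),   # body probe (not promoter)
    cg3 = c(0.90, 0.85, 0.05, 0.05, 0.50, 0.50),   # chrX XI signature
    cg4 = c(0.92, 0.88, 0.92, 0.92, 0.88, 0.88),   # methylated in normal
    cg5 = c(0.90, 0.85, 0.40, 0.40, 0.40, 0.40),   # fits neither rule
    cg6 = c(0.90, 0.30, 0.05, 0.05, 0.05, 0.05)    # lost methylation
  ), sample_ids = c("parental", "resistant", "nm1", "nm2", "nf1", "nf2"))
  list(manifest = manifest, betas = betas, sheet = normal_sheet())
}

test_that("selection requires promoter context and high beta in both lines", {
  toy <- toy_classification()
  sel <- select_retained_promoter_probes(toy$betas, toy$manifest,
                                         "parental", "resistant")
  expect_setequal(sel, c("cg1", "cg3", "cg4", "cg5"))
  # cg2 fails the promoter filter, cg6 lost methylation in the resistant line
  expect_false("cg2" %in% sel)
  expect_false("cg6" %in% sel)
  # nothing qualifies at an extreme cutoff
  expect_warning(
    none <- select_retained_promoter_probes(toy$betas, toy$manifest,
                                            "parental", "resistant",
                                            cutoff = 0.95),
    "no promoter probe")
  expect_length(none, 0)
})

test_that("classification applies the sex- and chromosome-aware rules", {
  toy <- toy_classification()
  calls <- classify_probes(toy$betas, toy$manifest, toy$sheet,
                           c("cg1", "cg3", "cg4", "cg5"),
                           "parental", "resistant")
  expect_equal(calls$category[calls$probe_id == "cg1"],
               "unmethylated_in_normal")   # autosomal: low in both sexes
  expect_equal(calls$category[calls$probe_id == "cg3"],
               "unmethylated_in_normal")   # chrX: male low, female monoallelic
  expect_equal(calls$category[calls$probe_id == "cg4"],
               "methylated_in_normal")     # high in both sexes
  expect_equal(calls$category[calls$probe_id == "cg5"],
               "unclassified")             # chrX male 0.4: fits neither rule
  expect_equal(calls$male_mean[calls$probe_id == "cg3"], 0.05)
  expect_equal(calls$female_mean[calls$probe_id == "cg3"], 0.5)
})

test_that("classification demands normal tissue evidence from both sexes", {
  toy <- toy_classification()
  males_only <- toy$sheet[toy$sheet$sex == "male" |
                            toy$sheet$group != "normal_tissue", ]
  expect_error(classify_probes(toy$betas, toy$manifest, males_only,
                               "cg1", "parental", "resistant"),
               "each sex")
})

test_that("summary percentages reproduce count-level arithmetic", {
  # genome-wide: 112 de novo (31 of them on chrX) vs 1145 methylated;
  # chrX alone: 31 de novo vs 88 methylated
  calls <- data.frame(
    probe_id = sprintf("cg%04d", 1:1257),
    chromosome = c(rep("chrX", 31), rep("chr1", 81),
                   rep("chrX", 88), rep("chr2", 1057)),
    category = c(rep("unmethylated_in_normal", 112),
                 rep("methylated_in_normal", 1145)),
    stringsAsFactors = FALSE)
  gw <- classification_summary(calls, "genome_wide")
  expect_equal(gw$n_total, 1257)
  expect_equal(round(gw$pct_de_novo), 9)
  expect_equal(round(gw$pct_de_novo_on_chrX), 28)
  cx <- classification_summary(calls, "chrX_only")
  expect_equal(cx$n_total, 119)
  expect_equal(round(cx$pct_de_novo), 26)
  # counts always partition the input
  expect_equal(gw$n_de_novo + gw$n_methylated_normal + gw$n_unclassified,
               gw$n_total)
})

test_that("single-category inputs give boundary percentages", {
  calls <- data.frame(probe_id = paste0("cg", 1:5), chromosome = "chr1",
                      category = "unmethylated_in_normal",
                      stringsAsFactors = FALSE)
  expect_equal(classification_summary(calls)$pct_de_novo, 100)
  calls$category <- "methylated_in_normal"
  expect_equal(classification_summary(calls)$pct_de_novo, 0)
  calls$category <- "unclassified"
  expect_true(is.na(classification_summary(calls)$pct_de_novo))
})

test_that("classification recovers simulated ground truth with default components", {
  sim <- default_sim()
  sel <- select_retained_promoter_probes(sim$betas, sim$manifest,
                                         "parental", "resistant")
  calls <- classify_probes(sim$betas, sim$manifest, sim$samples, sel,
                           "parental", "resistant")
  expected <- truth_category(sim$truth)
  names(expected) <- sim$truth$probe_id
  accuracy <- mean(calls$category == expected[calls$probe_id])
  expect_gte(accuracy, 0.99)
  # every selected probe gets exactly one category
  expect_true(all(calls$category %in% c("unmethylated_in_normal",
                                        "methylated_in_normal",
                                        "unclassified")))
  expect_equal(nrow(calls), length(sel))
})

test_that("accuracy degrades monotonically as mixture components merge", {
  run_at <- function(low, high, mono) {
    sim <- simulate_dataset(simulation_config(
      seed = 71L, probes_per_chromosome = default_probe_counts(6000),
      beta_shape_low = low, beta_shape_high = high, beta_shape_mono = mono))
    sel <- select_retained_promoter_probes(sim$betas, sim$manifest,
                                           "parental", "resistant")
    calls <- classify_probes(sim$betas, sim$manifest, sim$samples, sel,
                             "parental", "resistant")
    expected <- truth_category(sim$truth)
    names(expected) <- sim$truth$probe_id
    mean(calls$category == expected[calls$probe_id])
  }
  acc_separated <- run_at(c(2, 18), c(18, 2), c(12, 12))
  acc_medium <- run_at(c(2, 6), c(6, 2), c(5, 5))
  acc_overlapping <- run_at(c(1.5, 3), c(3, 1.5), c(2, 2))
  expect_gte(acc_separated, acc_medium)
  expect_gte(acc_medium, acc_overlapping)
  expect_lt(acc_overlapping, 0.99)
})

test_that("calls are invariant to sample order within a sex", {
  sim <- small_sim(seed = 72L, total = 2000)
  sel <- select_retained_promoter_probes(sim$betas, sim$manifest,
                                         "parental", "resistant")
  calls <- classify_probes(sim$betas, sim$manifest, sim$samples, sel,
                           "parental", "resistant")
  # permute the female (and male) normal columns in both sheet and matrix
  sheet <- sim$samples[rev(seq_len(nrow(sim$samples))), ]
  calls_perm <- classify_probes(sim$betas, sim$manifest, sheet, sel,
                                "parental", "resistant")
  expect_equal(calls_perm, calls)
})

test_that("locus profiles extract position-ordered probes within a region", {
  sim <- small_sim(seed = 73L, total = 1000)
  chr1 <- sim$manifest[sim$manifest$chromosome == "chr1", ]
  chr1 <- chr1[order(chr1$position), ]
  window <- c(chr1$position[3], chr1$position[6])
  prof <- locus_profile(sim$betas, sim$manifest, "chr1",
                        window[1], window[2], sim$samples)
  expect_equal(prof$probes$probe_id, chr1$probe_id[3:6])
  expect_true(all(diff(prof$probes$position) >= 0))
  expect_equal(rownames(prof$beta), chr1$probe_id[3:6])
  # reversed coordinates are normalized
  prof_rev <- locus_profile(sim$betas, sim$manifest, "chr1",
                            window[2], window[1], sim$samples)
  expect_equal(prof_rev$probes, prof$probes)
  # group means agree with a direct per-group computation
  for (g in colnames(prof$group_means)) {
    ids <- sim$samples$sample_id[sim$samples$group == g]
    expect_equal(prof$group_means[, g],
                 rowMeans(prof$beta[, ids, drop = FALSE]))
  }
  expect_warning(empty <- locus_profile(sim$betas, sim$manifest, "chr2",
                                        1, 2), "no probes")
  expect_equal(nrow(empty$probes), 0)
})

test_that("random-region extraction matches a linear scan oracle", {
  sim <- small_sim(seed = 74L, total = 1500)
  set.seed(99)
  for (i in 1:10) {
    ch <- sample(unique(sim$manifest$chromosome), 1)
    bounds <- sort(sample.int(200000000L, 2))
    suppressWarnings(
      prof <- locus_profile(sim$betas, sim$manifest, ch, bounds[1], bounds[2]))
    oracle <- character(0)
    for (j in seq_len(nrow(sim$manifest))) {
      if (sim$manifest$chromosome[j] == ch &&
          sim$manifest$position[j] >= bounds[1] &&
          sim$manifest$position[j] <= bounds[2]) {
        oracle <- c(oracle, sim$manifest$probe_id[j])
      }
    }
    oracle <- oracle[order(sim$manifest$position[match(oracle,
                                                       sim$manifest$probe_id)])]
    expect_equal(prof$probes$probe_id, oracle)
  }
})
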