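# Readers, validators, QC filtering and per-sample summaries.

write_csv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("manifest reading maps fields and derives the promoter flag", {
  path <- write_csv_fixture(c(
    "probe_id,chromosome,position,genomic_context,strand",
    "cg0001,chrX,1000,TSS200,+",
    "cg0002,chr1,500,body,-",
    "cg0003,chr2,77,5UTR,+"
  ))
  m <- read_manifest(path)
  expect_equal(m$chromosome, c("chrX", "chr1", "chr2"))
  expect_equal(m$is_promoter, c(TRUE, FALSE, TRUE))
  expect_equal(m$position, c(1000L, 500L, 77L))
  expect_true(is.integer(m$position))
})

test_that("manifest validation rejects bad chromosomes, duplicates and missing columns", {
  bad_chrom <- write_csv_fixture(c(
    "probe_id,chromosome,position,genomic_context,strand",
    "cg0001,chr23,1000,TSS200,+"
  ))
  expect_error(read_manifest(bad_chrom), "chr23")

  dup <- write_csv_fixture(c(
    "probe_id,chromosome,position,genomic_context,strand",
    "cg0001,chr1,1000,TSS200,+",
    "cg0001,chr2,2000,body,-"
  ))
  expect_error(read_manifest(dup), "duplicate probe_id")

  missing_col <- write_csv_fixture(c(
    "probe_id,chromosome,genomic_context",
    "cg0001,chr1,TSS200"
  ))
  expect_error(read_manifest(missing_col), "position")
})

test_that("beta matrix TSV round trip preserves values, ids and missingness", {
  set.seed(11)
  betas <- make_betas(matrix(round(runif(12), 6), 4, 3))
  betas[2, 3] <- NA
  path <- withr::local_tempfile(fileext = ".tsv")
  write_beta_matrix(betas, path)
  back <- read_beta_matrix(path)
  expect_identical(dimnames(back), dimnames(betas))
  expect_equal(back, betas, tolerance = 1e-12)
  expect_true(is.na(back[2, 3]))
})

test_that("beta matrix validation pinpoints out-of-range values", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\ts1\ts2", "cg01\t0.1\t0.9", "cg02\t1.2\t0.5"), path)
  expect_error(read_beta_matrix(path), "cg02.*s1")
  expect_error(make_betas(matrix(c(0.5, -0.1), 1, 2)), "out of \\[0,1\\]")
})

test_that("detection filter drops exactly the probes failing anywhere, in order", {
  betas <- make_betas(matrix(0.5, 3, 2))
  p <- matrix(0.01, 3, 2, dimnames = dimnames(betas))
  p[2, 2] <- 0.06
  out <- apply_detection_filter(betas, p, 0.05)
  expect_equal(rownames(out), rownames(betas)[c(1, 3)])
  expect_equal(attr(out, "n_removed"), 1L)

  # all-pass is the identity
  p_ok <- matrix(0.01, 3, 2, dimnames = dimnames(betas))
  out_ok <- apply_detection_filter(betas, p_ok, 0.05)
  expect_equal(rownames(out_ok), rownames(betas))
  expect_equal(attr(out_ok, "n_removed"), 0L)
})

test_that("detection filter agrees with a per-probe scan oracle and is idempotent", {
  set.seed(101)
  betas <- make_betas(matrix(runif(50), 10, 5))
  p <- matrix(runif(50, 0, 0.04), 10, 5, dimnames = dimnames(betas))
  # push exactly 4 probes over the threshold somewhere
  fail_rows <- sample(10, 4)
  p[cbind(fail_rows, sample(5, 4, replace = TRUE))] <- runif(4, 0.06, 0.5)

  keep_oracle <- logical(10)
  for (i in 1:10) {
    keep_oracle[i] <- TRUE
    for (j in 1:5) if (p[i, j] > 0.05) keep_oracle[i] <- FALSE
  }
  out <- apply_detection_filter(betas, p, 0.05)
  expect_equal(nrow(out), 6)
  expect_equal(rownames(out), rownames(betas)[keep_oracle])

  twice <- apply_detection_filter(out, p[rownames(out), , drop = FALSE], 0.05)
  expect_identical(dimnames(twice), dimnames(out))
  expect_equal(as.vector(twice), as.vector(out))
  expect_equal(attr(twice, "n_removed"), 0L)
  expect_lte(nrow(out), nrow(betas))
})

test_that("detection filter validates shapes, thresholds and missing p-values", {
  betas <- make_betas(matrix(0.5, 3, 2))
  expect_error(apply_detection_filter(betas, matrix(0.01, 2, 2)), "shape")
  expect_error(apply_detection_filter(betas,
                                      matrix(0.01, 3, 2,
                                             dimnames = dimnames(betas)),
                                      threshold = 0), "threshold")
  p <- matrix(0.01, 3, 2, dimnames = dimnames(betas))
  p[1, 1] <- NA
  expect_equal(nrow(apply_detection_filter(betas, p)), 2)
})

test_that("summarize_beta reproduces hand-computable and degenerate cases", {
  betas <- make_betas(cbind(a = c(0, 0.5, 1), b = rep(0.7, 3)))
  s <- summarize_beta(betas, "a")
  expect_equal(s$mean, 0.5)
  expect_equal(s$median, 0.5)
  s2 <- summarize_beta(betas, "b")
  expect_equal(unlist(s2[c("p5", "q25", "median", "q75", "p95")],
                      use.names = FALSE), rep(0.7, 5))
  expect_error(summarize_beta(betas, "nope"), "unknown sample")
  all_na <- make_betas(cbind(a = c(0.1, 0.2), b = c(NA_real_, NA_real_)))
  expect_error(summarize_beta(all_na, "b"), "no non-missing")
})

test_that("summary quantiles equal an independent sort-based computation", {
  # oracle: linear interpolation between order statistics, h = (n-1)p + 1
  sort_quantile <- function(x, p) {
    x <- sort(x)
    n <- length(x)
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  set.seed(303)
  v <- c(rbeta(500, 2, 18), rbeta(500, 18, 2))  # bimodal mixture
  betas <- make_betas(cbind(mix = v))
  s <- summarize_beta(betas, "mix")
  for (stat in list(c("p5", 0.05), c("q25", 0.25), c("median", 0.5),
                    c("q75", 0.75), c("p95", 0.95))) {
    expect_equal(s[[stat[1]]], sort_quantile(v, as.numeric(stat[2])),
                 tolerance = 1e-12)
  }
})

test_that("summary order statistics form a monotone chain on arbitrary inputs", {
  set.seed(404)
  for (rep in 1:20) {
    n <- sample(2:200, 1)
    v <- switch(1 + rep %% 3,
                runif(n),
                rbeta(n, 0.3, 0.3),
                rep(runif(1), n))
    s <- summarize_beta(make_betas(cbind(x = v)), "x")
    chain <- unlist(s[c("p5", "q25", "median", "q75", "p95")],
                    use.names = FALSE)
    expect_true(all(diff(chain) >= -1e-12))
    expect_true(all(chain >= 0 & chain <= 1))
  }
})

test_that("sample sheets validate group and sex vocabularies", {
  sheet <- normal_sheet()
  expect_silent(validate_sample_sheet(sheet))
  bad <- sheet
  bad$group[1] <- "mystery"
  expect_error(validate_sample_sheet(bad), "mystery")
  bad2 <- sheet
  bad2$sample_id[2] <- bad2$sample_id[1]
  expect_error(validate_sample_sheet(bad2), "duplicate")
})

test_that("BED export converts 1-based points to 0-based half-open intervals", {
  m <- make_manifest(c(chr1 = 2))
  path <- withr::local_tempfile(fileext = ".bed")
  probes_to_bed(m, path)
  bed <- read.table(path, sep = "\t")
  expect_equal(bed$V2, m$position - 1L)
  expect_equal(bed$V3, m$position)
})
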