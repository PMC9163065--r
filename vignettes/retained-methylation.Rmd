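---
title: "Quantifying chromosome-level retention of DNA methylation after DNMT1 inhibition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chromosome-level retention of DNA methylation after DNMT1 inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methretain)
```

## The analysis in one paragraph

A cancer cell line whose maintenance methyltransferase DNMT1 has been
disabled — by long-term exposure to a DNMT1-selective inhibitor, or by a
hypomorphic *DNMT1* allele combined with *DNMT3B* knockout — loses most of
its CpG methylation, but not uniformly: a minority of probes stay highly
methylated, and their chromosomal distribution is biased. `methretain`
quantifies that bias from Infinium array beta values in three steps:
per-chromosome retention percentages at several beta cutoffs, a
hypergeometric enrichment-bias statistic per chromosome, and a sex-aware
classification of the retained promoter probes against non-cancer tissue
methylation that separates cancer-acquired (de novo) hypermethylation
from constitutive methylation.

## Data model and quality control

Beta values (methylated signal fraction, in [0,1]) arrive as a probes ×
samples matrix; a probe manifest supplies chromosome, 1-based position,
genomic context and a derived promoter flag; a sample sheet labels each
sample's group (parental, resistant, dko, normal_tissue, tumor,
adjacent_normal) and biological sex. Missing values are carried as `NA`
and excluded pairwise from every summary and call: a masked probe carries
no evidence, so it is never counted as highly methylated.

QC follows the standard detection-p rule for these arrays: a probe whose
detection p-value exceeds 0.05 in *any* sample is removed, because a
single failing sample makes the probe's cross-sample comparison
unreliable. The filter is applied per analysis set (the matrix handed to
it), not jointly across independently processed panels; the count removed
is reported alongside the result. The filter is idempotent and
order-preserving, properties the test suite asserts directly.

Promoter status: contexts `TSS200`, `TSS1500` and `5UTR` count as
promoter-proximal, the usual reading of Infinium annotation; the set is an
argument of `read_manifest()` for users who prefer a stricter TSS-only
definition.

## Retention and enrichment bias

A probe *retains* methylation when its beta is at or above the cutoff
(inclusive, matching the conventional "β ≥ 0.7" phrasing) in **both** the
parental and the compromised sample. The denominator of the per-chromosome
retention percentage is the parental-high count on that chromosome; a
chromosome with no parental-high probe gets an undefined (`NA`)
percentage, never a zero, and ranks last with a warning. Chromosomes are
ranked least- to most-retained at the 0.7 reference cutoff, ties broken by
label so the order is reproducible. The companion
`parental_high_fraction()` profiles the baseline: in parental lines the
fraction of probes at β ≥ 0.7 is roughly uniform (~0.6) across
chromosomes, which rules out baseline differences as an explanation for
differential retention.

The enrichment statistic restricts the population to parental-high probes
genome-wide. For a chromosome with `m` parental-high probes (and `n`
elsewhere), of which `q` are among the `k` genome-wide retained probes,
the chance expectation is `e = (m/(m+n))·k` and the percent enrichment
bias is `100·(q−e)/k`. Two identities follow from the partition —
`Σq = k` and `Σe = k`, hence `Σ bias = 0` — and the implementation asserts
them on every run. This population choice (parental-high probes, not all
array probes) is the only one under which `e` is an expected *retained*
count per chromosome; with the all-probe population, `e` would mix
retention with baseline methylation density.

Significance comes from the hypergeometric distribution (`phyper`), the
exact law of `q` when `k` retained probes are allocated at random among
`m + n` candidates. We report a direction-matched one-sided tail: upper
(`P(X ≥ q)`, computed as the survival function at `q − 1` so the observed
count is included) when `q ≥ e`, lower (`P(X ≤ q)`) when `q < e` — both
enriched and depleted chromosomes are flagged, at a fixed α = 1e-6 on the
raw p-value across the 23 tested chromosomes. A Bonferroni-adjusted
column is emitted for reference but does not drive the flag. chrY is
excluded from the population by default (configurable): its sparse probes
are reported separately rather than diluted into the autosome + chrX
analysis.

## Classifying retained promoter probes

The scientific question behind the classifier: of the promoter probes that
keep β ≥ 0.7 in both parental and resistant lines, which were already
methylated in normal tissue, and which acquired methylation de novo in
cancer? The evidence is the mean beta per sex across a non-cancer tissue
panel (the aggregation rule is the per-sex mean; at least one sample of
each sex is required). Thresholds, all configurable:

* `methylated_in_normal`: both sex means ≥ 0.7 — the same high-methylation
  cutoff used throughout.
* `unmethylated_in_normal` (de novo in cancer), autosomes: both sex means
  ≤ 0.3.
* `unmethylated_in_normal`, chrX: male mean ≤ 0.3 **and** female mean
  ≤ 0.7. The male bound is the anchor — the cell lines carry a single
  active X, so "unmethylated in normal" for that X is a male-side
  statement. The female side accepts both the X-inactivation signature
  (monoallelic, near 0.5) and the female-low pattern of probes that escape
  X inactivation. We deliberately do not require the female mean to sit
  *inside* the monoallelic band: an XCI-escaping CpG island that is
  unmethylated in both sexes yet methylated in the cancer line is still de
  novo hypermethylation, and a strict band would miscall exactly those
  probes.
* anything else: `unclassified`, counted but excluded from the de novo
  percentage denominator.

The numeric bounds (0.3 low, [0.3, 0.7] monoallelic band, 0.7 high) are
the package's operationalisation of the verbal categories "unmethylated",
"50% methylated" and "methylated"; only the 0.7 bound is standard usage,
the others are design choices exposed in `classification_thresholds()`.

`classification_summary()` reports category counts and
`pct_de_novo = 100·n_de_novo/(n_de_novo + n_methylated_normal)` either
genome-wide or chrX-only, plus (genome-wide) the share of de novo probes
located on chrX — the three percentages that summarize how strongly de
novo hypermethylation concentrates on the X chromosome.

## The simulator

`simulate_dataset()` generates the structure the analysis assumes, with
ground truth, so every stage is testable end to end:

* **Mixture components.** Beta values are drawn from two-parameter beta
  distributions: low (2,18), mean 0.1; high (18,2), mean 0.9; monoallelic
  (12,12), mean 0.5; intermediate (6,6). The low/high pair reproduces the
  bimodal parental density; the low component's mass above 0.7 is ~5e-9,
  so demethylated probes essentially never leak into high calls.
* **Latent states.** Each probe is constitutively methylated in tissue
  with probability 0.45; of the remaining chrX probes, 80% follow the
  X-inactivation pattern (female monoallelic, male low) and 20% escape.
  De novo methylation in the parental line is then calibrated per
  chromosome so the parental-high fraction hits 0.6 — the roughly uniform
  baseline real parental lines show. These two fractions (0.45, 0.8) are
  realism choices of the generator, not measured quantities.
* **Retention.** Each parental-high probe keeps its methylation in the
  compromised lines with a per-chromosome probability: default 0.05,
  lowered to 0.02 on the depleted chromosomes 16/17/19/22, raised to 0.25
  on chrX. Lost probes in the drug-resistant (but not the genetic dko)
  line land in the intermediate component with probability 0.15,
  reproducing the intermediate-methylation shoulder specific to drug
  treatment. Note the shoulder has appreciable mass above 0.7 (~8%), so
  resistant-line retention percentages sit slightly above the nominal
  retention probability; the dko line has no such inflation.
* **Scale.** ~20,000 probes distributed proportionally to real EPIC
  per-chromosome densities, 5 normal samples per sex, and (for cohorts)
  20 tumors / 10 adjacent normals by default — sizes chosen so the full
  test suite exercises every stage at meaningful statistical resolution
  in well under a minute. Parameter-recovery checks use 20 replicate
  seeds at this scale.
* **Determinism.** One RNG stream seeded once; draws are consumed in a
  fixed order (manifest, latent states, betas sample-by-sample in sheet
  order, detection p-values), so identical configs give bit-identical
  output on any platform with R's default generator.

What the simulator does *not* emulate: intensity-level (idat) signals and
their preprocessing, probe-type chemistry differences, batch effects,
copy-number artifacts, spatially correlated methylation along the genome,
and inter-individual variation in the tissue panel. Passing tests
therefore validate the pipeline's statistics and bookkeeping, not its
robustness to those real-data phenomena — preprocessing is assumed done
upstream (e.g. SeSAMe) before betas reach this package.

## Cohort summaries

`cohort_summary()` is descriptive: per-probe mean beta and sample count in
each sex × tissue-type cell, tumor-minus-adjacent-normal deltas *per sex*
(mandatory stratification, since baseline chrX methylation differs by sex),
and a tumor hypermethylation fraction. The default hyper call is relative —
tumor beta exceeding the sex-matched adjacent-normal mean by 0.3 — with an
absolute β ≥ 0.7 alternative; the relative form is preferred because a
female X-inactivated baseline of ~0.5 makes any absolute cutoff
sex-confounded. Rows order by hyper fraction descending and the emitted
sample ordering is sex-major then tissue type, the layout used for
tumor/normal heatmaps. `intersect_probe_sets()` handles carrying an
EPIC-selected probe set onto an HM450-profiled cohort. Model-based
tumor-vs-normal inference (mixed-effects beta regression and the like) is
out of scope here.

## Numerical conventions and degenerate inputs

* Quantiles: linear interpolation between order statistics
  (`stats::quantile` type 7), fixed so oracle tests are exact.
* Cutoff comparisons are inclusive (≥); percentages are kept at full float
  precision, rounding is presentation-only.
* Zero-denominator cases are flagged, not silently zeroed: no
  parental-high probes on a chromosome → `NA` retention; none genome-wide
  → error; `k = 0` → bias undefined; empty locus window → empty table with
  a warning.
* The pipeline entry point (`run_pipeline()`) validates its config
  strictly — unknown keys are errors naming the key — writes every stage
  as TSV with a parameter header, and records package version, parameters,
  input checksums and seed in a JSON run manifest; a failed stage leaves
  an `INCOMPLETE` marker.

## Known limitations

The classifier's thresholds are step functions of panel means; probes with
borderline means (e.g. a true monoallelic probe whose small-panel mean
drifts past 0.7) are misclassified at a rate that grows as the mixture
components overlap — the test suite demonstrates this degradation
deliberately. The enrichment test conditions on `k` and so inherits the
usual caveat of hypergeometric enrichment tests: it tests allocation given
the total, not the total itself. And because the cohort layer is
descriptive, differences it reports carry no uncertainty quantification.
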