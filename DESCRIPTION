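Package: methretain
Title: Chromosome-Level Retention of DNA Methylation After DNMT1 Inhibition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for Infinium methylation array beta values from
    DNMT1-compromised cancer cell lines. Quantifies, per chromosome, the
    retention of high methylation after pharmacological DNMT1 inhibition or
    genetic knockdown, computes a chromosome enrichment-bias statistic with
    hypergeometric significance testing, and classifies demethylation-resistant
    promoter probes by their methylation status in non-cancer tissues,
    separating constitutive methylation from cancer-acquired (de novo)
    hypermethylation, with sex-aware handling of X-inactivation methylation
    patterns. Includes a synthetic EPIC-like methylome simulator so every
    stage is testable without external array data, and a descriptive
    tumor/adjacent-normal cohort summary layer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
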