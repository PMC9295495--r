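Package: ncvint
Title: Evidence-Based Interpretation of Small Variants in Non-Coding Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An automatable engine for clinical interpretation of small
    variants (SNVs and indels under 50 bp) in non-coding regions of the
    genome. Builds interpretable region sets (UTRs, introns, promoters and
    evidence-linked cis-regulatory elements) from transcript models,
    triages candidate molecular mechanisms (upstream start codon creation,
    splice-context disruption, polyadenylation-signal loss and others),
    gates proposed ACMG/AMP evidence codes through non-coding-specific
    applicability rules with strength modulation, and combines the
    surviving evidence into a five-tier classification in both the
    categorical combining-table and point-based modes. Also implements a
    trio-based scan for rare non-coding variants in trans with heterozygous
    predicted loss-of-function alleles in biallelic loss-of-function genes,
    and a ClinVar-style census of variant classifications by genomic region
    with transcript footprint statistics. Ships deterministic synthetic
    fixture generators (toy genomes, trio cohorts, ClinVar-like call sets
    and worked-example evidence worksheets) so every pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
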