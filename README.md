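# ncvint — evidence-based interpretation of small variants in non-coding regions

Most clinical variant interpretation concentrates on protein-coding
exons, yet penetrant disease variants occur in 5′/3′ UTRs, deep introns,
promoters and distal cis-regulatory elements (CREs). `ncvint` is an R
package for clinical scientists and pipeline developers that turns
practice recommendations for this variant class into a deterministic,
auditable engine:

* **Interpretable regions** — per-gene region sets from clinical
  (MANE-first) transcript models: exact UTR/coding/intron tiling plus a
  promoter in four modes (200 bp core upstream, 2 kb audit window,
  250 bp up+down minimal, or the open-chromatin interval containing the
  TSS), and a two-step CRE admission gate (element evidence + validated
  gene link + gene–disease validity ≥ moderate).
* **Mechanism triage** — a machine-readable taxonomy of documented
  non-coding disease mechanisms with sequence-level detectors: uAUG/uORF
  scanning with Kozak grading, splice-context classification (canonical
  ±1/2, donor +5, splice region, deep intronic), polyA-signal motif
  disruption.
* **ACMG/AMP evidence gating** — code-specific applicability rules for
  PVS1, PM1, PS1/PM5, PM3, PS3/BS3, PP3/BP4 and PP4 that cap or reject
  proposed evidence (never strengthen it), reject missense-only codes,
  cap PM2 at Supporting, and resolve mutual exclusivities (e.g. PVS1 ×
  PP3; PS3 × PP3 on a shared mechanism).
* **Five-tier classification** — the standard categorical combining
  table (verified exhaustively against an independent truth-table
  oracle) and the 1/2/4/8 point scale (Pathogenic ≥ 10, Likely
  Pathogenic 6–9, VUS 0–5, Likely Benign −6…−1, Benign ≤ −7), with
  conflict-to-VUS semantics and BA1 as stand-alone.
* **Cohort pipelines** — a trio scan for rare non-coding variants in
  trans with heterozygous high-confidence pLoF alleles in biallelic-LoF
  genes (AF < 0.5 %, allele balance 25–75 %, filtering allele frequency,
  zero homozygotes, permissive splice filter ≥ 0.2 on intronic
  candidates), and a ClinVar-style census of classifications by region
  category with transcript footprint statistics.
* **Synthetic fixtures** — seed-deterministic generators for toy
  genomes, Mendelian-consistent trio cohorts with planted in-trans/
  in-cis variants, and ClinVar-like call sets with planted mixtures, so
  everything is testable offline.

## Worked example

The package ships fully specified evidence worksheets for three example
curations. The deep-intronic cryptic-exon case — a variant proven in
trans with a pathogenic coding allele, with a patient RNA splicing
assay and conflicting in-silico predictions:

```r
library(ncvint)
ws <- worked_example_worksheets()
classify_variant(ws$cftr_initial$observations, ws$cftr_initial$context)
#> Non-coding variant classification
#>   Tier: LikelyPathogenic (categorical: LikelyPathogenic; points: +8 -> LikelyPathogenic)
#>   Applied: PM2_Supporting, PM3_Moderate, PP4_Supporting, PS3_Strong
#>   Gate trail:
#>     - PM2: accepted at Supporting [pm2_cap_supporting]
#>     - PM3: accepted at Moderate
#>     - PP3: rejected [conflicting_predictions]
#>     - PP4: accepted at Supporting
#>     - PS3: accepted at Strong
```

Reading the output: the splicing assay supports PS3 at Strong (4
points); the confirmed in-trans occurrence gives PM3 Moderate (2);
absence from reference populations gives PM2 capped at Supporting (1);
the specific phenotype gives PP4 (1). PP3 is rejected because the
prediction tools disagree. 1 Strong + 1 Moderate + 2 Supporting — or
equivalently 8 points — is Likely Pathogenic. When later reports
confirm additional in-trans families, raising PM3 to VeryStrong, the
same worksheet (`ws$cftr_updated`) reaches Pathogenic (14 points).
`tidy()` and `glance()` return the gate decisions and a one-row summary
as tibbles; `autoplot()` methods plot census and scan summaries.

A thin command-line wrapper over the same functions is installed at
`inst/cli/ncvint.R` with subcommands `regions`, `classify`,
`trans-scan`, `clinvar-audit`, `footprint` and `simulate`.

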