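---
title: "Interpreting small variants in non-coding regions with ncvint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting small variants in non-coding regions with ncvint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncvint)
library(dplyr)
```

## The problem

Clinical genetic testing concentrates on protein-coding exons, yet
penetrant disease variants are repeatedly found in 5' and 3' UTRs, deep
introns, promoters and distal cis-regulatory elements (CREs). Because
there is no regulatory equivalent of the triplet code, such variants are
hard to predict, routinely left as variants of uncertain significance
(VUS), or dropped from analysis entirely. `ncvint` turns a set of
practice recommendations for this variant class into an automatable
engine with four cooperating parts:

1. **Region definition and filtering** — which bases of the genome are
   *interpretable* for a given gene, and which candidate CREs qualify.
2. **Mechanism triage** — which documented disease mechanisms are
   plausible for a variant in that region, supported by sequence-level
   detectors (upstream start codon creation, splice context,
   polyadenylation-signal loss).
3. **Evidence gating** — validating proposed ACMG/AMP evidence codes
   against non-coding applicability rules, capping or rejecting them.
4. **Combination** — a five-tier verdict from the surviving codes, in
   categorical and point modes.

Two cohort-scale pipelines reuse these parts: a trio scan for rare
non-coding variants in trans with heterozygous predicted
loss-of-function (pLoF) alleles, and a ClinVar-style census of variant
classifications by region.

## Regions

All interval arithmetic is 0-based half-open internally; VCF (1-based),
GFF3 (1-based inclusive) and BED (0-based half-open) conventions are
converted only at the I/O boundary. Contig-name dialects ("chr17" vs
"17") are harmonised with `harmonize_contigs()`.

Per gene, interpretation uses a single clinical transcript chosen by
`select_clinical_transcript()` with precedence MANE Select > MANE Plus
Clinical > canonical and a lexical tie-break. `derive_gene_regions()`
then tiles the transcript span exactly into 5'UTR, coding, 3'UTR and
intron pieces (introns between UTR exon fragments are classed *intron*,
since both cohort pipelines treat intronic sequence as one class) and
adds a promoter in one of four modes:

| mode | window | use |
|------|--------|-----|
| `core200` | 200 bp directly upstream of the TSS | trio in-trans scan |
| `audit2kb` | 2 kb directly upstream | region census |
| `minimal250` | 250 bp up- **and** downstream | fallback when no epigenetic support exists |
| `epigenetic` | union of open-chromatin peaks containing the TSS | preferred when tissue-relevant data exist |

Upstream is strand-aware (5' of the TSS in transcript orientation), and
windows are clipped at contig edges. In `minimal250` and `epigenetic`
modes the promoter may overlap the 5' end of the gene body; the genic
tiling itself is always disjoint. When several open-chromatin peaks
contain the TSS their union is used, reading "the region of open
chromatin surrounding the TSS" as one contiguous region. The 2-kb audit
promoter is *not* trimmed where it overlaps a neighbouring gene's
transcript; precedence rules in the census resolve such overlaps
deterministically instead.

Candidate CREs pass `admit_candidate_cre()` only with (i) at least one
element-level line of evidence (open chromatin, H3K27Ac/H3K4Me1, TF
ChIP), (ii) at least one experimental link to the target gene (chromatin
interaction, perturbation, eQTL) and (iii) gene-disease validity at
definitive, strong or moderate level (or PanelApp green). Anything less
is a research variant; the failed gates are named in the output. This is
a *filter*, never evidence of pathogenicity.

`assign_region_contexts()` may give one variant several contexts — e.g.
intronic in gene B while inside an admitted CRE linked to gene A — and
each context is interpreted against its own gene.

## Mechanism triage

`mechanism_taxonomy()` ships a versioned table of documented
disease mechanisms keyed by region class, with matching VEP consequence
categories and the class of in-silico predictor applicable. Three
sequence-level detectors rank this list for a concrete variant:

* `scan_uaug()` detects ATG creation in any reading window covering the
  edit, classifies the resulting ORF (discrete uORF when an in-frame
  stop lies wholly upstream of the CDS; CDS elongation when in frame
  with no intervening stop; overlapping out-of-frame ORF otherwise) and
  grades the Kozak context. Kozak strength is binarised on the two
  positions with the strongest consensus signal (-3 in A/G and +4 = G;
  both = strong, one = moderate, none = weak) — the minimal standard
  operationalisation of "strong Kozak consensus".
* `classify_splice_context()` computes junction offsets in transcript
  orientation: canonical dinucleotides at intronic offsets 1-2, the
  donor +5 site (elevated prior of splice disruption), the common
  splice-region convention (exonic 1-3 / intronic 3-8), and deep
  intronic beyond that. The convention is stated explicitly because the
  category is named in annotation practice without fixed bounds.
* `check_polya_motif()` flags destruction of an AATAAA/ATTAAA hexamer;
  converting one canonical hexamer into the other is not disruption.

Detector hits **only reorder the triage list**; they never activate an
evidence code by themselves. Predictions feed PP3/BP4 through explicit
score inputs, respecting the caution against over-interpreting
predictors.

## Evidence gating

`evaluate_evidence()` dispatches each proposed code to its gate. Gates
can accept, cap (downgrade) or reject — no gate ever raises a proposed
strength. The non-coding-specific rules:

* **PVS1** only for canonical ±1/2 splice sites in genes with an
  established loss-of-function mechanism, and not for canonical sites
  inside UTRs unless the downstream impact is clearly LoF. Everything
  else is rejected: a null effect cannot be confidently predicted for
  non-coding variants without data.
* **PM1** only for validated recurrent TF-motif disruption or variant
  clustering in a well-defined enhancer sub-region, always capped at
  Supporting (non-coding constraint is base-specific, not regional).
  In-silico-only motif calls are rejected with reason `use_pp3`.
* **PS1** at full strength when the same base as an established
  pathogenic change is hit (e.g. the same uORF stop codon); at
  Supporting for same-position different-alt splice matches whose
  predicted impact is at least as great as the prior variant's.
* **PM5** for variants predicted to have exactly the same impact on the
  same gene as an established pathogenic variant (e.g. a new uAUG in
  strong Kozak context creating an out-of-frame overlapping ORF),
  capped at Moderate. "Exactly the same impact" is operationalised as
  the `same_predicted_impact` relation plus a same-gene requirement,
  and surfaces in the decision reasons rather than being hidden.
* **PM3** per standard recessive rules for confirmed in-trans
  configurations, downgraded one step for genes with > 1 Mb intronic
  span or when reference datasets poorly match the individual's
  ancestry. `pm3_gene_adjustment()` supplies the empirical exceedance
  probability of the candidate's score across the gene, adjusting for
  region size and local mutability.
* **PS3/BS3**: patient RNA assays reach Strong only with tissue-matched
  expression and adequate sequencing depth; reporter and MAVE assays
  cap at Moderate (artificial systems requiring validation) as do
  chromatin-interaction disruption assays (kept at Moderate since no
  stronger precedent is established); BS3 requires biallelic expression
  shown, adequate coverage and coverage of *all* candidate mechanisms
  of the context (a normal RNA read-out cannot clear a 5'UTR variant
  whose plausible mechanism is translational), or a direction of effect
  contradicting the gene's dosage mechanism.
* **PP3/BP4**: scores computed for a different target gene's context
  are ignored (a splice score for a neighbouring gene's transcript says
  nothing about an enhancer's target); conflicting tool calls apply
  neither code; the donor +5 context and genome-wide-predictor caution
  are recorded as reasons.
* **PP4** only when the phenotype is discriminative and the gene is
  one of at most 3 associated genes (the "only, or one of very few"
  wording made concrete; configurable via `threshold_config()`).
* **PP2/BP1** are missense-specific and always rejected. Frequency,
  de novo and segregation codes pass through unchanged, except **PM2**
  which is capped at Supporting per current consensus.

`resolve_exclusivities()` then prevents double-counting one evidence
source: PVS1 excludes PP3; PS3 excludes PP3 when the assay addressed
the predicted mechanism (mechanism tags travel with each observation);
PM1/PM5 beat PP3 on shared motif/prediction evidence.

## Combining

`combine_categorical()` encodes the standard five-tier combining table;
`combine_points()` the 1/2/4/8 point scale with tiers P ≥ 10, LP 6-9,
VUS 0-5, LB -6..-1, B ≤ -7. The engine prescribes modifications to
*codes*, not a new combiner, so both external standards are encoded;
categorical is the default and the two agree on every worked example.
Conflicting pathogenic and benign rule hits resolve to VUS (no
clinical-judgement override — the engine stays deterministic), except
BA1 which outranks everything. The benign side of the categorical table
has no Moderate bucket, so a benign observation at Moderate counts as
Supporting categorically and scores -2 in point mode. The categorical
mode is verified exhaustively against an independently written
truth-table oracle over all evidence multisets with up to six
pathogenic and three benign codes.

```{r}
ws <- worked_example_worksheets()
cl <- classify_variant(ws$cftr_initial$observations, ws$cftr_initial$context)
cl
```

## The trio in-trans scan

`find_plof_pairs()` keeps (proband, gene) pairs with exactly one
heterozygous high-confidence pLoF in a biallelic-LoF gene, allele
frequency below 0.5% in every available source (the "and/or" of
cohort-vs-reference frequency is implemented as a strict AND, with
`af_rule = "any"` for the permissive reading) and alt-read balance
strictly between 25% and 75%. `scan_in_trans_noncoding()` then searches
the gene's introns, UTRs and 200-bp core promoter for variants
transmitted by the alternative parent, with filtering allele frequency
below 0.5% and no observed homozygotes. The filtering allele frequency
uses the one-sided 95% lower confidence bound `qbeta(0.05, AC, AN-AC+1)`
when allele counts are available, falling back to the point estimate.
The permissive splice filter (score ≥ 0.2) applies to intronic
candidates only; unscored intronic variants fail the filter (documented
conservative choice). Phasing is by transmission: a parent is the
certain origin of a proband-het allele only when the other parent
cannot have contributed it (or the parent is homozygous); de novo and
doubly-heterozygous configurations are `unknown`. Sex-chromosome-style
non-diploid genotypes are excluded from phasing, and the 200-bp
promoter is strand-aware — upstream in transcript orientation — since
the alternative is not stated anywhere authoritative.

## The region census

`categorize_variants()` assigns each record exactly one category across
all overlapping MANE Select transcripts with precedence coding > 5'UTR
> 3'UTR > intron > 2-kb-upstream promoter, mirroring the order in which
the categories are defined; the precedence for multi-category overlaps
is a documented choice, not a stated rule. Indels are localised by the
leftmost altered base of their normalized (left-aligned, parsimonious)
representation. Genes without a MANE Select transcript contribute
nothing, so their coding variants fall into `other` — the same
behaviour observed in full-scale censuses. `audit_summary()` reports
counts, per-category VUS rates and the share of high-confidence
pathogenic records (review status multiple-submitters-no-conflicts,
expert panel, or practice guideline; significance Pathogenic /
Likely_pathogenic / Pathogenic-Likely_pathogenic, matched on the
primary term before comma modifiers) in UTRs or upstream windows.
`region_footprint_stats()` computes spliced region lengths, whose
per-transcript identity 5'UTR + CDS + 3'UTR + introns = span is
asserted in the tests; spliced (not genomic) UTR lengths are the
documented interpretation.

## Synthetic fixtures: what they emulate and what they do not

All validation runs on deterministic generators (`sim_config()` /
`make_toy_reference()` / `make_trio_cohort()` / `make_clinvar_like()`):

* Toy genomes: ~10 multi-exon genes on both strands with MANE-like
  provenance tags, one gene with a competing canonical transcript and
  one canonical-only gene, intergenic gaps of 4.5-7 kb so that census
  categories are unambiguous by construction.
* Trio cohorts (defaults chosen once as the study conditions): one
  planted heterozygous HC pLoF per trio, in-trans non-coding candidates
  at a Poisson rate of 0.9 per pair (the summary-shape the cohort
  procedure reports), in-cis decoys at rate 0.3, frequency- and
  homozygote-failing decoys at rates 0.3/0.2. Intronic candidates carry
  splice scores uniform on (0,1) and allele frequencies span the 0.5%
  threshold so every filter is exercised on both sides.
* ClinVar-like call sets: positions drawn (and verified) to hit planted
  category mixtures exactly; significance and review-status strings
  from configurable mixtures.

The generators make **no** attempt to model linkage structure, mutation
rate heterogeneity, sequencing error, population stratification or
realistic gene lengths. Passing tests therefore demonstrate that the
pipelines are *correct bookkeeping machines* — exact recovery of
planted truths, zero in-cis leakage, filter monotonicity — not that
they reproduce any particular cohort's yield. Cohort-scale published
figures from access-restricted data are consequently not asserted
anywhere; the full-scale census against pinned public releases is a
documented, download-gated reproduction path rather than part of the
test surface.

Problem sizes used throughout (chosen to keep the whole suite
comfortably interactive): 100 randomized transcripts for the region
property suites, 200 trios for rate recovery, 500 ClinVar-like records
for the census, and the full 4,200-multiset enumeration for the
combiner oracle.

## Numerical and degenerate-input choices

* Variant normalization: trim shared suffix (borrowing reference bases
  leftward through repeat runs), then shared prefix; idempotent; errors
  on reference mismatch and on left-alignment hitting the contig start.
* Region assignment uses a single anchor base per variant: SNV at
  `pos`, deletion at `pos + 1`, insertion at its anchor base.
* Promoter windows clip at contig edges; epigenetic mode falls back to
  `minimal250` when no peak contains the TSS.
* Duplicate code proposals keep the strongest and warn; evaluation
  output is sorted by code id, so results are permutation-invariant.
* Empty worksheets classify as VUS; an empty gene-score distribution in
  `pm3_gene_adjustment()` is an error, not a silent 0.

## Known limitations

* One clinical transcript per gene; interpreting against multiple
  transcripts of the same gene is out of scope.
* Enhancer-gene links, predictor scores and LoF confidence classes are
  consumed as inputs, never computed.
* Structural variants (≥ 50 bp), non-coding RNA gene interpretation
  (taxonomy rows exist but gating defaults to research-variant, since
  gene-level validity is mostly unestablished) and Bayesian
  code-calibration are not implemented.
* Read-backed phasing is not attempted; phase comes from transmission
  only.
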