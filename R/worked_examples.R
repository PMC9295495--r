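#' Worked-example evidence worksheets
#'
#' Three fully specified evidence bundles exercising the gating and
#' combining machinery end to end, modelled on published example
#' curations of non-coding variants:
#'
#' \describe{
#'   \item{nf1}{A 5'UTR uAUG-creating variant (strong Kozak context,
#'     out-of-frame overlapping ORF) matching the predicted impact of
#'     established pathogenic uAUG variants in the same gene: PM5 with
#'     PM2_Supporting and PP4, plus a configurable de novo / segregation
#'     code and an optional functional assay.}
#'   \item{cftr_initial / cftr_updated}{A deep-intronic cryptic-exon
#'     variant proven in trans with a pathogenic coding allele: PS3_Strong
#'     (patient RNA assay), PM3 (VeryStrong once additional in-trans
#'     families are reported), PM2_Supporting, PP4; a conflicting
#'     prediction set means neither PP3 nor BP4 survives gating.}
#'   \item{pax6}{A distal-enhancer variant (intronic in a neighbouring
#'     gene): PS2, PS3_Moderate (validated reporter assay),
#'     PM2_Supporting, PP3 (in-context deleteriousness scores; a splice
#'     score computed for the neighbouring gene's transcript is ignored),
#'     PP4.}
#' }
#'
#' @param nf1_denovo How the NF1 de novo / segregation evidence is coded:
#'   `"PM6"` (assumed de novo), `"PS2"` (confirmed), or `"PP1_Moderate"`
#'   (moderate segregation evidence).
#' @param nf1_ps3 Optional NF1 functional assay: `"none"` (default),
#'   `"reporter"` (validated translation reporter, graded Moderate) or
#'   `"patient_expression"` (tissue-matched patient expression assay,
#'   graded Strong).
#' @return Named list of bundles, each a list with `observations`
#'   (worksheet tibble) and `context`.
#' @export
worked_example_worksheets <- function(nf1_denovo = c("PM6", "PS2",
                                                     "PP1_Moderate"),
                                      nf1_ps3 = c("none", "reporter",
                                                  "patient_expression")) {
  nf1_denovo <- match.arg(nf1_denovo)
  nf1_ps3 <- match.arg(nf1_ps3)

  nf1_ctx <- evidence_context(
    gene_id = "NF1", region_class = "five_prime_utr", in_utr = TRUE,
    lof_established_mechanism = TRUE,
    n_genes_for_phenotype = 1L, phenotype_discriminative = TRUE,
    gene_dosage_direction = "haploinsufficient",
    candidate_mechanism_labels = c("uAUG_creation", "uORF_perturbation")
  )
  nf1_obs <- dplyr::bind_rows(
    evidence_observation("PM5", "Moderate", support = list(
      relation = "same_predicted_impact", same_gene = TRUE,
      prior_classification = "Pathogenic"
    ), mechanisms = "uAUG_creation"),
    evidence_observation("PM2", "Supporting"),
    evidence_observation("PP4", "Supporting"),
    switch(nf1_denovo,
      PM6 = evidence_observation("PM6", "Moderate"),
      PS2 = evidence_observation("PS2", "Strong"),
      PP1_Moderate = evidence_observation("PP1", "Moderate")
    )
  )
  if (nf1_ps3 == "reporter") {
    nf1_obs <- dplyr::bind_rows(nf1_obs, evidence_observation(
      "PS3", "Strong",
      support = list(assay_class = "reporter", controls_validated = TRUE,
                     mechanisms_assessed = "uAUG_creation"),
      mechanisms = "uAUG_creation"))
  } else if (nf1_ps3 == "patient_expression") {
    nf1_obs <- dplyr::bind_rows(nf1_obs, evidence_observation(
      "PS3", "Strong",
      support = list(assay_class = "rna_seq", tissue_expression_match = TRUE,
                     coverage_adequate = TRUE,
                     mechanisms_assessed = "uAUG_creation"),
      mechanisms = "uAUG_creation"))
  }

  cftr_ctx <- evidence_context(
    gene_id = "CFTR", region_class = "intron", splice_class = "deep_intronic",
    lof_established_mechanism = TRUE,
    n_genes_for_phenotype = 1L, phenotype_discriminative = TRUE,
    candidate_mechanism_labels = "cryptic_exon_activation"
  )
  cftr_preds <- list(tools = tibble::tibble(
    name = c("maxentscan", "spliceai", "trap"),
    score = c(NA_real_, 0.02, 0.05),
    threshold_call = c("deleterious", "benign", "benign"),
    target_gene = "CFTR"
  ))
  cftr_base <- function(pm3_strength) dplyr::bind_rows(
    evidence_observation("PS3", "Strong", support = list(
      assay_class = "rna_seq", tissue_expression_match = TRUE,
      coverage_adequate = TRUE, controls_validated = TRUE,
      mechanisms_assessed = "cryptic_exon_activation"
    ), mechanisms = "splicing"),
    evidence_observation("PM3", pm3_strength, support = list(
      phase = "in_trans", partner_pathogenic = TRUE, af_pass = TRUE
    )),
    evidence_observation("PM2", "Supporting"),
    evidence_observation("PP4", "Supporting"),
    evidence_observation("PP3", "Supporting", support = cftr_preds,
                         mechanisms = "splicing")
  )

  pax6_ctx <- evidence_context(
    gene_id = "PAX6", region_class = "cre",
    n_genes_for_phenotype = 1L, phenotype_discriminative = TRUE,
    gene_dosage_direction = "haploinsufficient",
    candidate_mechanism_labels = c("tf_binding_alteration",
                                   "enhancer_disruption")
  )
  pax6_obs <- dplyr::bind_rows(
    evidence_observation("PS2", "Strong"),
    evidence_observation("PS3", "Moderate", support = list(
      assay_class = "reporter", controls_validated = TRUE,
      mechanisms_assessed = "tf_binding_alteration"
    ), mechanisms = "tf_binding_alteration"),
    evidence_observation("PM2", "Supporting"),
    evidence_observation("PP3", "Supporting", support = list(
      tools = tibble::tibble(
        name = c("cadd", "remm", "fathmm_mkl", "spliceai"),
        score = c(17.4, 0.985, 0.993, 0.00),
        threshold_call = c("deleterious", "deleterious", "deleterious",
                           "benign"),
        target_gene = c("PAX6", "PAX6", "PAX6", "ELP4")
      ),
      genome_wide_flag = TRUE
    ), mechanisms = "genome_wide_deleteriousness"),
    evidence_observation("PP4", "Supporting")
  )

  list(
    nf1 = list(observations = nf1_obs, context = nf1_ctx),
    cftr_initial = list(observations = cftr_base("Moderate"),
                        context = cftr_ctx),
    cftr_updated = list(observations = cftr_base("VeryStrong"),
                        context = cftr_ctx),
    pax6 = list(observations = pax6_obs, context = pax6_ctx)
  )
}
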