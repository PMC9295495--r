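lof_ctx <- function(...) {
  evidence_context(gene_id = "G1", lof_established_mechanism = TRUE, ...)
}

test_that("PVS1 is confined to canonical splice sites with clear LoF", {
  obs <- evidence_observation("PVS1")
  ok <- evaluate_evidence(obs, lof_ctx(splice_class = "canonical_donor"))
  expect_identical(ok$outcome, "accepted")
  expect_identical(ok$final_strength, "VeryStrong")
  # canonical site inside a UTR with unclear downstream impact
  utr <- evaluate_evidence(obs, lof_ctx(splice_class = "canonical_acceptor",
                                        in_utr = TRUE))
  expect_identical(utr$outcome, "rejected")
  expect_true("utr_downstream_impact_unclear" %in% utr$reasons[[1]])
  clear <- evaluate_evidence(obs, lof_ctx(splice_class = "canonical_acceptor",
                                          in_utr = TRUE,
                                          utr_lof_impact_clear = TRUE))
  expect_identical(clear$outcome, "accepted")
  # anything deeper than the canonical dinucleotides is rejected
  deep <- evaluate_evidence(obs, lof_ctx(splice_class = "deep_intronic"))
  expect_identical(deep$outcome, "rejected")
  expect_true("no_null_prediction_without_data" %in% deep$reasons[[1]])
})

test_that("PM1 is capped at Supporting or rejected", {
  ctx <- lof_ctx()
  hot <- evaluate_evidence(
    evidence_observation("PM1", "Moderate",
                         support = list(motif_validated_recurrent = TRUE)),
    ctx)
  expect_identical(hot$outcome, "downgraded")
  expect_identical(hot$final_strength, "Supporting")
  generic <- evaluate_evidence(
    evidence_observation("PM1", "Moderate",
                         support = list(region_wide_only = TRUE)), ctx)
  expect_identical(generic$outcome, "rejected")
  insilico <- evaluate_evidence(
    evidence_observation("PM1", "Moderate",
                         support = list(insilico_only = TRUE)), ctx)
  expect_identical(insilico$outcome, "rejected")
  expect_identical(insilico$reasons[[1]], "use_pp3")
})

test_that("PS1 distinguishes same-base matches from splice-alike matches", {
  ctx <- lof_ctx()
  same_base <- evaluate_evidence(
    evidence_observation("PS1", "Strong", support = list(
      relation = "same_nucleotide", predicted_impact_ge_prior = TRUE)), ctx)
  expect_identical(same_base$outcome, "accepted")
  expect_identical(same_base$final_strength, "Strong")
  alike <- evaluate_evidence(
    evidence_observation("PS1", "Strong", support = list(
      relation = "same_position_diff_alt",
      predicted_impact_ge_prior = TRUE)), ctx)
  expect_identical(alike$outcome, "downgraded")
  expect_identical(alike$final_strength, "Supporting")
  weaker <- evaluate_evidence(
    evidence_observation("PS1", "Strong", support = list(
      relation = "same_position_diff_alt",
      predicted_impact_ge_prior = FALSE)), ctx)
  expect_identical(weaker$outcome, "rejected")
})

test_that("PM5 accepts same-predicted-impact matches at Moderate max", {
  ctx <- lof_ctx()
  pm5 <- evaluate_evidence(
    evidence_observation("PM5", "Strong", support = list(
      relation = "same_predicted_impact", same_gene = TRUE)), ctx)
  expect_identical(pm5$outcome, "downgraded")
  expect_identical(pm5$final_strength, "Moderate")
  other_gene <- evaluate_evidence(
    evidence_observation("PM5", "Moderate", support = list(
      relation = "same_predicted_impact", same_gene = FALSE)), ctx)
  expect_identical(other_gene$outcome, "rejected")
  expect_error(evaluate_evidence(evidence_observation("PM5", "Moderate"),
                                 ctx),
               "payload")
})

test_that("PM3 needs confirmed in-trans phase and downgrades risky genes", {
  ok <- evaluate_evidence(
    evidence_observation("PM3", "Moderate", support = list(
      phase = "in_trans", partner_pathogenic = TRUE, af_pass = TRUE)),
    lof_ctx())
  expect_identical(ok$outcome, "accepted")
  expect_identical(ok$final_strength, "Moderate")
  big <- evaluate_evidence(
    evidence_observation("PM3", "Moderate", support = list(
      phase = "in_trans", partner_pathogenic = TRUE, af_pass = TRUE)),
    lof_ctx(large_intronic_gene = TRUE))
  expect_identical(big$outcome, "downgraded")
  expect_identical(big$final_strength, "Supporting")
  expect_true("large_intronic_gene_downgrade" %in% big$reasons[[1]])
  unk <- evaluate_evidence(
    evidence_observation("PM3", "Moderate", support = list(
      phase = "unknown", partner_pathogenic = TRUE)), lof_ctx())
  expect_identical(unk$outcome, "rejected")
})

test_that("gene-wide score exceedance probability is the empirical tail", {
  scores <- c(seq_len(999) / 1000, 1)
  expect_equal(pm3_gene_adjustment(1, scores), 1 / 1000)
  expect_equal(pm3_gene_adjustment(0.5, rep(0.5, 50)), 1)
  expect_equal(pm3_gene_adjustment(-1, scores), 1)
  expect_error(pm3_gene_adjustment(1, numeric()), "empty")
})

test_that("PS3 grading follows assay class and validation", {
  ctx <- lof_ctx()
  rna <- evaluate_evidence(
    evidence_observation("PS3", "Strong", support = list(
      assay_class = "rna_seq", tissue_expression_match = TRUE,
      coverage_adequate = TRUE)), ctx)
  expect_identical(rna$final_strength, "Strong")
  rna_weak <- evaluate_evidence(
    evidence_observation("PS3", "Strong", support = list(
      assay_class = "rna_seq", tissue_expression_match = FALSE,
      coverage_adequate = TRUE)), ctx)
  expect_identical(rna_weak$final_strength, "Moderate")
  rep_ok <- evaluate_evidence(
    evidence_observation("PS3", "Strong", support = list(
      assay_class = "reporter", controls_validated = TRUE)), ctx)
  expect_identical(rep_ok$outcome, "downgraded")
  expect_identical(rep_ok$final_strength, "Moderate")
  rep_bad <- evaluate_evidence(
    evidence_observation("PS3", "Strong", support = list(
      assay_class = "reporter", controls_validated = FALSE)), ctx)
  expect_identical(rep_bad$outcome, "rejected")
})

test_that("BS3 requires biallelic expression, coverage and full mechanism
           coverage, or a contradicting direction of effect", {
  ctx5 <- lof_ctx(in_utr = TRUE,
                  candidate_mechanism_labels = c("uAUG_creation",
                                                 "utr_splice_disruption"))
  partial <- evaluate_evidence(
    evidence_observation("BS3", "Strong", support = list(
      biallelic_expression_shown = TRUE, coverage_adequate = TRUE,
      mechanisms_assessed = "utr_splice_disruption")), ctx5)
  expect_identical(partial$outcome, "rejected")
  expect_true("mechanism_coverage_incomplete" %in% partial$reasons[[1]])
  full <- evaluate_evidence(
    evidence_observation("BS3", "Strong", support = list(
      biallelic_expression_shown = TRUE, coverage_adequate = TRUE,
      mechanisms_assessed = c("uAUG_creation", "utr_splice_disruption"))),
    ctx5)
  expect_identical(full$outcome, "accepted")
  gain <- evaluate_evidence(
    evidence_observation("BS3", "Strong", support = list(
      direction_of_effect = "increase")),
    lof_ctx(gene_dosage_direction = "haploinsufficient"))
  expect_identical(gain$outcome, "accepted")
  expect_true("direction_contradicts_gene_mechanism" %in% gain$reasons[[1]])
})

test_that("PP3/BP4 respect gene context and conflicting predictions", {
  mk <- function(calls, genes = "G1", code = "PP3") {
    evidence_observation(code, "Supporting", support = list(
      tools = tibble::tibble(name = paste0("t", seq_along(calls)),
                             score = 1, threshold_call = calls,
                             target_gene = genes)))
  }
  ctx <- lof_ctx()
  ok <- evaluate_evidence(mk(c("deleterious", "deleterious")), ctx)
  expect_identical(ok$outcome, "accepted")
  conflict <- evaluate_evidence(mk(c("deleterious", "benign")), ctx)
  expect_identical(conflict$outcome, "rejected")
  expect_true("conflicting_predictions" %in% conflict$reasons[[1]])
  bp4_conflict <- evaluate_evidence(mk(c("deleterious", "benign"),
                                       code = "BP4"), ctx)
  expect_identical(bp4_conflict$outcome, "rejected")
  # a benign score computed for the wrong gene is ignored, not conflicting
  wrong_gene <- evaluate_evidence(
    mk(c("deleterious", "benign"), genes = c("G1", "OTHER")), ctx)
  expect_identical(wrong_gene$outcome, "accepted")
  expect_true("wrong_gene_context_ignored" %in% wrong_gene$reasons[[1]])
  plus5 <- evaluate_evidence(mk("deleterious"),
                             lof_ctx(splice_class = "donor_plus5"))
  expect_identical(plus5$final_strength, "Supporting")
  expect_true("donor_plus5_high_prior" %in% plus5$reasons[[1]])
})

test_that("PP4 requires a discriminative phenotype with very few genes", {
  yes <- evaluate_evidence(
    evidence_observation("PP4"),
    lof_ctx(phenotype_discriminative = TRUE, n_genes_for_phenotype = 1L))
  expect_identical(yes$outcome, "accepted")
  vague <- evaluate_evidence(
    evidence_observation("PP4"),
    lof_ctx(phenotype_discriminative = FALSE, n_genes_for_phenotype = 1L))
  expect_identical(vague$outcome, "rejected")
  many <- evaluate_evidence(
    evidence_observation("PP4"),
    lof_ctx(phenotype_discriminative = TRUE, n_genes_for_phenotype = 10L))
  expect_identical(many$outcome, "rejected")
})

test_that("missense-only codes are always rejected; PM2 caps at Supporting", {
  ctx <- lof_ctx()
  d <- evaluate_evidence(dplyr::bind_rows(
    evidence_observation("PP2"),
    evidence_observation("BP1"),
    evidence_observation("PM2", "Moderate"),
    evidence_observation("PS2", "Strong")
  ), ctx)
  expect_identical(d$outcome[d$code == "PP2"], "rejected")
  expect_identical(d$outcome[d$code == "BP1"], "rejected")
  expect_identical(d$final_strength[d$code == "PM2"], "Supporting")
  expect_identical(d$final_strength[d$code == "PS2"], "Strong")
})

test_that("gates never raise a proposed strength (randomized fuzzing)", {
  set.seed(99)
  codes <- c("PVS1", "PM1", "PS1", "PM5", "PM3", "PS3", "BS3", "PP3",
             "BP4", "PP4", "PM2", "PS2", "PM6", "PP1", "BA1", "BS1",
             "PP2", "BP1")
  supports <- list(
    list(relation = "same_nucleotide", predicted_impact_ge_prior = TRUE),
    list(relation = "same_position_diff_alt",
         predicted_impact_ge_prior = TRUE),
    list(relation = "same_predicted_impact", same_gene = TRUE),
    list(phase = "in_trans", partner_pathogenic = TRUE, af_pass = TRUE),
    list(assay_class = "rna_seq", tissue_expression_match = TRUE,
         coverage_adequate = TRUE),
    list(assay_class = "reporter", controls_validated = TRUE),
    list(motif_validated_recurrent = TRUE),
    list(insilico_only = TRUE),
    list(biallelic_expression_shown = TRUE, coverage_adequate = TRUE),
    list(tools = tibble::tibble(name = "t", score = 1,
                                threshold_call = "deleterious",
                                target_gene = "G1"))
  )
  for (i in 1:300) {
    code <- sample(codes, 1)
    proposed <- sample(strength_levels()[1:4], 1)
    sup <- supports[[sample.int(length(supports), 1)]]
    ctx <- lof_ctx(
      splice_class = sample(c("canonical_donor", "deep_intronic", "none"),
                            1),
      in_utr = sample(c(TRUE, FALSE), 1),
      large_intronic_gene = sample(c(TRUE, FALSE), 1),
      phenotype_discriminative = sample(c(TRUE, FALSE), 1),
      n_genes_for_phenotype = sample(1:10, 1)
    )
    obs <- evidence_observation(code, proposed, support = sup)
    d <- tryCatch(evaluate_evidence(obs, ctx), error = function(e) NULL)
    if (is.null(d) || nrow(d) == 0) next
    if (d$outcome != "rejected") {
      expect_lte(match(d$final_strength, strength_levels()),
                 match(proposed, strength_levels()))
    }
    if (d$code == "PM1" && d$outcome != "rejected") {
      expect_identical(d$final_strength, "Supporting")
    }
    if (d$code %in% c("PP2", "BP1")) {
      expect_identical(d$outcome, "rejected")
    }
  }
})

test_that("exclusivity resolution drops PP3 against PVS1 and shared-
           mechanism PS3/PM1/PM5, and keeps independent pairs", {
  ctx <- lof_ctx(splice_class = "canonical_donor")
  mk_pp3 <- function(mech) {
    evidence_observation("PP3", "Supporting", support = list(
      tools = tibble::tibble(name = "t", score = 1,
                             threshold_call = "deleterious",
                             target_gene = "G1")), mechanisms = mech)
  }
  # PVS1 x PP3
  d <- resolve_exclusivities(evaluate_evidence(dplyr::bind_rows(
    evidence_observation("PVS1"), mk_pp3("splicing")), ctx))
  expect_identical(d$outcome[d$code == "PP3"], "rejected")
  expect_true("pvs1_pp3_exclusive" %in% d$reasons[[which(d$code == "PP3")]])
  # PS3 on the same mechanism drops PP3
  d2 <- resolve_exclusivities(evaluate_evidence(dplyr::bind_rows(
    evidence_observation("PS3", "Strong", support = list(
      assay_class = "rna_seq", tissue_expression_match = TRUE,
      coverage_adequate = TRUE), mechanisms = "splicing"),
    mk_pp3("splicing")), lof_ctx()))
  expect_identical(d2$outcome[d2$code == "PP3"], "rejected")
  # PS3 on a different mechanism keeps both
  d3 <- resolve_exclusivities(evaluate_evidence(dplyr::bind_rows(
    evidence_observation("PS3", "Strong", support = list(
      assay_class = "rna_seq", tissue_expression_match = TRUE,
      coverage_adequate = TRUE), mechanisms = "transcription"),
    mk_pp3("splicing")), lof_ctx()))
  expect_identical(d3$outcome[d3$code == "PP3"], "accepted")
  expect_true(d3$outcome[d3$code == "PS3"] != "rejected")
})

test_that("evaluation is deterministic and order-insensitive", {
  ws <- worked_example_worksheets()$cftr_initial
  d1 <- evaluate_evidence(ws$observations, ws$context)
  shuffled <- ws$observations[sample(nrow(ws$observations)), ]
  d2 <- evaluate_evidence(shuffled, ws$context)
  expect_identical(d1, d2)
  expect_warning(
    dup <- evaluate_evidence(dplyr::bind_rows(
      evidence_observation("PM2", "Supporting"),
      evidence_observation("PM2", "Moderate")), lof_ctx()),
    "duplicate")
  expect_identical(nrow(dup), 1L)
})
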