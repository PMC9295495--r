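#' Evidence strength scale
#'
#' The ordered ACMG/AMP strength ladder used throughout the gates:
#' Supporting < Moderate < Strong < VeryStrong < StandAlone. Gates only
#' ever cap or reject a proposed strength; none raises one.
#'
#' @return Character vector of strength levels, weakest first.
#' @export
strength_levels <- function() {
  c("Supporting", "Moderate", "Strong", "VeryStrong", "StandAlone")
}

strength_rank <- function(x) match(x, strength_levels())

strength_min <- function(a, b) {
  strength_levels()[pmin(strength_rank(a), strength_rank(b))]
}

strength_step_down <- function(x) {
  strength_levels()[pmax(strength_rank(x) - 1L, 1L)]
}

#' Build an evidence observation (one proposed ACMG/AMP code)
#'
#' @param code ACMG/AMP code id (e.g. `"PVS1"`, `"PM3"`, `"BP4"`).
#' @param proposed_strength Strength proposed by the analyst; defaults to
#'   the code's nominal strength (PVS=VeryStrong, PS/BS=Strong,
#'   PM=Moderate, PP/BP=Supporting, BA=StandAlone).
#' @param support Named list payload for the code's gate (assay
#'   descriptor, prediction set, prior-variant match, trans partner, ...).
#' @param mechanisms Character vector tagging which mechanism class the
#'   evidence addresses (used by exclusivity resolution).
#' @return One-row observation tibble.
#' @export
evidence_observation <- function(code, proposed_strength = NULL,
                                 support = NULL, mechanisms = character()) {
  if (is.null(proposed_strength)) {
    proposed_strength <- switch(substr(code, 1, 2),
      PV = "VeryStrong", PS = "Strong", PM = "Moderate", PP = "Supporting",
      BA = "StandAlone", BS = "Strong", BP = "Supporting",
      stop("unrecognised code: ", code, call. = FALSE)
    )
  }
  stopifnot(proposed_strength %in% strength_levels())
  tibble::tibble(code = code, proposed_strength = proposed_strength,
                 support = list(support), mechanisms = list(mechanisms))
}

#' Build the interpretation context for evidence gating
#'
#' Context flags describing the variant's region, the gene's disease
#' mechanism and the phenotype fit; every gate reads from this one object.
#'
#' @param gene_id Target gene of the interpretation.
#' @param region_class Region class of the variant context.
#' @param splice_class Splice context class (see
#'   [classify_splice_context()]).
#' @param lof_established_mechanism Is loss of function an established
#'   disease mechanism for the gene?
#' @param in_utr Is the variant inside a UTR?
#' @param utr_lof_impact_clear For canonical splice sites inside UTRs: is
#'   the downstream impact clearly loss-of-function?
#' @param large_intronic_gene Total intronic span exceeds the configured
#'   ceiling (PM3 downgrade trigger).
#' @param ancestry_mismatch Reference AF datasets poorly match the
#'   individual's genetic ancestry (PM3 downgrade trigger).
#' @param n_genes_for_phenotype Number of genes credibly associated with
#'   the phenotype.
#' @param phenotype_discriminative Is the phenotype highly specific?
#' @param gene_dosage_direction `"haploinsufficient"`, `"triplosensitive"`,
#'   `"both"` or `"unknown"`.
#' @param candidate_mechanism_labels Mechanism labels plausible for this
#'   context (used for the BS3 mechanism-coverage check).
#' @return Named list of class `ncv_context`.
#' @export
evidence_context <- function(gene_id = NA_character_,
                             region_class = "other",
                             splice_class = "none",
                             lof_established_mechanism = FALSE,
                             in_utr = FALSE,
                             utr_lof_impact_clear = FALSE,
                             large_intronic_gene = FALSE,
                             ancestry_mismatch = FALSE,
                             n_genes_for_phenotype = NA_integer_,
                             phenotype_discriminative = FALSE,
                             gene_dosage_direction = "unknown",
                             candidate_mechanism_labels = character()) {
  structure(
    list(
      gene_id = gene_id, region_class = region_class,
      splice_class = splice_class,
      lof_established_mechanism = lof_established_mechanism,
      in_utr = in_utr, utr_lof_impact_clear = utr_lof_impact_clear,
      large_intronic_gene = large_intronic_gene,
      ancestry_mismatch = ancestry_mismatch,
      n_genes_for_phenotype = n_genes_for_phenotype,
      phenotype_discriminative = phenotype_discriminative,
      gene_dosage_direction = gene_dosage_direction,
      candidate_mechanism_labels = candidate_mechanism_labels
    ),
    class = "ncv_context"
  )
}

.decision <- function(code, outcome, final_strength, reasons,
                      mechanisms = character()) {
  tibble::tibble(
    code = code, outcome = outcome,
    final_strength = if (outcome == "rejected") NA_character_
                     else final_strength,
    reasons = list(reasons), mechanisms = list(mechanisms)
  )
}

.accept_or_downgrade <- function(code, proposed, capped, reasons, mechanisms) {
  if (strength_rank(capped) < strength_rank(proposed)) {
    .decision(code, "downgraded", capped, reasons, mechanisms)
  } else {
    .decision(code, "accepted", proposed, reasons, mechanisms)
  }
}

# --- individual gates ------------------------------------------------------

gate_pvs1 <- function(obs, ctx) {
  s <- obs$support[[1]]
  mech <- obs$mechanisms[[1]]
  canonical <- ctx$splice_class %in% c("canonical_donor", "canonical_acceptor")
  if (!canonical || !isTRUE(ctx$lof_established_mechanism)) {
    return(.decision("PVS1", "rejected", NA,
                     "no_null_prediction_without_data", mech))
  }
  if (isTRUE(ctx$in_utr) && !isTRUE(ctx$utr_lof_impact_clear)) {
    return(.decision("PVS1", "rejected", NA,
                     "utr_downstream_impact_unclear", mech))
  }
  .accept_or_downgrade("PVS1", obs$proposed_strength, obs$proposed_strength,
                       character(), union(mech, "splicing"))
}

gate_pm1 <- function(obs, ctx) {
  s <- obs$support[[1]] %||% list()
  mech <- obs$mechanisms[[1]]
  if (isTRUE(s$insilico_only)) {
    return(.decision("PM1", "rejected", NA, "use_pp3", mech))
  }
  hotspot <- isTRUE(s$motif_validated_recurrent) ||
    isTRUE(s$enhancer_cluster)
  if (!hotspot) {
    return(.decision("PM1", "rejected", NA,
                     "base_specific_constraint_no_hotspot", mech))
  }
  .accept_or_downgrade("PM1", obs$proposed_strength, "Supporting",
                       "pm1_cap_supporting", union(mech, "tf_binding"))
}

gate_ps1_pm5 <- function(obs, ctx) {
  s <- obs$support[[1]]
  mech <- obs$mechanisms[[1]]
  if (is.null(s) || is.null(s$relation)) {
    stop(obs$code, " requires a prior-variant-match payload", call. = FALSE)
  }
  code <- obs$code
  if (code == "PS1") {
    if (identical(s$relation, "same_nucleotide")) {
      return(.accept_or_downgrade("PS1", obs$proposed_strength,
                                  obs$proposed_strength, character(), mech))
    }
    if (identical(s$relation, "same_position_diff_alt")) {
      if (!isTRUE(s$predicted_impact_ge_prior)) {
        return(.decision("PS1", "rejected", NA, "impact_not_ge_prior", mech))
      }
      return(.accept_or_downgrade("PS1", obs$proposed_strength, "Supporting",
                                  "ps1_splice_alike_supporting", mech))
    }
    return(.decision("PS1", "rejected", NA, "relation_mismatch", mech))
  }
  # PM5: same predicted impact, same gene, different site
  if (!identical(s$relation, "same_predicted_impact")) {
    return(.decision("PM5", "rejected", NA, "relation_mismatch", mech))
  }
  if (!isTRUE(s$same_gene %||% TRUE)) {
    return(.decision("PM5", "rejected", NA, "different_gene", mech))
  }
  .accept_or_downgrade("PM5", obs$proposed_strength, "Moderate",
                       "pm5_cap_moderate", mech)
}

gate_pm3 <- function(obs, ctx) {
  s <- obs$support[[1]] %||% list()
  mech <- obs$mechanisms[[1]]
  phase <- s$phase %||% "unknown"
  partner_ok <- isTRUE(s$partner_pathogenic)
  if (!identical(phase, "in_trans")) {
    return(.decision("PM3", "rejected", NA, "phase_unknown", mech))
  }
  if (!partner_ok) {
    return(.decision("PM3", "rejected", NA, "partner_unconfirmed", mech))
  }
  if (!isTRUE(s$af_pass %||% TRUE)) {
    return(.decision("PM3", "rejected", NA, "allele_frequency_fail", mech))
  }
  reasons <- character()
  strength <- obs$proposed_strength
  if (isTRUE(ctx$large_intronic_gene)) {
    strength <- strength_step_down(strength)
    reasons <- c(reasons, "large_intronic_gene_downgrade")
  }
  if (isTRUE(ctx$ancestry_mismatch)) {
    strength <- strength_step_down(strength)
    reasons <- c(reasons, "ancestry_mismatch_downgrade")
  }
  .accept_or_downgrade("PM3", obs$proposed_strength, strength, reasons, mech)
}

#' Empirical exceedance probability of a score within a gene
#'
#' Probability of observing an in-silico score at least as extreme as the
#' candidate's under the empirical distribution of all per-base scores
#' across the gene. Adjusts PM3-style evidence for region size and
#' localised mutability: a high exceedance probability argues for
#' downgrading.
#'
#' @param candidate_score Score of the candidate variant.
#' @param gene_scores Numeric vector of per-base scores across the gene.
#' @return `P(score >= candidate_score)` under the empirical distribution.
#' @export
pm3_gene_adjustment <- function(candidate_score, gene_scores) {
  gene_scores <- gene_scores[!is.na(gene_scores)]
  if (length(gene_scores) == 0) {
    stop("gene score distribution is empty", call. = FALSE)
  }
  mean(gene_scores >= candidate_score)
}

grade_ps3_bs3 <- function(obs, ctx) {
  s <- obs$support[[1]] %||% list()
  mech <- union(obs$mechanisms[[1]], s$mechanisms_assessed %||% character())
  code <- obs$code
  if (code == "PS3") {
    cls <- s$assay_class %||% "other"
    if (cls == "rna_seq") {
      if (isTRUE(s$tissue_expression_match) && isTRUE(s$coverage_adequate)) {
        return(.accept_or_downgrade("PS3", obs$proposed_strength, "Strong",
                                    character(), mech))
      }
      reasons <- c(
        if (!isTRUE(s$tissue_expression_match)) "tissue_expression_mismatch",
        if (!isTRUE(s$coverage_adequate)) "sequencing_depth_inadequate"
      )
      return(.accept_or_downgrade("PS3", obs$proposed_strength, "Moderate",
                                  reasons, mech))
    }
    if (cls %in% c("reporter", "mave")) {
      if (!isTRUE(s$controls_validated)) {
        return(.decision("PS3", "rejected", NA, "assay_not_validated", mech))
      }
      return(.accept_or_downgrade("PS3", obs$proposed_strength, "Moderate",
                                  "artificial_assay_cap_moderate", mech))
    }
    if (cls == "chromatin_interaction") {
      if (!isTRUE(s$controls_validated)) {
        return(.decision("PS3", "rejected", NA, "assay_not_validated", mech))
      }
      return(.accept_or_downgrade("PS3", obs$proposed_strength, "Moderate",
                                  "chromatin_interaction_cap_moderate", mech))
    }
    return(.decision("PS3", "rejected", NA, "assay_class_not_admissible",
                     mech))
  }
  # BS3
  direction <- s$direction_of_effect %||% "none"
  dosage <- ctx$gene_dosage_direction
  contradicts <- dosage %in% c("haploinsufficient", "triplosensitive") &&
    ((direction == "increase" && dosage == "haploinsufficient") ||
       (direction == "decrease" && dosage == "triplosensitive"))
  if (contradicts) {
    return(.accept_or_downgrade("BS3", obs$proposed_strength,
                                obs$proposed_strength,
                                "direction_contradicts_gene_mechanism", mech))
  }
  reasons <- character()
  if (!isTRUE(s$biallelic_expression_shown)) {
    reasons <- c(reasons, "biallelic_expression_not_shown")
  }
  if (!isTRUE(s$coverage_adequate)) {
    reasons <- c(reasons, "sequencing_depth_inadequate")
  }
  assessed <- s$mechanisms_assessed %||% character()
  uncovered <- setdiff(ctx$candidate_mechanism_labels, assessed)
  if (length(ctx$candidate_mechanism_labels) && length(uncovered)) {
    reasons <- c(reasons, "mechanism_coverage_incomplete")
  }
  if (length(reasons)) {
    return(.decision("BS3", "rejected", NA, reasons, mech))
  }
  .accept_or_downgrade("BS3", obs$proposed_strength, obs$proposed_strength,
                       character(), mech)
}

gate_pp3_bp4 <- function(obs, ctx) {
  s <- obs$support[[1]] %||% list()
  mech <- obs$mechanisms[[1]]
  preds <- s$tools
  code <- obs$code
  if (is.null(preds) || nrow(preds) == 0) {
    return(.decision(code, "rejected", NA, "no_predictions", mech))
  }
  reasons <- character()
  if ("target_gene" %in% names(preds) && !is.na(ctx$gene_id)) {
    wrong <- !is.na(preds$target_gene) & preds$target_gene != ctx$gene_id
    if (any(wrong)) reasons <- c(reasons, "wrong_gene_context_ignored")
    preds <- preds[!wrong, , drop = FALSE]
  }
  if (nrow(preds) == 0) {
    return(.decision(code, "rejected", NA,
                     c(reasons, "no_predictions_in_gene_context"), mech))
  }
  calls <- preds$threshold_call
  has_del <- any(calls == "deleterious")
  has_ben <- any(calls == "benign")
  if (has_del && has_ben) {
    return(.decision(code, "rejected", NA,
                     c(reasons, "conflicting_predictions"), mech))
  }
  if (identical(ctx$splice_class, "donor_plus5")) {
    reasons <- c(reasons, "donor_plus5_high_prior")
  }
  if (isTRUE(s$genome_wide_flag)) {
    reasons <- c(reasons, "genome_wide_predictor_caution")
  }
  if (code == "PP3") {
    if (!has_del) {
      return(.decision("PP3", "rejected", NA,
                       c(reasons, "no_deleterious_support"), mech))
    }
    return(.accept_or_downgrade("PP3", obs$proposed_strength, "Supporting",
                                reasons, mech))
  }
  if (!has_ben) {
    return(.decision("BP4", "rejected", NA,
                     c(reasons, "no_benign_support"), mech))
  }
  .accept_or_downgrade("BP4", obs$proposed_strength, "Supporting",
                       reasons, mech)
}

gate_pp4 <- function(obs, ctx, config) {
  mech <- obs$mechanisms[[1]]
  few <- !is.na(ctx$n_genes_for_phenotype) &&
    ctx$n_genes_for_phenotype <= config$pp4_max_genes
  if (isTRUE(ctx$phenotype_discriminative) && few) {
    return(.accept_or_downgrade("PP4", obs$proposed_strength, "Supporting",
                                character(), mech))
  }
  .decision("PP4", "rejected", NA, "phenotype_not_discriminative_or_few",
            mech)
}

# Codes applied exactly as in the generic framework (frequency, de novo,
# segregation). PM2 is capped at Supporting per current consensus practice.
.passthrough_codes <- c("BA1", "BS1", "BS2", "BS4", "PM2", "PM6", "PS2",
                        "PP1", "PS4", "BP2", "BP5", "BP7")

#' Gate all proposed evidence codes for a non-coding variant context
#'
#' Dispatches every observation to its code-specific applicability gate:
#' PVS1, PM1, PS1/PM5, PM3, PS3/BS3, PP3/BP4 and PP4 get non-coding-specific
#' handling; the missense-only codes PP2 and BP1 are always rejected;
#' frequency/de novo/segregation codes pass through at their proposed
#' strength with PM2 capped at Supporting. Duplicate proposals of one code
#' keep the strongest and warn. Output is ordered by code id, so the result
#' is invariant to input permutation.
#'
#' @param observations Observation tibble (rows from
#'   [evidence_observation()]).
#' @param ctx Context from [evidence_context()].
#' @param config Threshold registry.
#' @return Decision tibble: `code`, `outcome` (accepted / downgraded /
#'   rejected), `final_strength`, `reasons`, `mechanisms`.
#' @export
evaluate_evidence <- function(observations, ctx = evidence_context(),
                              config = threshold_config()) {
  if (nrow(observations) == 0) {
    return(tibble::tibble(code = character(), outcome = character(),
                          final_strength = character(), reasons = list(),
                          mechanisms = list()))
  }
  if (anyDuplicated(observations$code)) {
    warning("duplicate code proposals; keeping the strongest of each")
    observations <- observations |>
      dplyr::mutate(.rank = strength_rank(.data$proposed_strength)) |>
      dplyr::arrange(.data$code, dplyr::desc(.data$.rank)) |>
      dplyr::distinct(.data$code, .keep_all = TRUE) |>
      dplyr::select(-".rank")
  }
  decisions <- purrr::map(seq_len(nrow(observations)), function(i) {
    obs <- observations[i, , drop = FALSE]
    code <- obs$code
    mech <- obs$mechanisms[[1]]
    if (code %in% c("PP2", "BP1")) {
      return(.decision(code, "rejected", NA, "missense_only_rule", mech))
    }
    if (code == "PVS1") return(gate_pvs1(obs, ctx))
    if (code == "PM1") return(gate_pm1(obs, ctx))
    if (code %in% c("PS1", "PM5")) return(gate_ps1_pm5(obs, ctx))
    if (code == "PM3") return(gate_pm3(obs, ctx))
    if (code %in% c("PS3", "BS3")) return(grade_ps3_bs3(obs, ctx))
    if (code %in% c("PP3", "BP4")) return(gate_pp3_bp4(obs, ctx))
    if (code == "PP4") return(gate_pp4(obs, ctx, config))
    if (code == "PM2") {
      return(.accept_or_downgrade("PM2", obs$proposed_strength, "Supporting",
                                  "pm2_cap_supporting", mech))
    }
    if (code %in% .passthrough_codes) {
      return(.accept_or_downgrade(code, obs$proposed_strength,
                                  obs$proposed_strength, character(), mech))
    }
    .decision(code, "rejected", NA, "unsupported_code", mech)
  })
  out <- dplyr::bind_rows(decisions)
  dplyr::arrange(out, .data$code)
}

#' Resolve mutual exclusivities between accepted evidence codes
#'
#' Enforces that two codes never double-count one evidence source:
#' PVS1 excludes PP3 (predicted null already implies the prediction);
#' PS3 excludes PP3 when the assay addressed the predicted mechanism;
#' PM1 and PP3 on the same motif evidence keep PM1; PM5 and PP3 on the
#' same prediction keep PM5. Dropped codes become `rejected` with the
#' exclusion rule recorded.
#'
#' @param decisions Decision tibble from [evaluate_evidence()].
#' @return Decision tibble with exclusions applied.
#' @export
resolve_exclusivities <- function(decisions) {
  live <- function(code) {
    i <- which(decisions$code == code)
    length(i) == 1 && decisions$outcome[i] != "rejected"
  }
  drop_pp3 <- function(reason) {
    i <- which(decisions$code == "PP3")
    decisions$outcome[i] <<- "rejected"
    decisions$final_strength[i] <<- NA_character_
    decisions$reasons[[i]] <<- c(decisions$reasons[[i]], reason)
  }
  mech_of <- function(code) {
    i <- which(decisions$code == code)
    decisions$mechanisms[[i]]
  }
  if (live("PP3")) {
    if (live("PVS1")) {
      drop_pp3("pvs1_pp3_exclusive")
    } else if (live("PS3") &&
               length(intersect(mech_of("PS3"), mech_of("PP3")))) {
      drop_pp3("ps3_assay_covers_predicted_mechanism")
    } else if (live("PM1") &&
               length(intersect(mech_of("PM1"), mech_of("PP3")))) {
      drop_pp3("pm1_pp3_same_motif_evidence")
    } else if (live("PM5") &&
               length(intersect(mech_of("PM5"), mech_of("PP3")))) {
      drop_pp3("pm5_pp3_same_prediction")
    }
  }
  decisions
}
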