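#' Classifier policy: combining mode, point values and tier cutoffs
#'
#' The categorical mode applies the standard ACMG/AMP combining table; the
#' point mode scores Supporting/Moderate/Strong/VeryStrong as 1/2/4/8
#' (benign-direction codes negative) with tiers Pathogenic >= 10, Likely
#' Pathogenic 6..9, VUS 0..5, Likely Benign -6..-1, Benign <= -7, following
#' current best-practice point scales. Conflicting pathogenic and benign
#' evidence resolves to VUS in categorical mode; BA1 outranks everything.
#'
#' @param mode `"categorical"` (default) or `"points"`.
#' @param point_values Named vector of points per strength.
#' @param conflict_rule Only `"conflict_to_vus"` is implemented.
#' @return Policy list of class `ncv_policy`.
#' @export
classifier_policy <- function(mode = c("categorical", "points"),
                              point_values = c(Supporting = 1, Moderate = 2,
                                               Strong = 4, VeryStrong = 8,
                                               StandAlone = 8),
                              conflict_rule = "conflict_to_vus") {
  mode <- match.arg(mode)
  stopifnot(identical(conflict_rule, "conflict_to_vus"))
  structure(list(mode = mode, point_values = point_values,
                 conflict_rule = conflict_rule),
            class = "ncv_policy")
}

.applied <- function(decisions) {
  decisions[decisions$outcome != "rejected", , drop = FALSE]
}

.strength_buckets <- function(decisions) {
  app <- .applied(decisions)
  pathogenic <- startsWith(app$code, "P")
  s <- app$final_strength
  list(
    pvs = sum(pathogenic & s == "VeryStrong"),
    ps = sum(pathogenic & s == "Strong"),
    pm = sum(pathogenic & s == "Moderate"),
    pp = sum(pathogenic & s == "Supporting"),
    ba = sum(!pathogenic & (s == "StandAlone" | app$code == "BA1")),
    bs = sum(!pathogenic & s == "Strong" & app$code != "BA1"),
    # the benign side has no Moderate bucket; a benign observation at
    # Moderate counts as Supporting categorically
    bp = sum(!pathogenic & s %in% c("Supporting", "Moderate") &
               app$code != "BA1")
  )
}

#' Combine final evidence decisions with the categorical table
#'
#' Applies the standard five-tier combining rules over the gated, final
#' decision set. Pathogenic requires one VeryStrong plus corroboration
#' (>=1 Strong, >=2 Moderate, 1 Moderate + 1 Supporting, or >=2
#' Supporting), >=2 Strong, or 1 Strong with >=3 Moderate / 2 Moderate +
#' >=2 Supporting / 1 Moderate + >=4 Supporting. Likely Pathogenic covers
#' its six combinations; Benign is BA1 or >=2 benign Strong; Likely Benign
#' is 1 benign Strong + 1 Supporting or >=2 benign Supporting. When both a
#' pathogenic-direction and a benign-direction rule fire, the verdict is
#' VUS (BA1 excepted, which outranks all other evidence).
#'
#' @param decisions Decision tibble after [resolve_exclusivities()].
#' @return One of `"Pathogenic"`, `"LikelyPathogenic"`, `"VUS"`,
#'   `"LikelyBenign"`, `"Benign"`.
#' @export
combine_categorical <- function(decisions) {
  b <- .strength_buckets(decisions)
  if (b$ba >= 1) return("Benign")
  path_tier <- if (
    (b$pvs >= 1 && (b$ps >= 1 || b$pm >= 2 ||
                      (b$pm >= 1 && b$pp >= 1) || b$pp >= 2)) ||
    b$pvs >= 2 ||
    b$ps >= 2 ||
    (b$ps == 1 && (b$pm >= 3 || (b$pm == 2 && b$pp >= 2) ||
                     (b$pm == 1 && b$pp >= 4)))
  ) "Pathogenic" else if (
    (b$pvs >= 1 && b$pm >= 1) ||
    (b$ps == 1 && b$pm >= 1 && b$pm <= 2) ||
    (b$ps == 1 && b$pp >= 2) ||
    b$pm >= 3 ||
    (b$pm == 2 && b$pp >= 2) ||
    (b$pm == 1 && b$pp >= 4)
  ) "LikelyPathogenic" else "VUS"
  benign_tier <- if (b$bs >= 2) "Benign"
  else if ((b$bs >= 1 && b$bp >= 1) || b$bp >= 2) "LikelyBenign"
  else "VUS"
  if (path_tier != "VUS" && benign_tier != "VUS") return("VUS")
  if (path_tier != "VUS") path_tier else benign_tier
}

#' Combine final evidence decisions on the point scale
#'
#' @param decisions Decision tibble after [resolve_exclusivities()].
#' @param policy Policy from [classifier_policy()].
#' @return List with `points` (signed integer sum) and `tier`.
#' @export
combine_points <- function(decisions, policy = classifier_policy()) {
  app <- .applied(decisions)
  if (any(app$code == "BA1")) {
    return(list(points = -sum(policy$point_values["StandAlone"]),
                tier = "Benign"))
  }
  sign <- ifelse(startsWith(app$code, "P"), 1, -1)
  pts <- sum(sign * policy$point_values[app$final_strength])
  if (length(pts) == 0 || is.na(pts)) pts <- 0
  tier <- if (pts >= 10) "Pathogenic"
  else if (pts >= 6) "LikelyPathogenic"
  else if (pts >= 0) "VUS"
  else if (pts >= -6) "LikelyBenign"
  else "Benign"
  list(points = pts, tier = tier)
}

#' Classify a variant from an evidence worksheet
#'
#' Full pipeline: gate every proposed code ([evaluate_evidence()]), resolve
#' mutual exclusivities ([resolve_exclusivities()]), then combine in both
#' categorical and point modes. The reported tier follows the policy's
#' mode; the other mode's verdict is retained for comparison. The
#' narrative lists every gate action with its rule ids.
#'
#' @param observations Observation tibble ([evidence_observation()] rows).
#' @param ctx Context from [evidence_context()].
#' @param policy Policy from [classifier_policy()].
#' @param config Threshold registry.
#' @return Object of class `ncv_classification`.
#' @export
classify_variant <- function(observations, ctx = evidence_context(),
                             policy = classifier_policy(),
                             config = threshold_config()) {
  decisions <- evaluate_evidence(observations, ctx, config)
  decisions <- resolve_exclusivities(decisions)
  cat_tier <- combine_categorical(decisions)
  pts <- combine_points(decisions, policy)
  tier <- if (policy$mode == "points") pts$tier else cat_tier
  narrative <- purrr::map_chr(seq_len(nrow(decisions)), function(i) {
    sprintf("%s: %s%s%s",
            decisions$code[i], decisions$outcome[i],
            ifelse(is.na(decisions$final_strength[i]), "",
                   paste0(" at ", decisions$final_strength[i])),
            ifelse(length(decisions$reasons[[i]]) == 0, "",
                   paste0(" [", paste(decisions$reasons[[i]],
                                      collapse = ", "), "]")))
  })
  structure(
    list(tier = tier, categorical_tier = cat_tier,
         points = pts$points, points_tier = pts$tier,
         decisions = decisions, applied = .applied(decisions),
         policy = policy, context = ctx, narrative = narrative),
    class = "ncv_classification"
  )
}

#' @export
print.ncv_classification <- function(x, ...) {
  cat("Non-coding variant classification\n")
  cat("  Tier:", x$tier,
      sprintf("(categorical: %s; points: %+d -> %s)\n",
              x$categorical_tier, x$points, x$points_tier))
  app <- x$applied
  if (nrow(app)) {
    cat("  Applied:",
        paste(sprintf("%s_%s", app$code, app$final_strength),
              collapse = ", "), "\n")
  } else {
    cat("  Applied: none\n")
  }
  cat("  Gate trail:\n")
  for (line in x$narrative) cat("    -", line, "\n")
  invisible(x)
}

#' Tidy the per-code gate decisions of a classification
#'
#' @param x An `ncv_classification`.
#' @param ... Unused.
#' @return Tibble with one row per evidence code: outcome, final strength
#'   and collapsed rule-id reasons.
#' @export
tidy.ncv_classification <- function(x, ...) {
  d <- x$decisions
  tibble::tibble(
    code = d$code,
    outcome = d$outcome,
    final_strength = d$final_strength,
    reasons = purrr::map_chr(d$reasons, paste, collapse = ";")
  )
}

#' One-row summary of a classification
#'
#' @param x An `ncv_classification`.
#' @param ... Unused.
#' @return One-row tibble: tier, points, counts of applied and rejected
#'   codes.
#' @export
glance.ncv_classification <- function(x, ...) {
  tibble::tibble(
    tier = x$tier,
    categorical_tier = x$categorical_tier,
    points = x$points,
    points_tier = x$points_tier,
    n_applied = nrow(x$applied),
    n_rejected = sum(x$decisions$outcome == "rejected")
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
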