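#' Read a trio VCF into a wide genotype table
#'
#' Expects a multi-sample VCF with GT and AD FORMAT fields for the proband
#' and both parents. Multi-allelic records are split; INFO keys are
#' extracted as columns.
#'
#' @param path Path to the trio VCF.
#' @param proband,father,mother Sample names in the VCF.
#' @param info_keys INFO keys to extract (e.g. allele frequencies,
#'   `LOF`, `SPLICE`, `GENE`).
#' @return Tibble with variant columns plus `gt_proband`, `gt_father`,
#'   `gt_mother`, `ad_proband` and the INFO columns.
#' @export
read_trio_vcf <- function(path, proband = "PROBAND", father = "FATHER",
                          mother = "MOTHER", info_keys = character()) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- vcfR::extract.gt(v, element = "AD")
  missing <- setdiff(c(proband, father, mother), colnames(gt))
  if (length(missing)) {
    stop("samples absent from VCF: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  out <- tibble::tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    id = as.character(ifelse(is.na(fix$ID) | fix$ID == ".", NA_character_, fix$ID)),
    ref = fix$REF,
    alt = fix$ALT,
    gt_proband = unname(gt[, proband]),
    gt_father = unname(gt[, father]),
    gt_mother = unname(gt[, mother]),
    ad_proband = unname(ad[, proband])
  )
  for (key in info_keys) {
    raw <- unname(vcfR::extract.info(v, element = key))
    suppressWarnings(num <- as.numeric(raw))
    out[[key]] <- if (all(is.na(num) == is.na(raw))) num else raw
  }
  out
}

.alt_count <- function(gt) {
  # diploid GT string -> number of alt alleles; NA for missing/other ploidy
  alleles <- strsplit(ifelse(is.na(gt), "./.", gt), "[/|]")
  vapply(alleles, function(a) {
    if (length(a) != 2 || any(a == ".")) return(NA_integer_)
    sum(a != "0")
  }, integer(1))
}

.alt_balance <- function(ad) {
  parts <- strsplit(ifelse(is.na(ad), "", ad), ",")
  vapply(parts, function(p) {
    if (length(p) < 2) return(NA_real_)
    d <- suppressWarnings(as.numeric(p))
    if (any(is.na(d)) || sum(d) == 0) return(NA_real_)
    d[2] / sum(d)
  }, numeric(1))
}

# Which parent certainly transmitted the alt allele of a proband-het call?
# "paternal"/"maternal" when unambiguous, "ambiguous" when both parents
# could have, "none" for apparent de novo, NA for non-het proband.
.transmitting_parent <- function(gt_p, gt_f, gt_m) {
  cp <- .alt_count(gt_p); cf <- .alt_count(gt_f); cm <- .alt_count(gt_m)
  out <- rep(NA_character_, length(cp))
  het <- !is.na(cp) & cp == 1L & !is.na(cf) & !is.na(cm)
  out[het & cf == 0L & cm == 0L] <- "none"
  out[het & (cf == 2L | (cf > 0L & cm == 0L))] <- "paternal"
  out[het & (cm == 2L | (cm > 0L & cf == 0L))] <- "maternal"
  out[het & is.na(out)] <- "ambiguous"
  out
}

#' Phase two heterozygous variants by trio transmission
#'
#' `in_trans` when the two variants were certainly transmitted by
#' different parents, `in_cis` when certainly by the same parent, and
#' `unknown` for apparent de novo occurrences, ambiguous configurations
#' (both parents carry an allele), Mendelian inconsistency, or non-diploid
#' / non-heterozygous genotypes.
#'
#' @param gt1,gt2 Length-3 character vectors of GT strings in the order
#'   (proband, father, mother).
#' @return `"in_trans"`, `"in_cis"` or `"unknown"`.
#' @export
phase_by_transmission <- function(gt1, gt2) {
  t1 <- .transmitting_parent(gt1[1], gt1[2], gt1[3])
  t2 <- .transmitting_parent(gt2[1], gt2[2], gt2[3])
  definite <- c("paternal", "maternal")
  if (is.na(t1) || is.na(t2) ||
      !(t1 %in% definite) || !(t2 %in% definite)) {
    return("unknown")
  }
  if (t1 == t2) "in_cis" else "in_trans"
}

#' Find proband genes with a single heterozygous high-confidence pLoF
#'
#' Implements the pairing step of the in-trans scan: keep (proband, gene)
#' pairs where the proband carries exactly one heterozygous
#' high-confidence predicted loss-of-function variant in a biallelic-LoF
#' gene, rare in every available AF source, with alt-read balance inside
#' the confident-het window. Genes with two or more passing pLoFs are
#' excluded (possible compound heterozygosity already).
#'
#' @param trio Tibble from [read_trio_vcf()] (or equivalent) with a
#'   `gene_id` column, a `lof_class` column (`"HC"` marks high
#'   confidence), and AF columns named in `af_keys`.
#' @param gene_list Character vector of biallelic-LoF gene ids.
#' @param af_keys Column names holding allele frequencies; a variant must
#'   be below `config$af_max` in every non-missing source (strict AND).
#'   Set `af_rule = "any"` for the permissive reading.
#' @param config Threshold registry.
#' @param af_rule `"all"` (default) or `"any"`.
#' @return Tibble of pairs: `gene_id`, pLoF variant columns, and
#'   `plof_parent` (transmitting parent).
#' @export
find_plof_pairs <- function(trio, gene_list, af_keys = "af_gnomad",
                            config = threshold_config(),
                            af_rule = c("all", "any")) {
  af_rule <- match.arg(af_rule)
  cand <- trio[!is.na(trio$lof_class) & trio$lof_class == "HC" &
                 trio$gene_id %in% gene_list, , drop = FALSE]
  if (nrow(cand) == 0) return(cand)
  het <- .alt_count(cand$gt_proband) == 1L
  bal <- .alt_balance(cand$ad_proband)
  bal_ok <- !is.na(bal) & bal > config$balance_lo & bal < config$balance_hi
  af_ok <- .af_pass(cand, af_keys, config$af_max, af_rule)
  cand <- cand[!is.na(het) & het & bal_ok & af_ok, , drop = FALSE]
  if (nrow(cand) == 0) return(cand)
  counts <- table(cand$gene_id)
  keep <- names(counts)[counts == 1L]  # a single het pLoF per gene
  cand <- cand[cand$gene_id %in% keep, , drop = FALSE]
  cand$plof_parent <- .transmitting_parent(cand$gt_proband, cand$gt_father,
                                           cand$gt_mother)
  cand
}

.af_pass <- function(x, af_keys, af_max, af_rule) {
  af_keys <- intersect(af_keys, names(x))
  if (length(af_keys) == 0) return(rep(TRUE, nrow(x)))
  mat <- vapply(af_keys, function(k) as.numeric(x[[k]]),
                numeric(nrow(x)))
  mat <- matrix(mat, nrow = nrow(x))
  pass <- mat < af_max
  if (af_rule == "all") {
    apply(pass, 1, function(p) all(p[!is.na(p)]) || all(is.na(p)))
  } else {
    apply(pass, 1, function(p) any(p[!is.na(p)]) || all(is.na(p)))
  }
}

#' Filtering allele frequency
#'
#' The conservative rarity filter for Mendelian disease: the lower bound
#' of the one-sided 95% confidence interval of the population allele
#' frequency given an allele count and number. With `ac = 0` the filtering
#' AF is 0.
#'
#' @param ac Allele counts.
#' @param an Allele numbers.
#' @return Numeric vector of filtering allele frequencies.
#' @export
filtering_af <- function(ac, an) {
  ifelse(ac == 0, 0, stats::qbeta(0.05, ac, an - ac + 1))
}

#' Scan for rare non-coding variants in trans with a pLoF allele
#'
#' For each (proband, gene) pair from [find_plof_pairs()], finds variants
#' in the gene's non-coding regions (introns, UTRs, core promoter) that
#' were transmitted by the alternative parent to the pLoF, have filtering
#' allele frequency below the rare ceiling and no observed homozygotes.
#' With `apply_splice_filter`, intronic candidates additionally require a
#' splice-impact score at or above the permissive threshold; UTR and
#' promoter candidates are unaffected.
#'
#' @param pairs Tibble from [find_plof_pairs()].
#' @param trio Full trio variant tibble (the search space).
#' @param regions Region tibble built in `core200` promoter mode.
#' @param config Threshold registry.
#' @param apply_splice_filter Apply the intronic splice-score filter?
#' @param splice_key Column holding the splice-impact score.
#' @param faf_key Column holding a precomputed filtering AF; when absent,
#'   `ac`/`an` columns are used via [filtering_af()], else the first
#'   `af_keys` column as a point estimate.
#' @param af_keys Fallback AF columns.
#' @param hom_key Column holding observed homozygote counts (absent
#'   column means zero).
#' @return `pairs` with a `candidates` list-column and `n_candidates`.
#' @export
scan_in_trans_noncoding <- function(pairs, trio, regions,
                                    config = threshold_config(),
                                    apply_splice_filter = TRUE,
                                    splice_key = "splice_score",
                                    faf_key = "faf",
                                    af_keys = "af_gnomad",
                                    hom_key = "nhomalt") {
  noncoding <- c("intron", "five_prime_utr", "three_prime_utr", "promoter")
  reg <- regions[regions$region_class %in% noncoding, , drop = FALSE]
  anchor0 <- to_internal(variant_anchor(trio$pos, trio$ref, trio$alt))
  faf <- if (faf_key %in% names(trio)) {
    as.numeric(trio[[faf_key]])
  } else if (all(c("ac", "an") %in% names(trio))) {
    filtering_af(trio$ac, trio$an)
  } else if (length(intersect(af_keys, names(trio)))) {
    as.numeric(trio[[intersect(af_keys, names(trio))[1]]])
  } else {
    rep(0, nrow(trio))
  }
  nhom <- if (hom_key %in% names(trio)) {
    tidyr::replace_na(as.numeric(trio[[hom_key]]), 0)
  } else {
    rep(0, nrow(trio))
  }
  results <- purrr::map(seq_len(nrow(pairs)), function(i) {
    pair <- pairs[i, , drop = FALSE]
    greg <- reg[reg$gene_id == pair$gene_id, , drop = FALSE]
    hit_class <- rep(NA_character_, nrow(trio))
    for (j in seq_len(nrow(greg))) {
      inside <- trio$chrom == greg$chrom[j] &
        anchor0 >= greg$start[j] & anchor0 < greg$end[j]
      hit_class[inside & is.na(hit_class)] <- greg$region_class[j]
    }
    idx <- which(!is.na(hit_class) &
                   !(trio$chrom == pair$chrom & trio$pos == pair$pos &
                       trio$alt == pair$alt))
    cand <- trio[idx, , drop = FALSE]
    cand$region_class <- hit_class[idx]
    cand$faf <- faf[idx]
    cand$nhomalt <- nhom[idx]
    phase <- vapply(seq_len(nrow(cand)), function(k) {
      phase_by_transmission(
        c(pair$gt_proband, pair$gt_father, pair$gt_mother),
        c(cand$gt_proband[k], cand$gt_father[k], cand$gt_mother[k])
      )
    }, character(1))
    keep <- phase == "in_trans" & cand$faf < config$af_max &
      cand$nhomalt == 0
    if (apply_splice_filter) {
      score <- if (splice_key %in% names(cand)) {
        as.numeric(cand[[splice_key]])
      } else {
        rep(NA_real_, nrow(cand))
      }
      intronic <- cand$region_class == "intron"
      keep <- keep & (!intronic |
                        (!is.na(score) & score >= config$splice_score_min))
    }
    cand[keep, , drop = FALSE]
  })
  pairs$candidates <- results
  pairs$n_candidates <- purrr::map_int(results, nrow)
  pairs
}

#' Summarise an in-trans scan across sample-pLoF pairs
#'
#' @param pairs Output of [scan_in_trans_noncoding()].
#' @param config Threshold registry (for the splice threshold used in the
#'   intronic-passing count).
#' @return Object of class `ncv_scan_summary`: overall counts (pairs,
#'   pairs with a candidate, fraction, mean and max candidates per pair)
#'   and a per-region breakdown.
#' @export
summarize_scan <- function(pairs, config = threshold_config()) {
  n_pairs <- nrow(pairs)
  if (n_pairs == 0 || !"candidates" %in% names(pairs)) {
    overall <- tibble::tibble(
      n_pairs = 0L, n_pairs_with_candidate = 0L,
      fraction_with_candidate = 0, mean_candidates_per_pair = 0,
      max_per_pair = 0L, n_intronic_passing_splice_filter = 0L
    )
    per_region <- tibble::tibble(region_class = character(),
                                 n_candidates = integer())
    return(structure(list(overall = overall, per_region = per_region),
                     class = "ncv_scan_summary"))
  }
  counts <- pairs$n_candidates
  all_cand <- dplyr::bind_rows(pairs$candidates)
  per_region <- if (nrow(all_cand)) {
    dplyr::count(all_cand, .data$region_class, name = "n_candidates")
  } else {
    tibble::tibble(region_class = character(), n_candidates = integer())
  }
  n_intronic_pass <- if (nrow(all_cand) &&
                           "splice_score" %in% names(all_cand)) {
    sum(all_cand$region_class == "intron" &
          !is.na(all_cand$splice_score) &
          all_cand$splice_score >= config$splice_score_min)
  } else 0L
  overall <- tibble::tibble(
    n_pairs = n_pairs,
    n_pairs_with_candidate = sum(counts > 0),
    fraction_with_candidate = mean(counts > 0),
    mean_candidates_per_pair = mean(counts),
    max_per_pair = max(counts),
    n_intronic_passing_splice_filter = as.integer(n_intronic_pass)
  )
  structure(list(overall = overall, per_region = per_region),
            class = "ncv_scan_summary")
}

#' @export
print.ncv_scan_summary <- function(x, ...) {
  cat("In-trans non-coding scan summary\n")
  o <- x$overall
  cat(sprintf("  %d sample-pLoF pairs; %d (%.1f%%) with >=1 candidate\n",
              o$n_pairs, o$n_pairs_with_candidate,
              100 * o$fraction_with_candidate))
  cat(sprintf("  mean %.3f candidates/pair (max %d)\n",
              o$mean_candidates_per_pair, o$max_per_pair))
  if (nrow(x$per_region)) {
    for (i in seq_len(nrow(x$per_region))) {
      cat(sprintf("    %s: %d\n", x$per_region$region_class[i],
                  x$per_region$n_candidates[i]))
    }
  }
  invisible(x)
}

#' @export
tidy.ncv_scan_summary <- function(x, ...) x$overall
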