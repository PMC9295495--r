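#' Read a ClinVar-style VCF
#'
#' Parses records with `CLNSIG` and `CLNREVSTAT` INFO keys, preserving the
#' raw strings verbatim; records missing either key are kept with an
#' empty string.
#'
#' @param path Path to the VCF.
#' @return Tibble with `chrom`, `pos`, `id`, `ref`, `alt`, `clnsig`,
#'   `clnrevstat`.
#' @export
read_clinvar <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  sig <- unname(vcfR::extract.info(v, element = "CLNSIG"))
  rev <- unname(vcfR::extract.info(v, element = "CLNREVSTAT"))
  tibble::tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    id = as.character(ifelse(is.na(fix$ID) | fix$ID == ".", NA_character_, fix$ID)),
    ref = fix$REF,
    alt = fix$ALT,
    clnsig = tidyr::replace_na(sig, ""),
    clnrevstat = tidyr::replace_na(rev, "")
  )
}

.hc_review_statuses <- c(
  "criteria_provided,_multiple_submitters,_no_conflicts",
  "reviewed_by_expert_panel",
  "practice_guideline"
)

.pathogenic_significances <- c(
  "Pathogenic", "Likely_pathogenic", "Pathogenic/Likely_pathogenic"
)

# primary CLNSIG term: everything before any comma-delimited modifier
.primary_sig <- function(clnsig) sub(",.*$", "", clnsig)

#' Is a record a high-confidence pathogenic variant?
#'
#' True only for records whose review status is multiple submitters with
#' no conflicts, expert-panel reviewed, or practice guideline, AND whose
#' primary significance is Pathogenic, Likely_pathogenic, or
#' Pathogenic/Likely_pathogenic.
#'
#' @param clnsig,clnrevstat Raw CLNSIG / CLNREVSTAT strings.
#' @return Logical vector.
#' @export
is_high_confidence_pathogenic <- function(clnsig, clnrevstat) {
  clnrevstat %in% .hc_review_statuses &
    .primary_sig(clnsig) %in% .pathogenic_significances
}

.sig_class <- function(clnsig) {
  p <- .primary_sig(clnsig)
  dplyr::case_when(
    p %in% .pathogenic_significances ~ "P/LP",
    p %in% c("Benign", "Likely_benign", "Benign/Likely_benign") ~ "B/LB",
    p == "Uncertain_significance" ~ "VUS",
    TRUE ~ "other"
  )
}

#' Categorize variants by genomic region against clinical transcripts
#'
#' Assigns each variant exactly one of `coding`, `five_prime_utr`,
#' `three_prime_utr`, `intron`, `promoter2kb` (within 2 kb upstream of the
#' TSS) or `other`, evaluated across all overlapping MANE-Select
#' transcripts with precedence coding > 5'UTR > 3'UTR > intron >
#' promoter2kb. Variants touching no MANE-Select transcript (nor its 2-kb
#' upstream window) are `other`; indels are localised by the leftmost
#' altered base of their normalized representation.
#'
#' @param variants Variant tibble (`chrom`, `pos`, `ref`, `alt`).
#' @param transcripts Transcript tibble; only `MANE_Select` rows are used.
#' @param config Threshold registry (for the 2-kb window size).
#' @return The input tibble with a `category` column.
#' @export
categorize_variants <- function(variants, transcripts,
                                config = threshold_config()) {
  mane <- transcripts[transcripts$provenance == "MANE_Select", , drop = FALSE]
  regions <- derive_gene_regions(mane, promoter_mode = "audit2kb",
                                 config = config)
  class_map <- c(coding = 1L, five_prime_utr = 2L, three_prime_utr = 3L,
                 intron = 4L, promoter = 5L)
  anchor0 <- to_internal(variant_anchor(variants$pos, variants$ref,
                                        variants$alt))
  best <- rep(NA_integer_, nrow(variants))
  for (j in seq_len(nrow(regions))) {
    rank <- class_map[[regions$region_class[j]]]
    inside <- variants$chrom == regions$chrom[j] &
      anchor0 >= regions$start[j] & anchor0 < regions$end[j]
    improve <- inside & (is.na(best) | rank < best)
    best[improve] <- rank
  }
  labels <- c("coding", "five_prime_utr", "three_prime_utr", "intron",
              "promoter2kb")
  variants$category <- ifelse(is.na(best), "other", labels[best])
  variants
}

#' Census of a categorized ClinVar-style call set
#'
#' Tabulates variant counts, significance classes and high-confidence
#' pathogenic counts by region category, with the derived proportions the
#' under-ascertainment analysis reports: the per-category VUS rate and the
#' share of high-confidence pathogenic variants falling in UTRs or the
#' 2-kb upstream window.
#'
#' @param records Categorized ClinVar tibble ([categorize_variants()]
#'   output with `clnsig`, `clnrevstat`).
#' @return Object of class `ncv_audit` with `by_category` and `overall`
#'   tibbles.
#' @export
audit_summary <- function(records) {
  records$sig_class <- .sig_class(records$clnsig)
  records$hc_pathogenic <- is_high_confidence_pathogenic(records$clnsig,
                                                         records$clnrevstat)
  cats <- c("coding", "five_prime_utr", "three_prime_utr", "intron",
            "promoter2kb", "other")
  by_category <- records |>
    dplyr::mutate(category = factor(.data$category, levels = cats)) |>
    dplyr::group_by(.data$category, .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_plp = sum(.data$sig_class == "P/LP"),
      n_blb = sum(.data$sig_class == "B/LB"),
      n_vus = sum(.data$sig_class == "VUS"),
      n_hc_pathogenic = sum(.data$hc_pathogenic),
      vus_rate = ifelse(dplyr::n() > 0,
                        sum(.data$sig_class == "VUS") / dplyr::n(), NA_real_),
      .groups = "drop"
    ) |>
    dplyr::mutate(category = as.character(.data$category))
  upstream_cats <- c("five_prime_utr", "three_prime_utr", "promoter2kb")
  n_hc <- sum(records$hc_pathogenic)
  n_hc_regulatory <- sum(records$hc_pathogenic &
                           records$category %in% upstream_cats)
  overall <- tibble::tibble(
    n_records = nrow(records),
    n_hc_pathogenic = n_hc,
    n_hc_pathogenic_utr_promoter = n_hc_regulatory,
    prop_hc_pathogenic_utr_promoter = ifelse(n_hc > 0,
                                             n_hc_regulatory / n_hc,
                                             NA_real_)
  )
  stopifnot(sum(by_category$n) == nrow(records))
  structure(list(by_category = by_category, overall = overall),
            class = "ncv_audit")
}

#' @export
print.ncv_audit <- function(x, ...) {
  cat("ClinVar-style region census\n")
  print(x$by_category)
  o <- x$overall
  if (!is.na(o$prop_hc_pathogenic_utr_promoter)) {
    cat(sprintf(
      "  %d/%d (%.2f%%) high-confidence pathogenic in UTR/upstream regions\n",
      o$n_hc_pathogenic_utr_promoter, o$n_hc_pathogenic,
      100 * o$prop_hc_pathogenic_utr_promoter))
  }
  invisible(x)
}

#' @export
tidy.ncv_audit <- function(x, ...) x$by_category

#' Spliced region-length statistics across transcripts
#'
#' Per-transcript spliced lengths of the 5'UTR, CDS and 3'UTR (sums of
#' exonic fragments), total intron length, and cohort means rounded to the
#' nearest bp. Per transcript, UTRs + CDS + introns always equal the
#' transcript span. UTR/CDS means are computed over coding transcripts.
#'
#' @param transcripts Transcript tibble.
#' @return Object of class `ncv_footprint` with `per_transcript` and
#'   `means` tibbles.
#' @export
region_footprint_stats <- function(transcripts) {
  per <- purrr::map(seq_len(nrow(transcripts)), function(i) {
    tx <- transcripts[i, , drop = FALSE]
    ex <- tx$exons[[1]]
    span <- tx$tx_end - tx$tx_start
    exonic <- sum(ex$end - ex$start)
    intron_total <- span - exonic
    if (is.na(tx$cds_start)) {
      return(tibble::tibble(
        transcript_id = tx$transcript_id, gene_id = tx$gene_id,
        coding = FALSE, five_prime_utr_bp = NA_integer_,
        cds_bp = NA_integer_, three_prime_utr_bp = NA_integer_,
        intron_total_bp = as.integer(intron_total),
        span_bp = as.integer(span)
      ))
    }
    cs <- tx$cds_start; ce <- tx$cds_end
    olap <- function(a, b) pmax(0L, pmin(ex$end, b) - pmax(ex$start, a))
    left <- sum(olap(tx$tx_start, cs))
    cds <- sum(olap(cs, ce))
    right <- sum(olap(ce, tx$tx_end))
    utr5 <- if (tx$strand == "+") left else right
    utr3 <- if (tx$strand == "+") right else left
    tibble::tibble(
      transcript_id = tx$transcript_id, gene_id = tx$gene_id,
      coding = TRUE,
      five_prime_utr_bp = as.integer(utr5),
      cds_bp = as.integer(cds),
      three_prime_utr_bp = as.integer(utr3),
      intron_total_bp = as.integer(intron_total),
      span_bp = as.integer(span)
    )
  })
  per <- dplyr::bind_rows(per)
  coding <- per[per$coding, , drop = FALSE]
  means <- tibble::tibble(
    five_prime_utr_bp = round(mean(coding$five_prime_utr_bp)),
    cds_bp = round(mean(coding$cds_bp)),
    three_prime_utr_bp = round(mean(coding$three_prime_utr_bp)),
    intron_total_bp = round(mean(per$intron_total_bp)),
    n_coding_transcripts = nrow(coding),
    n_transcripts = nrow(per)
  )
  total <- sum(means$five_prime_utr_bp, means$cds_bp,
               means$three_prime_utr_bp, means$intron_total_bp)
  means$share_intronic <- means$intron_total_bp / total
  structure(list(per_transcript = per, means = means),
            class = "ncv_footprint")
}

#' @export
print.ncv_footprint <- function(x, ...) {
  m <- x$means
  cat("Mean spliced region lengths (bp):\n")
  cat(sprintf("  5'UTR %d | CDS %d | 3'UTR %d | introns %d (%.1f%% of footprint)\n",
              m$five_prime_utr_bp, m$cds_bp, m$three_prime_utr_bp,
              m$intron_total_bp, 100 * m$share_intronic))
  invisible(x)
}

#' @export
tidy.ncv_footprint <- function(x, ...) x$per_transcript
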