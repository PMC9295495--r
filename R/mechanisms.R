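#' Mechanism taxonomy for non-coding region variants
#'
#' A machine-readable table of documented mechanisms through which small
#' non-coding variants cause penetrant disease, keyed by region class,
#' with the matching VEP consequence categories, the class of in-silico
#' predictor applicable (if any), and a literature exemplar.
#'
#' @return Tibble with columns `region_class`, `mechanism`,
#'   `vep_categories`, `predictor_class`, `exemplar`.
#' @export
mechanism_taxonomy <- function() {
  path <- system.file("extdata", "mechanism_taxonomy.tsv", package = "ncvint")
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Classify the splice context of variants relative to a transcript
#'
#' Offsets are computed in transcript orientation. Canonical donor/acceptor
#' are the first/last two intronic bases; `donor_plus5` the fifth intronic
#' base of a donor (elevated prior of splice disruption); `splice_region`
#' covers intronic offsets 3-8 from either junction (excluding the above)
#' and exonic offsets 1-3 from a junction; remaining intronic positions are
#' `deep_intronic`; everything else is `none`.
#'
#' @param variants Variant tibble (`chrom`, `pos`, `ref`, `alt`).
#' @param tx A single transcript row.
#' @return Tibble with `class`, `distance_to_junction`, `intron_index`, one
#'   row per variant.
#' @export
classify_splice_context <- function(variants, tx) {
  anchor0 <- to_internal(variant_anchor(variants$pos, variants$ref,
                                        variants$alt))
  ex <- tx$exons[[1]]
  n_introns <- nrow(ex) - 1L
  rows <- purrr::map(anchor0, function(b) {
    .splice_context_one(b, ex, tx$strand, n_introns)
  })
  out <- dplyr::bind_rows(rows)
  out$class[variants$chrom != tx$chrom] <- "none"
  out
}

.splice_context_one <- function(b, ex, strand, n_introns) {
  none <- tibble::tibble(class = "none",
                         distance_to_junction = NA_integer_,
                         intron_index = NA_integer_)
  if (b < min(ex$start) || b >= max(ex$end)) return(none)
  in_exon <- any(ex$start <= b & b < ex$end)
  if (in_exon) {
    # exonic distance to the nearest junction that abuts an intron
    dists <- integer()
    for (j in seq_len(nrow(ex))) {
      if (ex$start[j] <= b && b < ex$end[j]) {
        if (j > 1) dists <- c(dists, b - ex$start[j] + 1L)        # after acceptor
        if (j < nrow(ex)) dists <- c(dists, ex$end[j] - b)        # before donor
      }
    }
    if (length(dists) && min(dists) <= 3L) {
      return(tibble::tibble(class = "splice_region",
                            distance_to_junction = min(dists),
                            intron_index = NA_integer_))
    }
    return(none)
  }
  # intronic: find the gap
  gaps <- tibble::tibble(start = ex$end[-nrow(ex)], end = ex$start[-1])
  j <- which(gaps$start <= b & b < gaps$end)
  left_off <- b - gaps$start[j] + 1L   # bases from the genomic-left junction
  right_off <- gaps$end[j] - b         # bases from the genomic-right junction
  if (strand == "+") {
    donor_off <- left_off; acceptor_off <- right_off; idx <- j
  } else {
    donor_off <- right_off; acceptor_off <- left_off
    idx <- n_introns - j + 1L
  }
  dist <- min(donor_off, acceptor_off)
  class <- if (donor_off <= 2L) "canonical_donor"
  else if (acceptor_off <= 2L) "canonical_acceptor"
  else if (donor_off == 5L) "donor_plus5"
  else if (donor_off <= 8L || acceptor_off <= 8L) "splice_region"
  else "deep_intronic"
  tibble::tibble(class = class, distance_to_junction = as.integer(dist),
                 intron_index = as.integer(idx))
}

#' Scan for upstream start-codon (uAUG) creation by a 5'UTR variant
#'
#' Applies the alternate allele to the 5'UTR-containing transcript sequence
#' and checks the three reading windows covering the edit for a newly
#' created ATG. A created uAUG is classified by its downstream open reading
#' frame: a stop codon wholly upstream of the CDS start gives a `uORF`;
#' no upstream in-frame stop gives `cds_elongation` when the uAUG is in
#' frame with the CDS and `overlapping_oORF` otherwise. Kozak strength is
#' assessed at positions -3 (A/G) and +4 (G): both matching is `strong`,
#' one is `moderate`, neither `weak`.
#'
#' @param utr_seq Transcript-orientation sequence starting at the TSS and
#'   extending through (at least) the CDS start codon.
#' @param var_offset 0-based offset of the variant in `utr_seq`.
#' @param ref,alt Alleles in transcript orientation.
#' @param cds_start_offset 0-based offset of the A of the canonical ATG.
#' @return One-row tibble: `creates_uaug`, `uaug_offset`, `frame`
#'   (`in_frame`/`out_of_frame`), `orf_type` (`uORF`, `overlapping_oORF`,
#'   `cds_elongation`, `none`), `kozak`.
#' @export
scan_uaug <- function(utr_seq, var_offset, ref, alt, cds_start_offset) {
  utr_seq <- toupper(utr_seq)
  ref <- toupper(ref); alt <- toupper(alt)
  stopifnot(substr(utr_seq, var_offset + 1L, var_offset + nchar(ref)) == ref)
  alt_seq <- paste0(
    substr(utr_seq, 1L, var_offset),
    alt,
    substr(utr_seq, var_offset + nchar(ref) + 1L, nchar(utr_seq))
  )
  shift <- nchar(alt) - nchar(ref)
  cds_alt <- cds_start_offset +
    if (var_offset < cds_start_offset) shift else 0L
  none <- tibble::tibble(creates_uaug = FALSE, uaug_offset = NA_integer_,
                         frame = NA_character_, orf_type = "none",
                         kozak = NA_character_)
  # windows covering any edited base
  edit_lo <- var_offset - 2L
  edit_hi <- var_offset + nchar(alt) - 1L
  codon_at <- function(s, w) substr(s, w + 1L, w + 3L)
  hit <- NA_integer_
  for (w in seq(max(0L, edit_lo), edit_hi)) {
    if (w + 3L > nchar(alt_seq) || w >= cds_alt) next
    created <- codon_at(alt_seq, w) == "ATG"
    # the same genomic window in the reference (only defined for SNVs;
    # for indels any ATG spanning the edit counts as created)
    was_atg <- shift == 0L && codon_at(utr_seq, w) == "ATG"
    if (created && !was_atg) { hit <- w; break }
  }
  if (is.na(hit)) return(none)
  frame <- if ((cds_alt - hit) %% 3L == 0L) "in_frame" else "out_of_frame"
  # scan codons downstream of the created ATG for an upstream stop
  stops <- c("TAA", "TAG", "TGA")
  orf_type <- NULL
  w <- hit + 3L
  while (w + 3L <= cds_alt) {
    if (codon_at(alt_seq, w) %in% stops) { orf_type <- "uORF"; break }
    w <- w + 3L
  }
  if (is.null(orf_type)) {
    orf_type <- if (frame == "in_frame") "cds_elongation" else "overlapping_oORF"
  }
  minus3 <- if (hit >= 3L) substr(alt_seq, hit - 2L, hit - 2L) else ""
  plus4 <- if (hit + 4L <= nchar(alt_seq)) {
    substr(alt_seq, hit + 4L, hit + 4L)
  } else ""
  n_match <- (minus3 %in% c("A", "G")) + (plus4 == "G")
  kozak <- c("weak", "moderate", "strong")[n_match + 1L]
  tibble::tibble(creates_uaug = TRUE, uaug_offset = as.integer(hit),
                 frame = frame, orf_type = orf_type, kozak = kozak)
}

#' Check whether a 3'UTR variant destroys a canonical polyadenylation motif
#'
#' True only when a hexamer window overlapping the variant reads AATAAA or
#' ATTAAA in the reference and the edited window is no longer either
#' canonical hexamer (converting one canonical motif into the other does
#' not count as disruption).
#'
#' @param utr3_seq 3'UTR sequence in transcript orientation.
#' @param var_offset 0-based offset of the variant in `utr3_seq`.
#' @param ref,alt Alleles in transcript orientation.
#' @return Logical scalar.
#' @export
check_polya_motif <- function(utr3_seq, var_offset, ref, alt) {
  utr3_seq <- toupper(utr3_seq)
  ref <- toupper(ref); alt <- toupper(alt)
  stopifnot(substr(utr3_seq, var_offset + 1L, var_offset + nchar(ref)) == ref)
  hexamers <- c("AATAAA", "ATTAAA")
  alt_seq <- paste0(
    substr(utr3_seq, 1L, var_offset),
    alt,
    substr(utr3_seq, var_offset + nchar(ref) + 1L, nchar(utr3_seq))
  )
  shift <- nchar(alt) - nchar(ref)
  for (w in seq(max(0L, var_offset - 5L), var_offset + nchar(ref) - 1L)) {
    ref_hex <- substr(utr3_seq, w + 1L, w + 6L)
    if (!ref_hex %in% hexamers) next
    alt_hex <- substr(alt_seq, w + 1L, w + 6L)
    if (!alt_hex %in% hexamers) return(TRUE)
  }
  FALSE
}

#' Rank candidate mechanisms for a region context
#'
#' Returns the taxonomy rows for the context's region class, promoted by
#' detector hits: a uAUG call ranks `uAUG_creation` (or
#' `n_terminal_elongation` for in-frame elongations) first, a canonical or
#' plus-5 splice context ranks `canonical_splice_disruption` first, and a
#' polyA-motif hit ranks `polyA_signal_disruption` first. Detector hits
#' order triage only; they never activate evidence codes by themselves.
#'
#' @param region_class One of the closed region vocabulary.
#' @param uorf_call Optional row from [scan_uaug()].
#' @param splice_context Optional row from [classify_splice_context()].
#' @param polya_hit Logical from [check_polya_motif()].
#' @return Tibble of taxonomy rows, most relevant first; empty (with a
#'   warning) for an unknown region class.
#' @export
candidate_mechanisms <- function(region_class, uorf_call = NULL,
                                 splice_context = NULL, polya_hit = FALSE) {
  tax <- mechanism_taxonomy()
  if (!region_class %in% tax$region_class) {
    warning("no mechanism taxonomy for region class: ", region_class)
    return(tax[0, , drop = FALSE])
  }
  rows <- tax[tax$region_class == region_class, , drop = FALSE]
  promote <- character()
  if (!is.null(uorf_call) && isTRUE(uorf_call$creates_uaug)) {
    promote <- c(promote,
                 if (identical(uorf_call$orf_type, "cds_elongation"))
                   "n_terminal_elongation" else "uAUG_creation")
  }
  if (!is.null(splice_context) &&
      splice_context$class %in% c("canonical_donor", "canonical_acceptor",
                                  "donor_plus5", "splice_region")) {
    promote <- c(promote, "canonical_splice_disruption",
                 "utr_splice_disruption", "utr3_splice_disruption")
  }
  if (isTRUE(polya_hit)) promote <- c(promote, "polyA_signal_disruption")
  rank <- match(rows$mechanism, promote)
  rows[order(is.na(rank), rank), , drop = FALSE]
}
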