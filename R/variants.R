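#' Normalize variant representations (left-align and trim)
#'
#' Reduces each record to its parsimonious, left-aligned representation:
#' shared trailing bases are trimmed (extending leftward through repeat
#' runs using the reference sequence), then shared leading bases are
#' trimmed. SNVs pass through unchanged. The operation is idempotent.
#'
#' @param variants Tibble with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`; other columns are carried through.
#' @param reference Named character vector or `Biostrings::DNAStringSet`
#'   of contig sequences.
#' @return The input tibble with `pos`, `ref`, `alt` normalized.
#' @export
normalize_variants <- function(variants, reference) {
  seqs <- .as_seq_list(reference)
  norm <- purrr::pmap(
    list(variants$chrom, variants$pos, variants$ref, variants$alt),
    function(chrom, pos, ref, alt) {
      seq <- seqs[[chrom]]
      if (is.null(seq)) stop("unknown contig: ", chrom, call. = FALSE)
      .normalize_one(seq, pos, ref, alt)
    }
  )
  variants$pos <- purrr::map_int(norm, "pos")
  variants$ref <- purrr::map_chr(norm, "ref")
  variants$alt <- purrr::map_chr(norm, "alt")
  variants
}

.as_seq_list <- function(reference) {
  if (inherits(reference, "DNAStringSet")) {
    reference <- stats::setNames(as.character(reference), names(reference))
  }
  as.list(reference)
}

.normalize_one <- function(seq, pos, ref, alt) {
  observed <- substr(seq, pos, pos + nchar(ref) - 1L)
  if (!identical(toupper(observed), toupper(ref))) {
    stop(sprintf("reference mismatch at pos %d: expected '%s', found '%s'",
                 pos, ref, observed), call. = FALSE)
  }
  if (identical(ref, alt)) stop("ref and alt are identical", call. = FALSE)
  # trim shared suffix, borrowing the preceding reference base when an
  # allele would empty out (classic left-alignment through repeat runs)
  repeat {
    lr <- nchar(ref); la <- nchar(alt)
    if (lr > 0 && la > 0 &&
        substr(ref, lr, lr) == substr(alt, la, la) &&
        (lr > 1 || la > 1)) {
      ref <- substr(ref, 1L, lr - 1L)
      alt <- substr(alt, 1L, la - 1L)
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        if (pos == 1L) {
          stop("cannot left-align at contig start", call. = FALSE)
        }
        pos <- pos - 1L
        base <- substr(seq, pos, pos)
        ref <- paste0(base, ref)
        alt <- paste0(base, alt)
      }
    } else {
      break
    }
  }
  # trim shared prefix while both alleles keep at least one base
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = ref, alt = alt)
}

#' Split multi-allelic records into biallelic records
#'
#' Every interpretation rule in the engine is per-allele, so comma-separated
#' ALT fields are exploded into one row per alternate allele before use.
#'
#' @param variants Tibble with an `alt` column possibly containing commas.
#' @return Tibble with one row per (site, alternate allele).
#' @export
split_multiallelic <- function(variants) {
  tidyr::separate_rows(variants, "alt", sep = ",")
}

#' Leftmost altered reference base of a normalized variant
#'
#' Deterministic single-base localisation used for region assignment:
#' an SNV sits at `pos`; a deletion's first deleted base is `pos + 1`
#' (the anchor base is unchanged); an insertion is anchored at `pos`.
#'
#' @param pos,ref,alt Vectors describing normalized variants.
#' @return Integer vector of 1-based positions.
#' @export
variant_anchor <- function(pos, ref, alt) {
  pos <- as.integer(pos)
  deletion_like <- nchar(ref) > 1L
  ifelse(deletion_like, pos + 1L, pos)
}

#' Read variant records from a VCF file
#'
#' Thin wrapper over `vcfR::read.vcfR()` returning a tibble of biallelic
#' records with requested INFO keys as columns (numeric where they parse).
#' Per-allele (Number=A) INFO values are matched to their allele on
#' multi-allelic split.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @param info_keys Character vector of INFO keys to extract.
#' @return Tibble with `chrom`, `pos`, `id`, `ref`, `alt` and INFO columns.
#' @export
read_vcf_variants <- function(path, info_keys = character()) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  out <- tibble::tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    id = as.character(ifelse(is.na(fix$ID) | fix$ID == ".", NA_character_, fix$ID)),
    ref = fix$REF,
    alt = fix$ALT
  )
  n_alt <- stringr::str_count(out$alt, ",") + 1L
  allele_index <- unlist(lapply(n_alt, seq_len))
  for (key in info_keys) {
    raw <- unname(vcfR::extract.info(v, element = key))
    out[[key]] <- raw
  }
  out <- tidyr::separate_rows(out, "alt", sep = ",")
  out$.allele <- allele_index
  for (key in info_keys) {
    vals <- out[[key]]
    per_allele <- stringr::str_count(vals, ",") + 1L
    multi <- !is.na(vals) & per_allele > 1L
    if (any(multi)) {
      vals[multi] <- purrr::map2_chr(
        strsplit(vals[multi], ","), out$.allele[multi],
        function(parts, i) if (i <= length(parts)) parts[[i]] else NA_character_
      )
    }
    suppressWarnings(num <- as.numeric(vals))
    out[[key]] <- if (all(is.na(num) == is.na(vals))) num else vals
  }
  out$.allele <- NULL
  out
}
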