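#' Convert 1-based genomic positions to 0-based internal offsets
#'
#' All interval arithmetic inside the package uses 0-based half-open
#' coordinates; VCF positions (1-based) and GFF3 coordinates (1-based
#' inclusive) are converted at the I/O boundary only.
#'
#' @param pos_1based Integer vector of 1-based positions (`pos >= 1`).
#' @return Integer vector of 0-based offsets.
#' @seealso [to_genomic()]
#' @export
#' @examples
#' to_internal(1)    # 0
#' to_internal(1000) # 999
to_internal <- function(pos_1based) {
  pos_1based <- as.integer(pos_1based)
  if (any(is.na(pos_1based)) || any(pos_1based < 1L)) {
    stop("positions must be integers >= 1", call. = FALSE)
  }
  pos_1based - 1L
}

#' Convert 0-based internal offsets back to 1-based genomic positions
#'
#' @param offset Integer vector of 0-based offsets (`offset >= 0`).
#' @return Integer vector of 1-based positions.
#' @export
to_genomic <- function(offset) {
  offset <- as.integer(offset)
  if (any(is.na(offset)) || any(offset < 0L)) {
    stop("offsets must be integers >= 0", call. = FALSE)
  }
  offset + 1L
}

#' Numeric thresholds used across the interpretation pipelines
#'
#' Central registry for every tunable constant: the rare-variant allele
#' frequency ceiling (0.5%), heterozygous read-balance window (25-75%),
#' permissive splice-score floor (0.2), the three promoter window sizes
#' (200 bp core upstream, 2 kb audit upstream, 250 bp up+down minimal),
#' and the small-variant size limit (indels < 50 bp).
#'
#' @param af_max Maximum allele frequency for a variant to count as rare.
#' @param balance_lo,balance_hi Open interval of acceptable alt-read
#'   fraction for a confident heterozygous call.
#' @param splice_score_min Permissive splice-impact score threshold applied
#'   to intronic in-trans candidates.
#' @param promoter_core_bp Core promoter: bases directly upstream of the TSS.
#' @param promoter_audit_bp Audit promoter: bases upstream of the TSS used
#'   for the region census.
#' @param promoter_minimal_bp Minimal promoter: bases immediately up- AND
#'   downstream of the TSS when no open-chromatin support exists.
#' @param indel_max_len Maximum indel length (exclusive) in scope.
#' @param pp4_max_genes Maximum number of genes associated with a phenotype
#'   for PP4 ("only, or one of very few genes").
#' @param pm3_large_intron_bp Total intronic span above which PM3 is
#'   downgraded one strength step.
#' @return A named list of class `ncv_thresholds`.
#' @export
threshold_config <- function(af_max = 0.005,
                             balance_lo = 0.25,
                             balance_hi = 0.75,
                             splice_score_min = 0.2,
                             promoter_core_bp = 200L,
                             promoter_audit_bp = 2000L,
                             promoter_minimal_bp = 250L,
                             indel_max_len = 50L,
                             pp4_max_genes = 3L,
                             pm3_large_intron_bp = 1e6) {
  stopifnot(
    af_max > 0, af_max < 1,
    balance_lo > 0, balance_lo < balance_hi, balance_hi < 1,
    splice_score_min >= 0,
    promoter_core_bp > 0, promoter_audit_bp > 0, promoter_minimal_bp > 0,
    indel_max_len > 0, pp4_max_genes >= 1, pm3_large_intron_bp > 0
  )
  structure(
    list(
      af_max = af_max,
      balance_lo = balance_lo,
      balance_hi = balance_hi,
      splice_score_min = splice_score_min,
      promoter_core_bp = as.integer(promoter_core_bp),
      promoter_audit_bp = as.integer(promoter_audit_bp),
      promoter_minimal_bp = as.integer(promoter_minimal_bp),
      indel_max_len = as.integer(indel_max_len),
      pp4_max_genes = as.integer(pp4_max_genes),
      pm3_large_intron_bp = pm3_large_intron_bp
    ),
    class = "ncv_thresholds"
  )
}

#' Harmonise contig-name dialects against a target naming style
#'
#' Variant sets and transcript sets frequently disagree on the "chr" prefix
#' ("chr17" vs "17"). This strips or adds the prefix so `chrom` matches the
#' style used by `target_chroms`.
#'
#' @param chrom Character vector of contig names to harmonise.
#' @param target_chroms Character vector exemplifying the target dialect.
#' @return `chrom` rewritten in the target dialect.
#' @export
harmonize_contigs <- function(chrom, target_chroms) {
  target_prefixed <- any(startsWith(target_chroms, "chr"))
  has_prefix <- startsWith(chrom, "chr")
  if (target_prefixed) {
    chrom[!has_prefix] <- paste0("chr", chrom[!has_prefix])
  } else {
    chrom[has_prefix] <- sub("^chr", "", chrom[has_prefix])
  }
  chrom
}

# Closed vocabulary of interpretable region classes.
region_classes <- function() {
  c("five_prime_utr", "three_prime_utr", "intron", "promoter", "cre",
    "coding", "other")
}
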