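#' Derive interpretable region sets for transcripts
#'
#' For every transcript, builds the genic tiling (5'UTR, coding exon parts,
#' 3'UTR, introns) plus a promoter in the requested mode. All intervals are
#' 0-based half-open and strand-aware: "upstream" means 5' of the TSS in
#' transcript orientation.
#'
#' Promoter modes:
#' \describe{
#'   \item{core200}{first 200 bp directly upstream of the TSS}
#'   \item{audit2kb}{2 kb directly upstream of the TSS}
#'   \item{minimal250}{250 bp immediately up- and downstream of the TSS}
#'   \item{epigenetic}{the union of open-chromatin peaks containing the
#'     TSS, falling back to minimal250 when no peak contains it}
#' }
#'
#' Introns between UTR exon fragments are classed `intron`, not UTR.
#' Non-coding transcripts yield introns (and promoter) only. Promoter
#' windows are clipped at contig edges when `contig_lengths` is given.
#'
#' @param transcripts Transcript tibble (see [read_transcripts()]).
#' @param promoter_mode One of `"core200"`, `"audit2kb"`, `"minimal250"`,
#'   `"epigenetic"`.
#' @param open_chromatin Optional tibble of peaks (`chrom`, `start`, `end`,
#'   0-based half-open) for `epigenetic` mode.
#' @param contig_lengths Optional named integer vector of contig lengths.
#' @param config Threshold registry from [threshold_config()].
#' @return Region tibble: `gene_id`, `transcript_id`, `chrom`, `strand`,
#'   `region_class`, `start`, `end`, `intron_index`, `promoter_mode`.
#' @export
derive_gene_regions <- function(transcripts,
                                promoter_mode = c("core200", "audit2kb",
                                                  "minimal250", "epigenetic"),
                                open_chromatin = NULL,
                                contig_lengths = NULL,
                                config = threshold_config()) {
  promoter_mode <- match.arg(promoter_mode)
  rows <- purrr::map(seq_len(nrow(transcripts)), function(i) {
    .regions_one(transcripts[i, , drop = FALSE], promoter_mode,
                 open_chromatin, contig_lengths, config)
  })
  dplyr::bind_rows(rows)
}

.regions_one <- function(tx, promoter_mode, open_chromatin, contig_lengths,
                         config) {
  ex <- tx$exons[[1]]
  strand <- tx$strand
  coding <- !is.na(tx$cds_start)
  pieces <- list()
  add <- function(class, start, end, intron_index = NA_integer_) {
    if (end > start) {
      pieces[[length(pieces) + 1L]] <<- tibble::tibble(
        region_class = class, start = as.integer(start),
        end = as.integer(end), intron_index = intron_index
      )
    }
  }
  if (coding) {
    cs <- tx$cds_start; ce <- tx$cds_end
    for (j in seq_len(nrow(ex))) {
      s <- ex$start[j]; e <- ex$end[j]
      left <- c(max(s, 0), min(e, cs))     # exon part genomically left of CDS
      mid <- c(max(s, cs), min(e, ce))
      right <- c(max(s, ce), min(e, tx$tx_end))
      left_class <- if (strand == "+") "five_prime_utr" else "three_prime_utr"
      right_class <- if (strand == "+") "three_prime_utr" else "five_prime_utr"
      add(left_class, left[1], left[2])
      add("coding", mid[1], mid[2])
      add(right_class, right[1], right[2])
    }
  }
  # introns: gaps between consecutive exons, indexed in transcript orientation
  if (nrow(ex) > 1) {
    gaps <- tibble::tibble(start = ex$end[-nrow(ex)], end = ex$start[-1])
    idx <- seq_len(nrow(gaps))
    if (strand == "-") idx <- rev(idx)
    for (j in seq_len(nrow(gaps))) {
      add("intron", gaps$start[j], gaps$end[j], intron_index = idx[j])
    }
  }
  prom <- .promoter_interval(tx, promoter_mode, open_chromatin, config)
  if (!is.null(contig_lengths) && tx$chrom %in% names(contig_lengths)) {
    prom[1] <- max(prom[1], 0L)
    prom[2] <- min(prom[2], contig_lengths[[tx$chrom]])
  } else {
    prom[1] <- max(prom[1], 0L)
  }
  add("promoter", prom[1], prom[2])
  out <- dplyr::bind_rows(pieces)
  out$gene_id <- tx$gene_id
  out$transcript_id <- tx$transcript_id
  out$chrom <- tx$chrom
  out$strand <- strand
  out$promoter_mode <- promoter_mode
  dplyr::select(out, "gene_id", "transcript_id", "chrom", "strand",
                "region_class", "start", "end", "intron_index",
                "promoter_mode")
}

.promoter_interval <- function(tx, mode, open_chromatin, config) {
  tss <- transcript_tss(tx)
  up <- function(n) {
    if (tx$strand == "+") c(tx$tx_start - n, tx$tx_start)
    else c(tx$tx_end, tx$tx_end + n)
  }
  minimal <- function() {
    n <- config$promoter_minimal_bp
    c(tss - n + ifelse(tx$strand == "+", 0L, 1L),
      tss + n + ifelse(tx$strand == "+", 0L, 1L))
  }
  switch(mode,
    core200 = up(config$promoter_core_bp),
    audit2kb = up(config$promoter_audit_bp),
    minimal250 = minimal(),
    epigenetic = {
      peaks <- open_chromatin
      if (!is.null(peaks)) {
        peaks <- peaks[peaks$chrom == tx$chrom &
                         peaks$start <= tss & tss < peaks$end, , drop = FALSE]
      }
      if (is.null(peaks) || nrow(peaks) == 0) {
        minimal()  # no supporting open chromatin around the TSS
      } else {
        c(min(peaks$start), max(peaks$end))
      }
    }
  )
}

#' Admit candidate cis-regulatory elements for clinical interpretation
#'
#' A candidate CRE is admitted only when it has at least one element-level
#' line of evidence (open chromatin, enhancer histone marks, TF ChIP), at
#' least one experimental link to its target gene (chromatin interaction,
#' perturbation, eQTL), and the target gene has gene-disease validity at
#' definitive/strong/moderate level (or is PanelApp green). Candidates
#' failing any gate are research variants, with every failed gate named.
#'
#' @param cres Tibble with `chrom`, `start`, `end`, `target_gene`,
#'   `element_evidence` and `link_evidence` (list-columns of character
#'   vectors, or comma-separated strings), and optionally `tissue_context`.
#' @param validity Gene-disease validity tibble with `gene_id`, `level`,
#'   `source` (see [read_gene_validity()]).
#' @return `cres` with logical `admitted` and list-column `reasons`.
#' @export
admit_candidate_cre <- function(cres, validity) {
  to_set <- function(x) {
    if (is.list(x)) x else strsplit(ifelse(is.na(x), "", x), ",\\s*")
  }
  element <- to_set(cres$element_evidence)
  link <- to_set(cres$link_evidence)
  ok_levels <- c("definitive", "strong", "moderate")
  res <- purrr::map(seq_len(nrow(cres)), function(i) {
    reasons <- character()
    if (length(element[[i]]) == 0 || all(element[[i]] == "")) {
      reasons <- c(reasons, "no_element_evidence")
    }
    if (length(link[[i]]) == 0 || all(link[[i]] == "")) {
      reasons <- c(reasons, "research_variant_no_gene_link")
    }
    v <- validity[validity$gene_id == cres$target_gene[i], , drop = FALSE]
    valid_ok <- nrow(v) > 0 &&
      any(v$level %in% ok_levels | v$source == "PanelApp_green")
    if (!valid_ok) {
      reasons <- c(reasons, "gene_disease_validity_below_moderate")
    }
    reasons
  })
  cres$admitted <- lengths(res) == 0
  cres$reasons <- res
  cres
}

#' Read a gene-disease validity registry from TSV
#'
#' Expected columns: `gene` (or `gene_id`), `phenotype`, `level`
#' (definitive/strong/moderate/limited/disputed/none), `source`.
#'
#' @param path Path to the TSV file.
#' @return Tibble with `gene_id`, `phenotype`, `level`, `source`.
#' @export
read_gene_validity <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if ("gene" %in% names(x) && !"gene_id" %in% names(x)) {
    x <- dplyr::rename(x, gene_id = "gene")
  }
  lv <- c("definitive", "strong", "moderate", "limited", "disputed", "none")
  bad <- setdiff(unique(x$level), lv)
  if (length(bad)) stop("unknown validity level(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  x
}

#' Assign variants to per-gene region contexts
#'
#' Each variant may fall in regions of several genes (for example intronic
#' in one gene and inside an admitted CRE linked to another); one context
#' row is emitted per (variant, gene, region). Localisation uses the
#' leftmost altered base of the normalized representation
#' ([variant_anchor()]). Variants overlapping nothing interpretable yield
#' no rows.
#'
#' @param variants Normalized variant tibble (`chrom`, `pos`, `ref`, `alt`).
#' @param regions Region tibble from [derive_gene_regions()].
#' @param cres Optional admitted-CRE tibble from [admit_candidate_cre()];
#'   only rows with `admitted == TRUE` are used.
#' @return Context tibble: variant columns plus `gene_id`, `transcript_id`,
#'   `region_class`, `intron_index`, `via_cre`.
#' @export
assign_region_contexts <- function(variants, regions, cres = NULL) {
  anchor0 <- to_internal(variant_anchor(variants$pos, variants$ref,
                                        variants$alt))
  vkey <- tibble::tibble(
    .vrow = seq_len(nrow(variants)),
    chrom = variants$chrom,
    anchor0 = anchor0
  )
  hits <- dplyr::inner_join(vkey, regions, by = "chrom",
                            relationship = "many-to-many")
  hits <- hits[hits$start <= hits$anchor0 & hits$anchor0 < hits$end, ,
               drop = FALSE]
  ctx <- dplyr::bind_cols(
    variants[hits$.vrow, , drop = FALSE],
    tibble::tibble(
      gene_id = hits$gene_id,
      transcript_id = hits$transcript_id,
      region_class = hits$region_class,
      intron_index = hits$intron_index,
      via_cre = NA_character_
    )
  )
  if (!is.null(cres)) {
    adm <- cres[cres$admitted, , drop = FALSE]
    if (nrow(adm)) {
      adm$.crow <- seq_len(nrow(adm))
      ch <- dplyr::inner_join(vkey, adm, by = "chrom",
                              relationship = "many-to-many")
      ch <- ch[ch$start <= ch$anchor0 & ch$anchor0 < ch$end, , drop = FALSE]
      if (nrow(ch)) {
        cre_ctx <- dplyr::bind_cols(
          variants[ch$.vrow, , drop = FALSE],
          tibble::tibble(
            gene_id = ch$target_gene,
            transcript_id = NA_character_,
            region_class = "cre",
            intron_index = NA_integer_,
            via_cre = paste0(ch$chrom, ":", ch$start, "-", ch$end)
          )
        )
        ctx <- dplyr::bind_rows(ctx, cre_ctx)
      }
    }
  }
  dplyr::arrange(ctx, .data$chrom, .data$pos, .data$gene_id,
                 .data$region_class)
}
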