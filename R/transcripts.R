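#' Read transcript models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS features into one row per transcript with the
#' exon structure as a nested tibble. Provenance is taken from a `tag`
#' attribute (`MANE_Select`, `MANE_Plus_Clinical`) when present, falling
#' back to `canonical`. Coordinates are converted from GFF3 1-based
#' inclusive to the internal 0-based half-open convention.
#'
#' @param path Path to a GFF3 file.
#' @return Transcript tibble: `transcript_id`, `gene_id`, `gene_symbol`,
#'   `chrom`, `strand`, `provenance`, `tx_start`, `tx_end`, `cds_start`,
#'   `cds_end` (0-based half-open; `NA` for non-coding transcripts) and an
#'   `exons` list-column of tibbles with `start`, `end`.
#' @export
read_transcripts <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gff, stringsAsFactors = FALSE)
  df$start0 <- df$start - 1L  # GFF3 1-based inclusive -> 0-based half-open
  df$end0 <- df$end
  tx_types <- c("mRNA", "transcript", "lnc_RNA", "ncRNA")
  tx <- df[df$type %in% tx_types, , drop = FALSE]
  parts <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  parent <- as.character(lapply(parts$Parent, function(p) p[[1]]))
  parts$parent_id <- parent
  gene_of <- stats::setNames(
    as.character(lapply(tx$Parent, function(p) if (length(p)) p[[1]] else NA)),
    tx$ID
  )
  genes <- df[df$type == "gene", , drop = FALSE]
  symbol_of <- stats::setNames(
    if ("Name" %in% names(genes)) genes$Name else genes$ID, genes$ID
  )
  prov <- rep("canonical", nrow(tx))
  if ("tag" %in% names(tx)) {
    tags <- vapply(tx$tag, function(x) paste(unlist(x), collapse = ","), "")
    prov[grepl("MANE_Plus_Clinical", tags)] <- "MANE_Plus_Clinical"
    prov[grepl("MANE_Select", tags)] <- "MANE_Select"
  }
  rows <- purrr::map(seq_len(nrow(tx)), function(i) {
    tid <- tx$ID[i]
    ex <- parts[parts$parent_id == tid & parts$type == "exon", , drop = FALSE]
    ex <- ex[order(ex$start0), , drop = FALSE]
    cds <- parts[parts$parent_id == tid & parts$type == "CDS", , drop = FALSE]
    gid <- gene_of[[tid]]
    tibble::tibble(
      transcript_id = tid,
      gene_id = gid,
      gene_symbol = unname(symbol_of[gid] %||% gid),
      chrom = as.character(tx$seqnames[i]),
      strand = as.character(tx$strand[i]),
      provenance = prov[i],
      tx_start = min(ex$start0),
      tx_end = max(ex$end0),
      cds_start = if (nrow(cds)) min(cds$start0) else NA_integer_,
      cds_end = if (nrow(cds)) max(cds$end0) else NA_integer_,
      exons = list(tibble::tibble(start = ex$start0, end = ex$end0))
    )
  })
  out <- dplyr::bind_rows(rows)
  validate_transcripts(out)
  out
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0 ||
      (length(a) == 1 && is.atomic(a) && is.na(a))) b else a
}

#' Validate transcript-model invariants
#'
#' Checks that exons are sorted and non-overlapping and that any CDS
#' interval is contained in the exon union.
#'
#' @param transcripts Transcript tibble as returned by [read_transcripts()].
#' @return The input, invisibly; errors on violation.
#' @export
validate_transcripts <- function(transcripts) {
  for (i in seq_len(nrow(transcripts))) {
    ex <- transcripts$exons[[i]]
    if (any(ex$start >= ex$end)) {
      stop("degenerate exon in ", transcripts$transcript_id[i], call. = FALSE)
    }
    if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)])) {
      stop("overlapping exons in ", transcripts$transcript_id[i],
           call. = FALSE)
    }
    cs <- transcripts$cds_start[i]
    if (!is.na(cs)) {
      ce <- transcripts$cds_end[i]
      if (cs < min(ex$start) || ce > max(ex$end)) {
        stop("CDS outside exon span in ", transcripts$transcript_id[i],
             call. = FALSE)
      }
    }
  }
  invisible(transcripts)
}

#' Transcription start site of a transcript (0-based position)
#'
#' The 5'-most transcribed base in transcript orientation: the leftmost
#' genomic base for plus-strand transcripts, the rightmost for minus.
#'
#' @param tx A single transcript row.
#' @return 0-based genomic position of the TSS base.
#' @export
transcript_tss <- function(tx) {
  if (tx$strand == "+") tx$tx_start else tx$tx_end - 1L
}

#' Select the clinically relevant transcript for a gene
#'
#' Precedence is MANE Select, then MANE Plus Clinical, then the canonical
#' transcript, with a deterministic lexical tie-break on transcript id.
#'
#' @param transcripts Transcript tibble.
#' @param gene_id Gene to select for.
#' @return One transcript row.
#' @export
select_clinical_transcript <- function(transcripts, gene_id) {
  cand <- transcripts[transcripts$gene_id == gene_id, , drop = FALSE]
  if (nrow(cand) == 0) {
    stop("no transcript found for gene ", gene_id, call. = FALSE)
  }
  rank <- match(cand$provenance,
                c("MANE_Select", "MANE_Plus_Clinical", "canonical"))
  cand[order(rank, cand$transcript_id), , drop = FALSE][1, , drop = FALSE]
}
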