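#' Configuration for the synthetic fixture generators
#'
#' The defaults define the study conditions every pipeline is validated
#' under: trio cohorts plant in-trans candidates at a Poisson rate of 0.9
#' per sample-pLoF pair with in-cis decoys at rate 0.3, allele frequencies
#' span the 0.5% rarity threshold so filters are exercised on both sides,
#' and ClinVar-like call sets mix the five region categories with a
#' realistic excess of coding records.
#'
#' @param seed Integer seed; fully determines all generator output.
#' @param n_genes Number of toy genes.
#' @param exons_per_gene Integer range (min, max) of exons per gene.
#' @param exon_bp,intron_bp Ranges of exon and intron lengths.
#' @param gap_bp Range of intergenic gaps.
#' @param n_trios Number of synthetic trios.
#' @param lambda_in_trans Expected planted in-trans candidates per pair.
#' @param p_in_cis Probability of planting an in-cis decoy per pair.
#' @param p_af_fail,p_hom_fail Probabilities of planting frequency /
#'   homozygote-count decoys per pair.
#' @param clinvar_n Number of ClinVar-like records.
#' @param clinvar_category_mix Named proportions over the six categories.
#' @param clinvar_sig_mix Named proportions over CLNSIG values.
#' @param clinvar_hc_fraction Fraction of records given a high-confidence
#'   review status.
#' @return Named list of class `ncv_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 10L,
                       exons_per_gene = c(2L, 5L),
                       exon_bp = c(80L, 300L),
                       intron_bp = c(250L, 1500L),
                       gap_bp = c(4500L, 7000L),
                       n_trios = 200L,
                       lambda_in_trans = 0.9,
                       p_in_cis = 0.3,
                       p_af_fail = 0.3,
                       p_hom_fail = 0.2,
                       clinvar_n = 600L,
                       clinvar_category_mix = c(coding = 0.50,
                                                five_prime_utr = 0.08,
                                                three_prime_utr = 0.12,
                                                intron = 0.20,
                                                promoter2kb = 0.05,
                                                other = 0.05),
                       clinvar_sig_mix = c(Pathogenic = 0.15,
                                           Likely_pathogenic = 0.10,
                                           Uncertain_significance = 0.45,
                                           Likely_benign = 0.15,
                                           Benign = 0.15),
                       clinvar_hc_fraction = 0.4) {
  stopifnot(
    seed == as.integer(seed),
    abs(sum(clinvar_category_mix) - 1) < 1e-8,
    abs(sum(clinvar_sig_mix) - 1) < 1e-8,
    lambda_in_trans >= 0, p_in_cis >= 0, p_in_cis <= 1
  )
  structure(as.list(environment()), class = "ncv_sim_config")
}

.random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a deterministic toy reference (genome + transcript models)
#'
#' Builds multi-exon genes alternating between strands on one contig with
#' MANE-like provenance tags: most genes carry a single MANE-Select
#' transcript, one gene additionally carries a canonical transcript, and
#' one gene is canonical-only (emulating genes without a designated
#' clinical transcript). Output is byte-identical across runs with the
#' same seed.
#'
#' @param cfg Configuration from [sim_config()].
#' @param dir Optional directory; when given, FASTA and GFF3 files are
#'   written and their paths returned.
#' @return List with `contig`, `seq`, `contig_lengths`, `transcripts`
#'   (tibble, see [read_transcripts()]) and, when `dir` is given,
#'   `fasta_path` / `gff_path`.
#' @export
make_toy_reference <- function(cfg = sim_config(), dir = NULL) {
  set.seed(cfg$seed)
  contig <- "chr1"
  cursor <- sample(seq(cfg$gap_bp[1], cfg$gap_bp[2]), 1)
  rows <- list()
  for (g in seq_len(cfg$n_genes)) {
    n_ex <- sample(seq(cfg$exons_per_gene[1], cfg$exons_per_gene[2]), 1)
    ex_len <- sample(seq(cfg$exon_bp[1], cfg$exon_bp[2]), n_ex,
                     replace = TRUE)
    in_len <- if (n_ex > 1) {
      sample(seq(cfg$intron_bp[1], cfg$intron_bp[2]), n_ex - 1,
             replace = TRUE)
    } else integer(0)
    starts <- cursor + c(0L, cumsum(ex_len[-n_ex] + in_len))
    ends <- starts + ex_len
    strand <- if (g %% 2 == 0) "-" else "+"
    exonic <- sum(ex_len)
    utr5_sp <- sample(40:min(150, floor(exonic / 4)), 1)
    utr3_sp <- sample(40:min(150, floor(exonic / 4)), 1)
    # map spliced UTR lengths to genomic CDS bounds
    cum <- cumsum(ex_len)
    sp2gen <- function(sp_off) {  # spliced offset (0-based, genomic order)
      j <- which(sp_off < cum)[1]
      prev <- if (j > 1) cum[j - 1] else 0L
      starts[j] + (sp_off - prev)
    }
    if (strand == "+") {
      cds_start <- sp2gen(utr5_sp)
      cds_end <- sp2gen(exonic - utr3_sp - 1L) + 1L
    } else {
      cds_start <- sp2gen(utr3_sp)
      cds_end <- sp2gen(exonic - utr5_sp - 1L) + 1L
    }
    gid <- sprintf("GENE%02d", g)
    prov <- if (g == cfg$n_genes) "canonical" else "MANE_Select"
    rows[[length(rows) + 1L]] <- tibble::tibble(
      transcript_id = sprintf("TX%02d.1", g),
      gene_id = gid, gene_symbol = gid, chrom = contig, strand = strand,
      provenance = prov,
      tx_start = starts[1], tx_end = ends[n_ex],
      cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
      exons = list(tibble::tibble(start = as.integer(starts),
                                  end = as.integer(ends)))
    )
    if (g == 1) {
      # a second, lower-precedence transcript on the same gene
      alt <- rows[[length(rows)]]
      alt$transcript_id <- sprintf("TX%02d.2", g)
      alt$provenance <- "canonical"
      rows[[length(rows) + 1L]] <- alt
    }
    cursor <- ends[n_ex] + sample(seq(cfg$gap_bp[1], cfg$gap_bp[2]), 1)
  }
  transcripts <- dplyr::bind_rows(rows)
  contig_len <- max(transcripts$tx_end) + cfg$gap_bp[2]
  seq <- .random_seq(contig_len)
  ref <- list(contig = contig, seq = seq,
              contig_lengths = stats::setNames(contig_len, contig),
              transcripts = transcripts)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ref$fasta_path <- file.path(dir, "toy_reference.fa")
    ref$gff_path <- file.path(dir, "toy_reference.gff3")
    .write_fasta(ref, ref$fasta_path)
    .write_gff3(transcripts, ref$gff_path)
  }
  ref
}

.write_fasta <- function(ref, path) {
  lines <- c(paste0(">", ref$contig),
             substring(ref$seq, seq(1, nchar(ref$seq), 70),
                       pmin(seq(1, nchar(ref$seq), 70) + 69,
                            nchar(ref$seq))))
  writeLines(lines, path)
}

.write_gff3 <- function(transcripts, path) {
  lines <- "##gff-version 3"
  for (gid in unique(transcripts$gene_id)) {
    txs <- transcripts[transcripts$gene_id == gid, , drop = FALSE]
    g_start <- min(txs$tx_start) + 1L
    g_end <- max(txs$tx_end)
    strand <- txs$strand[1]
    chrom <- txs$chrom[1]
    lines <- c(lines, sprintf(
      "%s\ttoy\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
      chrom, g_start, g_end, strand, gid, txs$gene_symbol[1]))
    for (i in seq_len(nrow(txs))) {
      tx <- txs[i, , drop = FALSE]
      tag <- if (tx$provenance == "canonical") ""
      else paste0(";tag=", tx$provenance)
      lines <- c(lines, sprintf(
        "%s\ttoy\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s%s",
        chrom, tx$tx_start + 1L, tx$tx_end, strand, tx$transcript_id, gid,
        tag))
      ex <- tx$exons[[1]]
      for (j in seq_len(nrow(ex))) {
        lines <- c(lines, sprintf(
          "%s\ttoy\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
          chrom, ex$start[j] + 1L, ex$end[j], strand, tx$transcript_id, j,
          tx$transcript_id))
      }
      if (!is.na(tx$cds_start)) {
        for (j in seq_len(nrow(ex))) {
          cs <- max(ex$start[j], tx$cds_start)
          ce <- min(ex$end[j], tx$cds_end)
          if (ce > cs) {
            lines <- c(lines, sprintf(
              "%s\ttoy\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds%d;Parent=%s",
              chrom, cs + 1L, ce, strand, tx$transcript_id, j,
              tx$transcript_id))
          }
        }
      }
    }
  }
  writeLines(lines, path)
}

.ref_base <- function(ref, pos0, n = 1L) {
  substr(ref$seq, pos0 + 1L, pos0 + n)
}

.snv_alt <- function(base) {
  setdiff(c("A", "C", "G", "T"), base)[sample.int(3, 1)]
}

.sample_region_pos <- function(regions) {
  w <- regions$end - regions$start
  j <- sample.int(nrow(regions), 1, prob = w)
  regions$start[j] + sample.int(w[j], 1) - 1L  # 0-based base in region
}

#' Generate a synthetic trio cohort with planted in-trans candidates
#'
#' For each trio, plants one heterozygous high-confidence pLoF variant in
#' the coding sequence of a randomly chosen gene (Mendelian-consistent,
#' transmitted by one parent) plus: in-trans non-coding candidates at a
#' Poisson rate per pair (passing every scan filter), in-cis decoys
#' transmitted by the pLoF parent, and decoys failing the frequency or
#' homozygote-count filters. Intronic candidates carry a splice-impact
#' score drawn uniformly on (0, 1) so the permissive 0.2 filter is
#' exercised on both sides. A truth table records every planted variant
#' with its phase, region and scores.
#'
#' @param cfg Configuration from [sim_config()].
#' @param reference Output of [make_toy_reference()].
#' @return List with `trios` (list of per-trio variant tibbles in
#'   [read_trio_vcf()] layout), `truth` (tibble), `regions` (the core200
#'   region set used) and `gene_list`.
#' @export
make_trio_cohort <- function(cfg = sim_config(), reference = NULL) {
  if (is.null(reference)) reference <- make_toy_reference(cfg)
  set.seed(cfg$seed + 1000L)
  tx_all <- reference$transcripts
  genes <- unique(tx_all$gene_id[tx_all$provenance == "MANE_Select"])
  clinical <- dplyr::bind_rows(
    lapply(genes, function(g) select_clinical_transcript(tx_all, g))
  )
  regions <- derive_gene_regions(clinical, promoter_mode = "core200",
                                 contig_lengths = reference$contig_lengths)
  noncoding <- c("intron", "five_prime_utr", "three_prime_utr", "promoter")
  trios <- vector("list", cfg$n_trios)
  truth <- list()
  for (i in seq_len(cfg$n_trios)) {
    gene <- sample(genes, 1)
    greg <- regions[regions$gene_id == gene, , drop = FALSE]
    coding_reg <- greg[greg$region_class == "coding", , drop = FALSE]
    nc_reg <- greg[greg$region_class %in% noncoding, , drop = FALSE]
    plof_parent <- sample(c("paternal", "maternal"), 1)
    other_parent <- setdiff(c("paternal", "maternal"), plof_parent)
    used <- integer(0)
    draw_pos <- function(reg) {
      repeat {
        p <- .sample_region_pos(reg)
        if (!p %in% used) { used <<- c(used, p); return(p) }
      }
    }
    gt_for <- function(parent) {
      if (parent == "paternal") c("0/1", "0/1", "0/0")
      else c("0/1", "0/0", "0/1")
    }
    mk_row <- function(pos0, parent, region_class, type) {
      base <- .ref_base(reference, pos0)
      gts <- gt_for(parent)
      intronic <- identical(region_class, "intron")
      tibble::tibble(
        chrom = reference$contig, pos = pos0 + 1L,
        id = NA_character_, ref = base, alt = .snv_alt(base),
        gt_proband = gts[1], gt_father = gts[2], gt_mother = gts[3],
        ad_proband = {
          alt_n <- sample(12:20, 1); ref_n <- sample(12:20, 1)
          paste0(ref_n, ",", alt_n)
        },
        gene_id = gene,
        lof_class = if (type == "plof") "HC" else NA_character_,
        af_gnomad = stats::runif(1, 0, 0.004),
        faf = if (type == "af_fail") stats::runif(1, 0.006, 0.05)
              else stats::runif(1, 0, 0.004),
        nhomalt = if (type == "hom_fail") sample(1:5, 1) else 0,
        splice_score = if (intronic && type != "plof")
          round(stats::runif(1), 3) else NA_real_,
        region_class_truth = region_class,
        planted_type = type,
        planted_parent = parent
      )
    }
    rows <- list(mk_row(draw_pos(coding_reg), plof_parent, "coding", "plof"))
    k <- stats::rpois(1, cfg$lambda_in_trans)
    for (j in seq_len(k)) {
      reg_row <- nc_reg[sample.int(nrow(nc_reg), 1,
                                   prob = nc_reg$end - nc_reg$start), ,
                        drop = FALSE]
      rows[[length(rows) + 1L]] <- mk_row(draw_pos(reg_row), other_parent,
                                          reg_row$region_class, "in_trans")
    }
    if (stats::runif(1) < cfg$p_in_cis) {
      reg_row <- nc_reg[sample.int(nrow(nc_reg), 1), , drop = FALSE]
      rows[[length(rows) + 1L]] <- mk_row(draw_pos(reg_row), plof_parent,
                                          reg_row$region_class, "in_cis")
    }
    if (stats::runif(1) < cfg$p_af_fail) {
      reg_row <- nc_reg[sample.int(nrow(nc_reg), 1), , drop = FALSE]
      rows[[length(rows) + 1L]] <- mk_row(draw_pos(reg_row), other_parent,
                                          reg_row$region_class, "af_fail")
    }
    if (stats::runif(1) < cfg$p_hom_fail) {
      reg_row <- nc_reg[sample.int(nrow(nc_reg), 1), , drop = FALSE]
      rows[[length(rows) + 1L]] <- mk_row(draw_pos(reg_row), other_parent,
                                          reg_row$region_class, "hom_fail")
    }
    tbl <- dplyr::arrange(dplyr::bind_rows(rows), .data$pos)
    trios[[i]] <- tbl
    tr <- tbl
    tr$trio_id <- i
    truth[[i]] <- tr[, c("trio_id", "gene_id", "pos", "planted_type",
                         "planted_parent", "region_class_truth",
                         "splice_score", "faf", "nhomalt")]
  }
  list(trios = trios, truth = dplyr::bind_rows(truth), regions = regions,
       gene_list = genes, clinical_transcripts = clinical)
}

#' Write one synthetic trio as a multi-sample VCF
#'
#' @param trio Per-trio tibble from [make_trio_cohort()].
#' @param path Output path.
#' @param samples Sample names (proband, father, mother).
#' @return `path`, invisibly.
#' @export
write_trio_vcf <- function(trio, path,
                           samples = c("PROBAND", "FATHER", "MOTHER")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene id\">",
    "##INFO=<ID=LOF,Number=1,Type=String,Description=\"LoF confidence class\">",
    "##INFO=<ID=AF_GNOMAD,Number=1,Type=Float,Description=\"Reference AF\">",
    "##INFO=<ID=FAF,Number=1,Type=Float,Description=\"Filtering AF\">",
    "##INFO=<ID=NHOMALT,Number=1,Type=Integer,Description=\"Homozygote count\">",
    "##INFO=<ID=SPLICE,Number=1,Type=Float,Description=\"Splice impact score\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  info <- sprintf(
    "GENE=%s%s;AF_GNOMAD=%.6f;FAF=%.6f;NHOMALT=%d%s",
    trio$gene_id,
    ifelse(is.na(trio$lof_class), "", paste0(";LOF=", trio$lof_class)),
    trio$af_gnomad, trio$faf, as.integer(trio$nhomalt),
    ifelse(is.na(trio$splice_score), "",
           sprintf(";SPLICE=%.3f", trio$splice_score))
  )
  # parents carrying the alt allele get a het-like AD
  carrier_f <- trio$gt_father != "0/0"
  carrier_m <- trio$gt_mother != "0/0"
  body <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\tGT:AD\t%s:%s\t%s:%s\t%s:%s",
    trio$chrom, trio$pos, trio$ref, trio$alt, info,
    trio$gt_proband, trio$ad_proband,
    trio$gt_father, ifelse(carrier_f, "14,15", "20,0"),
    trio$gt_mother, ifelse(carrier_m, "14,15", "20,0")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Generate a ClinVar-like call set with planted category/class mixtures
#'
#' Positions are drawn so that each record's region category (under the
#' census precedence rules against the reference's MANE-Select
#' transcripts) equals its planted category exactly; significance and
#' review-status strings are drawn from the configured mixtures. The
#' returned truth table is the ground truth for recovery tests.
#'
#' @param cfg Configuration from [sim_config()].
#' @param reference Output of [make_toy_reference()].
#' @return List with `records` (tibble incl. `planted_category`),
#'   `truth_category_share` and `truth_vus_rate` tibbles.
#' @export
make_clinvar_like <- function(cfg = sim_config(), reference = NULL) {
  if (is.null(reference)) reference <- make_toy_reference(cfg)
  set.seed(cfg$seed + 2000L)
  tx <- reference$transcripts
  mane <- tx[tx$provenance == "MANE_Select", , drop = FALSE]
  regions <- derive_gene_regions(mane, promoter_mode = "audit2kb",
                                 contig_lengths = reference$contig_lengths)
  class_for <- c(coding = "coding", five_prime_utr = "five_prime_utr",
                 three_prime_utr = "three_prime_utr", intron = "intron",
                 promoter2kb = "promoter")
  # integer counts per category summing to n
  mix <- cfg$clinvar_category_mix
  counts <- floor(mix * cfg$clinvar_n)
  rem <- cfg$clinvar_n - sum(counts)
  if (rem > 0) {
    top <- order(mix * cfg$clinvar_n - counts, decreasing = TRUE)[seq_len(rem)]
    counts[top] <- counts[top] + 1L
  }
  contig_len <- unname(reference$contig_lengths[reference$contig])
  draw_category_pos <- function(category) {
    repeat {
      pos0 <- if (category == "other") {
        sample.int(contig_len - 10L, 1) - 1L
      } else {
        .sample_region_pos(
          regions[regions$region_class == class_for[[category]], ,
                  drop = FALSE])
      }
      probe <- tibble::tibble(chrom = reference$contig, pos = pos0 + 1L,
                              ref = "A", alt = "C")
      got <- categorize_variants(probe, tx)$category
      if (got == category) return(pos0)
    }
  }
  sig_values <- names(cfg$clinvar_sig_mix)
  hc_statuses <- .hc_review_statuses
  lc_statuses <- c("criteria_provided,_single_submitter",
                   "no_assertion_criteria_provided")
  recs <- list()
  for (category in names(counts)) {
    n_cat <- counts[[category]]
    if (n_cat == 0) next
    for (r in seq_len(n_cat)) {
      pos0 <- draw_category_pos(category)
      base <- .ref_base(reference, pos0)
      sig <- sample(sig_values, 1, prob = cfg$clinvar_sig_mix)
      revstat <- if (stats::runif(1) < cfg$clinvar_hc_fraction) {
        sample(hc_statuses, 1)
      } else {
        sample(lc_statuses, 1)
      }
      recs[[length(recs) + 1L]] <- tibble::tibble(
        chrom = reference$contig, pos = pos0 + 1L,
        id = sprintf("CV%05d", length(recs) + 1L),
        ref = base, alt = .snv_alt(base),
        clnsig = sig, clnrevstat = revstat,
        planted_category = category
      )
    }
  }
  records <- dplyr::arrange(dplyr::bind_rows(recs), .data$pos)
  share <- records |>
    dplyr::count(.data$planted_category, name = "n") |>
    dplyr::mutate(share = .data$n / sum(.data$n))
  vus <- records |>
    dplyr::group_by(.data$planted_category) |>
    dplyr::summarise(
      vus_rate = mean(.data$clnsig == "Uncertain_significance"),
      .groups = "drop")
  list(records = records, truth_category_share = share,
       truth_vus_rate = vus)
}

#' Write a ClinVar-like call set as a VCF
#'
#' @param records Records tibble from [make_clinvar_like()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinvar_vcf <- function(records, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CLNSIG,Number=.,Type=String,Description=\"Clinical significance\">",
    "##INFO=<ID=CLNREVSTAT,Number=.,Type=String,Description=\"Review status\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t")
  )
  body <- sprintf(
    "%s\t%d\t%s\t%s\t%s\t.\t.\tCLNSIG=%s;CLNREVSTAT=%s",
    records$chrom, records$pos, records$id, records$ref, records$alt,
    records$clnsig, records$clnrevstat
  )
  writeLines(c(header, body), path)
  invisible(path)
}
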