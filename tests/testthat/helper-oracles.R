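# Independent oracles used across the suite. These re-derive expected
# answers from first principles (per-base enumeration, literal rule
# tables) and deliberately share no code with the implementation paths
# they check.

# ---- per-base region labeller ---------------------------------------------
# Label a single 0-based base against one transcript, by definition:
# exonic bases left/right of the CDS are UTR (strand decides which),
# bases inside the CDS bounds are coding, bases between exons are introns.
oracle_label_base <- function(tx, b) {
  ex <- tx$exons[[1]]
  if (b < tx$tx_start || b >= tx$tx_end) return("none")
  in_exon <- any(ex$start <= b & b < ex$end)
  if (!in_exon) return("intron")
  if (is.na(tx$cds_start)) return("noncoding_exon")
  if (b < tx$cds_start) {
    return(if (tx$strand == "+") "five_prime_utr" else "three_prime_utr")
  }
  if (b >= tx$cds_end) {
    return(if (tx$strand == "+") "three_prime_utr" else "five_prime_utr")
  }
  "coding"
}

# Census category of a base across many transcripts, with the stated
# precedence, including the 2-kb upstream promoter window.
oracle_census_category <- function(transcripts, chrom, b, upstream = 2000L) {
  mane <- transcripts[transcripts$provenance == "MANE_Select", , drop = FALSE]
  found <- character()
  for (i in seq_len(nrow(mane))) {
    tx <- mane[i, , drop = FALSE]
    if (tx$chrom != chrom) next
    lab <- oracle_label_base(tx, b)
    if (lab %in% c("five_prime_utr", "three_prime_utr", "coding", "intron")) {
      found <- c(found, lab)
    }
    prom <- if (tx$strand == "+") {
      c(tx$tx_start - upstream, tx$tx_start)
    } else {
      c(tx$tx_end, tx$tx_end + upstream)
    }
    if (prom[1] <= b && b < prom[2]) found <- c(found, "promoter2kb")
  }
  order <- c("coding", "five_prime_utr", "three_prime_utr", "intron",
             "promoter2kb")
  hit <- order[order %in% found]
  if (length(hit)) hit[1] else "other"
}

# ---- splice-offset oracle --------------------------------------------------
# Definitional recomputation of the splice context of a base, working in
# transcript orientation from scratch.
oracle_splice_context <- function(tx, b) {
  ex <- tx$exons[[1]]
  if (b < tx$tx_start || b >= tx$tx_end) return("none")
  gaps <- data.frame(start = ex$end[-nrow(ex)], end = ex$start[-1])
  for (j in seq_len(nrow(gaps))) {
    if (gaps$start[j] <= b && b < gaps$end[j]) {
      if (tx$strand == "+") {
        donor <- b - gaps$start[j] + 1L
        acceptor <- gaps$end[j] - b
      } else {
        donor <- gaps$end[j] - b
        acceptor <- b - gaps$start[j] + 1L
      }
      if (donor <= 2) return("canonical_donor")
      if (acceptor <= 2) return("canonical_acceptor")
      if (donor == 5) return("donor_plus5")
      if (donor <= 8 || acceptor <= 8) return("splice_region")
      return("deep_intronic")
    }
  }
  # exonic: distance 1..3 to a junction abutting an intron
  for (j in seq_len(nrow(ex))) {
    if (ex$start[j] <= b && b < ex$end[j]) {
      d <- Inf
      if (j > 1) d <- min(d, b - ex$start[j] + 1L)
      if (j < nrow(ex)) d <- min(d, ex$end[j] - b)
      if (d <= 3) return("splice_region")
    }
  }
  "none"
}

# ---- ACMG combining-table oracle -------------------------------------------
# A literal transcription of the published five-tier combining rules over
# strength-bucket counts, written independently of the classifier.
oracle_combine <- function(pvs, ps, pm, pp, ba, bs, bp) {
  if (ba >= 1) return("Benign")
  pathogenic <-
    (pvs >= 1 && ps >= 1) ||
    (pvs >= 1 && pm >= 2) ||
    (pvs >= 1 && pm >= 1 && pp >= 1) ||
    (pvs >= 1 && pp >= 2) ||
    (pvs >= 2) ||
    (ps >= 2) ||
    (ps >= 1 && pm >= 3) ||
    (ps >= 1 && pm >= 2 && pp >= 2) ||
    (ps >= 1 && pm >= 1 && pp >= 4)
  likely_pathogenic <-
    (pvs >= 1 && pm >= 1) ||
    (ps >= 1 && pm >= 1) ||
    (ps >= 1 && pp >= 2) ||
    (pm >= 3) ||
    (pm >= 2 && pp >= 2) ||
    (pm >= 1 && pp >= 4)
  benign <- bs >= 2
  likely_benign <- (bs >= 1 && bp >= 1) || (bp >= 2)
  path_tier <- if (pathogenic) "Pathogenic"
  else if (likely_pathogenic) "LikelyPathogenic" else "VUS"
  ben_tier <- if (benign) "Benign"
  else if (likely_benign) "LikelyBenign" else "VUS"
  if (path_tier != "VUS" && ben_tier != "VUS") return("VUS")
  if (path_tier != "VUS") path_tier else ben_tier
}

# Build a decision tibble with given bucket counts (accepted codes only).
make_decisions <- function(pvs = 0, ps = 0, pm = 0, pp = 0,
                           ba = 0, bs = 0, bp = 0) {
  rows <- list()
  push <- function(code, strength, k) {
    for (i in seq_len(k)) {
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        code = code, outcome = "accepted", final_strength = strength,
        reasons = list(character()), mechanisms = list(character())
      )
    }
  }
  push("PX", "VeryStrong", pvs)
  push("PX", "Strong", ps)
  push("PX", "Moderate", pm)
  push("PX", "Supporting", pp)
  push("BA1", "StandAlone", ba)
  push("BX", "Strong", bs)
  push("BX", "Supporting", bp)
  if (length(rows) == 0) {
    return(tibble::tibble(code = character(), outcome = character(),
                          final_strength = character(), reasons = list(),
                          mechanisms = list()))
  }
  dplyr::bind_rows(rows)
}

# ---- random toy transcripts ------------------------------------------------
random_transcript <- function(id = "TX1", strand = NULL, coding = TRUE) {
  n_ex <- sample(2:6, 1)
  ex_len <- sample(30:150, n_ex, replace = TRUE)
  in_len <- sample(40:400, n_ex - 1, replace = TRUE)
  start0 <- sample(3000:10000, 1)
  starts <- start0 + c(0L, cumsum(ex_len[-n_ex] + in_len))
  ends <- starts + ex_len
  strand <- strand %||% sample(c("+", "-"), 1)
  exonic <- sum(ex_len)
  cum <- cumsum(ex_len)
  sp2gen <- function(sp) {
    j <- which(sp < cum)[1]
    prev <- if (j > 1) cum[j - 1] else 0L
    starts[j] + (sp - prev)
  }
  if (coding) {
    u5 <- sample(5:floor(exonic / 4), 1)
    u3 <- sample(5:floor(exonic / 4), 1)
    cds_start <- sp2gen(u5)
    cds_end <- sp2gen(exonic - u3 - 1L) + 1L
  } else {
    cds_start <- NA_integer_; cds_end <- NA_integer_
  }
  tibble::tibble(
    transcript_id = id, gene_id = paste0("G_", id), gene_symbol = id,
    chrom = "chr1", strand = strand, provenance = "MANE_Select",
    tx_start = starts[1], tx_end = ends[n_ex],
    cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
    exons = list(tibble::tibble(start = as.integer(starts),
                                end = as.integer(ends)))
  )
}

# Mirror a transcript around a fixed genome length L (reverse-complement
# coordinate image): intervals map [s, e) -> [L - e, L - s), strand flips.
mirror_transcript <- function(tx, L) {
  ex <- tx$exons[[1]]
  m <- tibble::tibble(start = L - rev(ex$end), end = L - rev(ex$start))
  out <- tx
  out$strand <- if (tx$strand == "+") "-" else "+"
  out$tx_start <- L - tx$tx_end
  out$tx_end <- L - tx$tx_start
  if (!is.na(tx$cds_start)) {
    out$cds_start <- L - tx$cds_end
    out$cds_end <- L - tx$cds_start
  }
  out$exons <- list(m)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
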