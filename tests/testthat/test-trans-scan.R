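trio_gts <- function(p, f, m) c(p, f, m)

test_that("transmission phasing enumerates trio configurations correctly", {
  pat <- trio_gts("0/1", "0/1", "0/0")
  mat <- trio_gts("0/1", "0/0", "0/1")
  expect_identical(phase_by_transmission(pat, mat), "in_trans")
  expect_identical(phase_by_transmission(pat, pat), "in_cis")
  expect_identical(phase_by_transmission(mat, mat), "in_cis")
  # apparent de novo partner -> unknown
  expect_identical(
    phase_by_transmission(pat, trio_gts("0/1", "0/0", "0/0")), "unknown")
  # both parents carry the allele -> ambiguous -> unknown
  expect_identical(
    phase_by_transmission(pat, trio_gts("0/1", "0/1", "0/1")), "unknown")
  # homozygous father must transmit: certain even if mother also carries
  expect_identical(
    phase_by_transmission(trio_gts("0/1", "1/1", "0/1"), mat), "in_trans")
  # non-het proband or missing genotype -> unknown
  expect_identical(
    phase_by_transmission(trio_gts("1/1", "0/1", "0/1"), mat), "unknown")
  expect_identical(
    phase_by_transmission(trio_gts("0/1", "./.", "0/0"), mat), "unknown")
  # haploid-style genotype is excluded from phasing
  expect_identical(
    phase_by_transmission(trio_gts("1", "0", "0"), mat), "unknown")
})

test_that("pLoF pairing enforces confidence class, rarity, balance and
           single-hit genes", {
  base <- tibble::tibble(
    chrom = "chr1", pos = c(10L, 20L, 30L, 40L, 50L, 60L),
    id = NA_character_, ref = "A", alt = "T",
    gt_proband = c("0/1", "0/1", "0/1", "0/1", "0/1", "0/1"),
    gt_father = c("0/1", "0/1", "0/1", "0/1", "0/1", "0/1"),
    gt_mother = "0/0",
    ad_proband = c("15,14", "15,14", "4,20", "15,14", "15,14", "15,14"),
    gene_id = c("G1", "G2", "G3", "G4", "G5", "G5"),
    lof_class = c("HC", "LC", "HC", "HC", "HC", "HC"),
    af_gnomad = c(0.001, 0.001, 0.001, 0.02, 0.001, 0.001)
  )
  pairs <- find_plof_pairs(base, paste0("G", 1:5))
  # G1 passes; G2 low confidence; G3 balance 0.83; G4 too common;
  # G5 has two passing pLoFs -> excluded
  expect_identical(pairs$gene_id, "G1")
  expect_identical(pairs$plof_parent, "paternal")
})

test_that("AF sources combine under strict AND with a permissive option", {
  x <- tibble::tibble(
    chrom = "chr1", pos = 1:3, id = NA_character_, ref = "A", alt = "T",
    gt_proband = "0/1", gt_father = "0/1", gt_mother = "0/0",
    ad_proband = "15,15", gene_id = c("G1", "G2", "G3"), lof_class = "HC",
    af_cohort = c(0.001, 0.001, 0.01),
    af_gnomad = c(0.001, 0.01, 0.001)
  )
  strict <- find_plof_pairs(x, c("G1", "G2", "G3"),
                            af_keys = c("af_cohort", "af_gnomad"))
  expect_identical(strict$gene_id, "G1")
  loose <- find_plof_pairs(x, c("G1", "G2", "G3"),
                           af_keys = c("af_cohort", "af_gnomad"),
                           af_rule = "any")
  expect_setequal(loose$gene_id, c("G1", "G2", "G3"))
})

test_that("filtering allele frequency is the one-sided 95% lower bound", {
  expect_identical(filtering_af(0, 10000), 0)
  expect_equal(filtering_af(5, 10000), stats::qbeta(0.05, 5, 9996))
  expect_lt(filtering_af(5, 10000), 5 / 10000)
})

test_that("scan recovers planted in-trans candidates and never reports
           in-cis decoys", {
  cfg <- sim_config(seed = 20, n_trios = 60, lambda_in_trans = 1.2,
                    p_in_cis = 0.5)
  ref <- make_toy_reference(cfg)
  coh <- make_trio_cohort(cfg, ref)
  found <- list()
  for (i in seq_along(coh$trios)) {
    trio <- coh$trios[[i]]
    pairs <- find_plof_pairs(trio, coh$gene_list)
    expect_identical(nrow(pairs), 1L)
    res <- scan_in_trans_noncoding(pairs, trio, coh$regions,
                                   apply_splice_filter = FALSE)
    cand <- res$candidates[[1]]
    truth <- coh$truth[coh$truth$trio_id == i, ]
    planted <- truth[truth$planted_type == "in_trans", ]
    # exact recovery of planted in-trans candidates
    expect_setequal(cand$pos, planted$pos)
    # in-cis decoys and filter-failing decoys never surface
    bad <- truth[truth$planted_type %in% c("in_cis", "af_fail", "hom_fail"),
                 ]
    expect_length(intersect(cand$pos, bad$pos), 0)
    found[[i]] <- cand
  }
  # region attribution agrees with the generator's bookkeeping
  all_cand <- dplyr::bind_rows(found)
  expect_gt(nrow(all_cand), 0)
  expect_identical(all_cand$region_class, all_cand$region_class_truth)
})

test_that("the intronic splice filter keeps exactly the above-threshold
           subset and is monotone", {
  cfg <- sim_config(seed = 21, n_trios = 40, lambda_in_trans = 1.5)
  ref <- make_toy_reference(cfg)
  coh <- make_trio_cohort(cfg, ref)
  for (i in seq_along(coh$trios)) {
    trio <- coh$trios[[i]]
    pairs <- find_plof_pairs(trio, coh$gene_list)
    open <- scan_in_trans_noncoding(pairs, trio, coh$regions,
                                    apply_splice_filter = FALSE)
    filt <- scan_in_trans_noncoding(pairs, trio, coh$regions,
                                    apply_splice_filter = TRUE)
    co <- open$candidates[[1]]
    cf <- filt$candidates[[1]]
    # filter never adds candidates
    expect_lte(nrow(cf), nrow(co))
    expect_true(all(cf$pos %in% co$pos))
    # exactly the intronic subset with score >= 0.2 survives
    want <- co[co$region_class != "intron" |
                 (!is.na(co$splice_score) & co$splice_score >= 0.2), ]
    expect_setequal(cf$pos, want$pos)
  }
})

test_that("scan summaries are exact bookkeeping over planted counts", {
  empty <- summarize_scan(tibble::tibble())
  expect_identical(empty$overall$n_pairs, 0L)
  expect_identical(empty$overall$mean_candidates_per_pair, 0)
  # hand-planted counts {0, 1, 3} -> mean 4/3
  pairs <- tibble::tibble(
    gene_id = c("A", "B", "C"),
    candidates = list(
      tibble::tibble(),
      tibble::tibble(region_class = "intron", splice_score = 0.5),
      tibble::tibble(region_class = c("intron", "promoter",
                                      "five_prime_utr"),
                     splice_score = c(0.1, NA, NA))
    ),
    n_candidates = c(0L, 1L, 3L)
  )
  s <- summarize_scan(pairs)
  expect_identical(s$overall$n_pairs, 3L)
  expect_identical(s$overall$n_pairs_with_candidate, 2L)
  expect_equal(s$overall$mean_candidates_per_pair, 4 / 3)
  expect_identical(s$overall$max_per_pair, 3L)
  expect_identical(s$overall$n_intronic_passing_splice_filter, 1L)
  expect_identical(sum(s$per_region$n_candidates),
                   sum(pairs$n_candidates))
})

test_that("trio VCF round trip preserves genotypes and annotations", {
  cfg <- sim_config(seed = 22, n_trios = 2)
  ref <- make_toy_reference(cfg)
  coh <- make_trio_cohort(cfg, ref)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_trio_vcf(coh$trios[[1]], path)
  back <- read_trio_vcf(path, info_keys = c("GENE", "LOF", "FAF",
                                            "NHOMALT", "SPLICE"))
  orig <- coh$trios[[1]]
  expect_identical(back$pos, orig$pos)
  expect_identical(back$gt_proband, orig$gt_proband)
  expect_identical(back$gt_father, orig$gt_father)
  expect_identical(back$GENE, orig$gene_id)
  # FAF is serialised at six decimals
  expect_lt(max(abs(back$FAF - orig$faf)), 1e-6)
  # the pipeline runs identically off the parsed file
  parsed <- dplyr::rename(back, gene_id = GENE, lof_class = LOF,
                          faf = FAF, nhomalt = NHOMALT,
                          splice_score = SPLICE)
  p1 <- find_plof_pairs(parsed, coh$gene_list, af_keys = character())
  p0 <- find_plof_pairs(orig, coh$gene_list)
  expect_identical(p1$pos, p0$pos)
})
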