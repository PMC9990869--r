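rna1 <- make_site_counts(list(
  c("chr1", 100, "A", "+", 35, 45, 0, 5, 0),    # A>G level 0.1
  c("chr1", 200, "A", "+", 35, 45, 0, 5, 0),    # het in DNA
  c("chr1", 300, "A", "+", 35, 50, 0, 0, 0),    # no mismatch
  c("chr1", 400, "A", "+", 35, 40, 5, 5, 0),    # two alt alleles
  c("chr1", 500, "A", "+", 25, 30, 0, 20, 0),   # low quality
  c("chr1", 600, "A", "+", 35, 4, 0, 5, 0),     # depth 9
  c("chr1", 700, "A", "+", 35, 0, 0, 20, 0),    # level exactly 1
  c("chr1", 800, "A", "+", 35, 40, 0, 10, 0),   # masked SNP
  c("chr1", 900, "A", "+", 35, 30, 0, 20, 0)))  # clean passing site
dna_rows <- lapply(c(100, 300, 400, 500, 600, 700, 800, 900), function(p)
  c("chr1", p, "A", "+", 35, 60, 0, 0, 0))
dna1 <- make_site_counts(c(dna_rows,
  list(c("chr1", 200, "A", "+", 35, 30, 0, 30, 0))))

test_that("candidate calling computes levels and screens DNA evidence", {
  cands <- call_candidates(rna1, dna1)
  expect_true(all(c(100, 200) %in% cands$pos))
  i <- match(100, cands$pos)
  expect_equal(cands$alt[i], "G")
  expect_equal(cands$level[i], 0.1)
  expect_equal(cands$rna_alt_count[i], 5L)
  # position 300 has no RNA mismatch
  expect_false(300 %in% cands$pos)
  # het DNA site is still a candidate; the cascade flags it
  j <- match(200, cands$pos)
  expect_equal(cands$dna_alt_frac[j], 0.5)

  # RNA position absent from (or too shallow in) the DNA table is excluded
  rna_extra <- make_site_counts(list(c("chr1", 999, "A", "+", 35, 45, 0, 5, 0)))
  dna_empty <- make_site_counts(list(c("chr1", 1, "A", "+", 35, 60, 0, 0, 0)))
  c2 <- call_candidates(rna_extra, dna_empty)
  expect_equal(nrow(c2), 0L)
  expect_equal(attr(c2, "n_no_dna_evidence"), 1L)
})

test_that("the filter cascade assigns exactly one first-fail flag", {
  mask <- as_snp_mask(data.frame(chrom = "chr1", pos = 800L))
  fc <- apply_filters(call_candidates(rna1, dna1), snp_mask = mask)
  flag_of <- function(p) fc$flag[match(p, fc$pos)]
  expect_equal(flag_of(200), "dna_variant_removed")
  expect_equal(flag_of(400), "multi_allelic_removed")
  expect_equal(flag_of(500), "low_quality_removed")
  expect_equal(flag_of(600), "low_depth_removed")
  expect_equal(flag_of(700), "level_out_of_range_removed")
  expect_equal(flag_of(800), "snp_removed")
  expect_equal(flag_of(900), "passed")
  expect_equal(flag_of(100), "passed")   # level 0.1 is inclusive

  # partition: every candidate passed or exactly one removal flag
  expect_true(all(fc$flag %in% c(editscape:::REMOVAL_FLAGS, "passed")))
  counts <- attr(fc, "filter_log")$flag_counts
  expect_equal(sum(counts), nrow(fc))

  # first-fail ordering: low quality outranks the level filter
  rna_lq <- make_site_counts(list(c("chr1", 100, "A", "+", 10, 50, 0, 1, 0)))
  dna_lq <- make_site_counts(list(c("chr1", 100, "A", "+", 35, 60, 0, 0, 0)))
  fc2 <- apply_filters(call_candidates(rna_lq, dna_lq))
  expect_equal(fc2$flag, "low_quality_removed")
})

test_that("raising thresholds never recovers sites (monotonicity)", {
  set.seed(7)
  sim <- simulate_dataset(small_cfg(seed = 7L))
  id <- sim$samples$sample_id[1]
  cands <- call_candidates(sim$rna[[id]], sim$dna[[id]])
  n_pass <- function(th) sum(apply_filters(cands, thresholds = th)$passed)
  base <- n_pass(list())
  for (md in c(10L, 20L, 30L)) {
    for (mq in c(30, 34, 36)) {
      n <- n_pass(list(min_depth = md, min_base_quality = mq))
      expect_lte(n, base)
      base2 <- n
    }
  }
  expect_lt(n_pass(list(min_depth = 40L)), base)
})

test_that("strand resolution complements mismatches in minus-strand genes", {
  ann <- toy_annotation()
  sites <- data.frame(
    chrom = "chr1", pos = c(150L, 1050L, 5000L),
    ref = c("A", "T", "A"), alt = c("G", "C", "G"),
    stringsAsFactors = FALSE)
  r <- resolve_strand(sites, ann)
  expect_equal(r$edit_type, c("A>G", "A>G", "A>G"))
  expect_equal(r$strand, c("+", "-", "unknown"))
  expect_equal(r$gene_id, c("GA", "GB", NA))
  # without annotation the raw mismatch is kept
  r2 <- resolve_strand(sites, NULL)
  expect_equal(r2$edit_type, c("A>G", "T>C", "A>G"))
  expect_true(all(r2$strand == "unknown"))
})

test_that("merging unions sites and counts per-condition coverage", {
  samples <- make_samples(2)
  mk <- function(pos_levels, id) {
    rows <- lapply(names(pos_levels), function(p) {
      lv <- pos_levels[[p]]
      g <- round(50 * lv); a <- 50 - g
      c("chr1", p, "A", "+", 35, a, 0, g, 0)
    })
    rna <- make_site_counts(rows, sample_id = id)
    dna <- make_site_counts(lapply(names(pos_levels), function(p)
      c("chr1", p, "A", "+", 35, 60, 0, 0, 0)), sample_id = id, assay = "DNA")
    apply_filters(call_candidates(rna, dna))
  }
  filtered <- list(
    T01 = mk(list(`100` = 0.2, `200` = 0.3), "T01"),
    T02 = mk(list(`100` = 0.25), "T02"),
    N01 = mk(list(`200` = 0.1), "N01"),
    N02 = mk(list(`300` = 0.5), "N02"))
  em <- merge_samples(filtered, samples)
  expect_equal(nrow(em$sites), 3L)
  i100 <- match("chr1:100", em$sites$key)
  expect_equal(em$sites$cov_tumor[i100], 2L)
  expect_equal(em$sites$cov_normal[i100], 0L)
  i200 <- match("chr1:200", em$sites$key)
  expect_equal(em$sites$cov_tumor[i200], 1L)
  expect_equal(em$sites$cov_normal[i200], 1L)
  expect_true(is.na(em$level["chr1:300", "T01"]))
  expect_equal(em$level["chr1:100", "T01"], 0.2)

  # duplicated position within one sample is an integrity error
  dup <- filtered$T01
  dup <- rbind(dup, dup[1, ])
  expect_error(merge_samples(c(filtered, list(T01 = NULL))[names(filtered)],
                             samples), NA)
  filtered2 <- filtered
  filtered2$T01 <- dup
  expect_error(merge_samples(filtered2, samples), "duplicate")

  # empty input gives an empty matrix
  emptyf <- lapply(filtered, function(x) x[0, , drop = FALSE])
  em0 <- merge_samples(emptyf, samples)
  expect_equal(nrow(em0$sites), 0L)
})

test_that("planted sites are recovered and confounders rejected", {
  sim <- simulate_dataset(small_cfg(seed = 99L))
  mask <- as_snp_mask(sim$truth$snps)
  em <- call_editing(sim$rna, sim$dna, sim$samples, snp_mask = mask,
                     ann = sim$reference$annotation)
  truth_keys <- site_key(sim$truth$sites$chrom, sim$truth$sites$pos)
  called <- em$sites$key
  expect_gt(mean(called %in% truth_keys), 0.95)           # precision
  hi <- sim$truth$sites[pmax(sim$truth$sites$true_tumor,
                             sim$truth$sites$true_normal) >= 0.15, ]
  expect_gt(mean(site_key(hi$chrom, hi$pos) %in% called), 0.90)  # recall
  bad <- c(site_key(sim$truth$snps$chrom, sim$truth$snps$pos),
           site_key(sim$truth$dna_variants$chrom,
                    sim$truth$dna_variants$pos))
  expect_equal(sum(called %in% bad), 0L)
  # with simulator defaults every planted edit is A-to-I
  expect_gt(mean(em$sites$edit_type == "A>G"), 0.9)
})
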