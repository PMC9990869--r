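cfg0 <- small_cfg(seed = 11L)
sim0 <- simulate_dataset(cfg0)

test_that("simulation is a deterministic function of its configuration", {
  sim1 <- simulate_dataset(small_cfg(seed = 11L))
  expect_identical(as.character(sim0$reference$genome),
                   as.character(sim1$reference$genome))
  expect_identical(sim0$truth$sites, sim1$truth$sites)
  expect_identical(as.data.frame(sim0$rna[[1]]), as.data.frame(sim1$rna[[1]]))
  expect_identical(sim0$expression, sim1$expression)
  # and byte-identical on disk
  d1 <- tempfile(); d2 <- tempfile()
  write_simulation(sim0, d1); write_simulation(sim1, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_true(length(f1) > 10)
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
  # a different seed changes the genome
  sim2 <- simulate_reference(small_cfg(seed = 12L))
  expect_false(identical(as.character(sim0$reference$genome),
                         as.character(sim2$genome)))
})

test_that("planted scaffold respects group structure and the reference", {
  tr <- sim0$truth$sites
  expect_equal(as.vector(table(tr$group)[c("shared", "tumor_specific",
                                           "normal_specific")]),
               c(40L, 20L, 20L))
  # specific groups are absent from the other condition by construction
  expect_true(all(tr$true_normal[tr$group == "tumor_specific"] == 0))
  expect_true(all(tr$true_tumor[tr$group == "normal_specific"] == 0))
  # selection-planted sites carry the configured diverged frequencies
  expect_equal(sum(tr$selected), 10L)
  expect_true(all(tr$true_tumor[tr$selected] == 0.8))
  expect_true(all(tr$true_normal[tr$selected] == 0.2))
  # center base is A on the editing strand
  g <- sim0$reference$genome
  base <- mapply(function(ch, p) as.character(
    Biostrings::subseq(g[[ch]], p, p)), tr$chrom, tr$pos)
  expect_true(all(ifelse(tr$strand == "-", base == "T", base == "A")))
  # genic sites agree with the annotation
  ann <- sim0$reference$annotation
  cls <- classify_positions(ann, tr$chrom, tr$pos)
  genic <- !is.na(tr$gene_id)
  expect_equal(cls$gene_id[genic], tr$gene_id[genic])
  expect_equal(cls$region[genic], tr$region[genic])
  expect_true(all(cls$region[!genic] == "intergenic"))
})

test_that("counts are calibrated to the configured Beta mean", {
  # >= 1000 planted sites, no ADAR scaling, no planted differences
  cfg <- sim_config(n_pairs = 2L, genome_length = 400000L, n_genes = 40L,
                    n_sites = c(shared = 1200L, tumor_specific = 0L,
                                normal_specific = 0L),
                    n_diff_shared = 0L, n_fst_sites = 0L,
                    adar_coupling = 0, adar_tumor_lfc = 0,
                    n_snps = 0L, n_dna_variants = 0L, n_background = 0L,
                    n_splice_events = 0L, error_rate = 0, seed = 21L)
  sim <- simulate_dataset(cfg)
  keys <- site_key(sim$truth$sites$chrom, sim$truth$sites$pos)
  x <- sim$rna[[1]]
  xk <- site_key(x$chrom, x$pos)
  planted <- x[xk %in% keys & x$depth >= 50, ]
  alt <- ifelse(planted$ref == "A", planted$count_G, planted$count_C)
  frac <- alt / planted$depth
  mu <- cfg$beta_shape[1] / sum(cfg$beta_shape)
  se <- sd(frac) / sqrt(length(frac))
  expect_gt(length(frac), 500)
  expect_lt(abs(mean(frac) - mu), 3 * se)
})

test_that("motif planting is exact at motif_bias = 1", {
  cfg <- small_cfg(seed = 31L, motif_bias = 1)
  ref <- simulate_reference(cfg)
  tr <- ref$sites
  g <- ref$genome
  up <- down <- character(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    w <- as.character(Biostrings::subseq(g[[tr$chrom[i]]],
                                         tr$pos[i] - 1L, tr$pos[i] + 1L))
    if (tr$strand[i] == "-")
      w <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(w)))
    up[i] <- substr(w, 1, 1); down[i] <- substr(w, 3, 3)
  }
  expect_true(all(tr$motif))
  expect_equal(mean(up == "G"), 0)     # -1 G frequency exactly 0
  expect_equal(mean(down == "G"), 1)   # +1 G frequency exactly 1
})

test_that("degenerate configurations simulate cleanly", {
  # zero genes: everything intergenic, no expression genes beyond ADARs
  cfg <- sim_config(n_pairs = 2L, n_genes = 0L, genome_length = 50000L,
                    n_sites = c(shared = 10L, tumor_specific = 0L,
                                normal_specific = 0L),
                    n_diff_shared = 0L, n_fst_sites = 0L,
                    n_snps = 0L, n_dna_variants = 0L, n_background = 0L,
                    n_splice_events = 0L, seed = 41L)
  sim <- simulate_dataset(cfg)
  expect_true(all(sim$truth$sites$region == "intergenic"))
  expect_equal(sort(rownames(sim$expression)),
               sort(c("ADAR", "ADARB1", "ADARB2")))
  expect_equal(nrow(sim$splicing), 0L)
  # infeasible gene layout is a configuration error
  expect_error(simulate_reference(
    sim_config(n_genes = 40L, genome_length = 20000L, seed = 1L)),
    "infeasible|place")
})

test_that("splicing events are anchored as configured", {
  ev <- sim0$truth$splicing
  expect_equal(nrow(ev), 20L)
  expect_equal(sum(ev$contains_site), round(0.42 * 20))
  tr <- sim0$truth$sites
  keys <- site_key(tr$chrom, tr$pos)
  for (i in which(ev$contains_site)) {
    anchor <- ev$anchor[i]
    expect_true(anchor %in% keys)
    pos <- as.integer(sub(".*:", "", anchor))
    expect_true(pos >= ev$upstream_start[i] && pos <= ev$downstream_end[i])
  }
  # non-anchored events contain no planted position
  for (i in which(!ev$contains_site)) {
    span <- site_key(ev$chrom[i], ev$upstream_start[i]:ev$downstream_end[i])
    expect_false(any(span %in% keys))
  }
})

test_that("truth files are written as valid TSV/VCF", {
  d <- tempfile()
  write_truth(sim0$truth, d)
  sites <- read.delim(file.path(d, "sites.tsv"))
  expect_equal(nrow(sites), nrow(sim0$truth$sites))
  mask <- read_snp_mask(file.path(d, "snps.vcf"))
  expect_equal(nrow(mask), nrow(sim0$truth$snps))
  expect_true(all(in_snp_mask(mask, sim0$truth$snps$chrom,
                              sim0$truth$snps$pos)))
})
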