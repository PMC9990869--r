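make_dre <- function(keys, genes, groups = "shared", is_dre = TRUE) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  data.frame(
    key = keys,
    chrom = vapply(parts, `[`, "", 1L),
    pos = as.integer(vapply(parts, `[`, "", 2L)),
    strand = "+", gene_id = genes, region = "intronic", edit_type = "A>G",
    group = rep_len(groups, length(keys)),
    cov_tumor = 10L, cov_normal = 10L,
    tumor_edited = 100L, tumor_unedited = 400L,
    normal_edited = 50L, normal_unedited = 450L,
    mean_level_tumor = 0.2, mean_level_normal = 0.1,
    fisher_p = 0.01, degenerate = FALSE, bh_q = 0.02,
    significant = TRUE, is_dre = rep_len(is_dre, length(keys)),
    fst = NA_real_, known = NA, stringsAsFactors = FALSE)
}

test_that("expression intersection joins on genes with thresholds", {
  dre <- make_dre(c("chr1:100", "chr1:200", "chr2:300"),
                  c("G1", "G2", "G3"))
  deg <- data.frame(gene_id = c("G1", "G2", "G3", "G4"),
                    log2fc = c(2, 0.5, -1.5, 3),
                    padj = c(0.001, 0.001, 0.2, 0.001),
                    stringsAsFactors = FALSE)
  ie <- intersect_expression(dre, deg)
  # G1 passes both thresholds; G2 fails |lfc|; G3 fails padj
  expect_equal(ie$edres$key, "chr1:100")
  expect_equal(ie$edres$de_log2fc, 2)
  expect_equal(ie$eddegs$gene_id, "G1")
  expect_equal(ie$summary$n_sites[ie$summary$group == "shared"], 1L)

  # a DRE in a gene absent from the DEG table is silently not an eDRE
  deg2 <- deg[deg$gene_id != "G1", ]
  ie2 <- intersect_expression(dre, deg2)
  expect_equal(nrow(ie2$edres), 0L)

  # disjoint namespaces raise an error naming unmatched genes
  deg3 <- data.frame(gene_id = c("X1", "X2"), log2fc = c(2, 2),
                     padj = c(0.01, 0.01))
  expect_error(intersect_expression(dre, deg3), "G1")
})

test_that("the paired log2FC stand-in recovers planted DE genes exactly", {
  sim <- simulate_dataset(small_cfg(seed = 81L))
  deg <- paired_log2fc(sim$expression, sim$samples)
  hits <- deg$gene_id[abs(deg$log2fc) >= 1 & deg$padj < 0.05]
  hits <- setdiff(hits, c("ADAR", "ADARB1", "ADARB2"))
  expect_setequal(hits, sim$truth$de_genes$gene_id)
  # planted direction is recovered
  m <- match(sim$truth$de_genes$gene_id, deg$gene_id)
  expect_equal(sign(deg$log2fc[m]), sign(sim$truth$de_genes$true_lfc))

  # join soundness on simulated data: output equals an independent re-join
  em <- call_editing(sim$rna, sim$dna, sim$samples,
                     snp_mask = as_snp_mask(sim$truth$snps),
                     ann = sim$reference$annotation)
  dre <- dre_table(em)
  ie <- intersect_expression(dre, deg)
  sig_genes <- deg$gene_id[abs(deg$log2fc) >= 1 & deg$padj < 0.05]
  manual <- dre[dre$is_dre & !is.na(dre$gene_id) &
                  dre$gene_id %in% sig_genes, "key"]
  expect_setequal(ie$edres$key, manual)
})

test_that("editing-expression correlation follows planted sign", {
  samples <- make_samples(8)
  lv <- seq(0.1, 0.9, length.out = 16)
  em <- make_editing_matrix(list("chr1:100" = setNames(lv, samples$sample_id)),
                            samples)
  em$sites$gene_id <- "G1"
  expr <- matrix(10 - 5 * lv + rnorm(16, 0, 0.01), 1,
                 dimnames = list("G1", samples$sample_id))
  r <- editing_expression_correlation(em, expr, "chr1:100", min_obs = 8L)
  expect_lt(r$rho, -0.9)
  expect_lt(r$p, 0.01)
  # constant expression is degenerate
  expr_c <- matrix(5, 1, 16, dimnames = list("G1", samples$sample_id))
  rc <- editing_expression_correlation(em, expr_c, "chr1:100", min_obs = 8L)
  expect_true(is.na(rc$rho))
  # n = 2 is refused (reported missing)
  s2 <- make_samples(1)
  em2 <- make_editing_matrix(list("chr1:100" = setNames(c(0.2, 0.4),
                                                        s2$sample_id)), s2)
  em2$sites$gene_id <- "G1"
  expr2 <- matrix(c(1, 2), 1, dimnames = list("G1", s2$sample_id))
  r2 <- editing_expression_correlation(em2, expr2, "chr1:100", min_obs = 2L)
  expect_true(is.na(r2$rho))
})

test_that("splicing intersection respects event spans and boundaries", {
  ev <- data.frame(
    event_id = c("E1", "E2"), gene_id = c("G1", "G2"), chrom = "chr1",
    strand = "+", event_type = c("SE", "RI"),
    exon_start = c(500L, 2500L), exon_end = c(600L, 2600L),
    upstream_start = c(300L, 2300L), upstream_end = c(499L, 2499L),
    downstream_start = c(601L, 2601L), downstream_end = c(800L, 2800L),
    inc_diff = c(0.3, -0.2), pvalue = c(1e-4, 1e-3),
    stringsAsFactors = FALSE)
  dre <- make_dre(c("chr1:350", "chr1:800", "chr1:801", "chr1:2499"),
                  c("G1", "G1", "G1", "G2"))
  is_ <- intersect_splicing(dre, ev)
  # upstream-intron edit and the closed right boundary are in; 1 bp out is
  # not
  expect_setequal(is_$sdres$key[is_$sdres$event_id == "E1"],
                  c("chr1:350", "chr1:800"))
  expect_false("chr1:801" %in% is_$sdres$key)
  expect_equal(is_$event_fraction, 1.0)
  expect_setequal(is_$eddsgs, c("G1", "G2"))
  expect_equal(is_$by_type$n_sdre[is_$by_type$event_type == "SE"], 2L)
  # unknown event type errors
  ev_bad <- ev; ev_bad$event_type[1] <- "XX"
  expect_error(intersect_splicing(dre, ev_bad), "XX")
})

test_that("planted splicing overlap fraction is recovered", {
  sim <- simulate_dataset(small_cfg(seed = 82L))
  em <- call_editing(sim$rna, sim$dna, sim$samples,
                     snp_mask = as_snp_mask(sim$truth$snps),
                     ann = sim$reference$annotation)
  dre <- dre_table(em)
  is_ <- intersect_splicing(dre, sim$splicing)
  planted <- mean(sim$truth$splicing$contains_site)
  expect_lt(abs(is_$event_fraction - planted), 0.1)
})

test_that("structure pairs differ at exactly the edited adenosine", {
  g <- Biostrings::DNAStringSet(
    c(chr1 = paste(c(rep("C", 100), "A", rep("G", 100)), collapse = "")))
  sites <- data.frame(chrom = "chr1", pos = 101L, strand = "+",
                      stringsAsFactors = FALSE)
  pr <- extract_structure_pairs(sites, g, window = 5L)
  expect_equal(length(pr), 2L)
  un <- as.character(pr[["chr1:101|unedited"]])
  ed <- as.character(pr[["chr1:101|edited"]])
  expect_equal(nchar(un), 11L)
  expect_equal(substr(un, 6, 6), "A")
  expect_equal(substr(ed, 6, 6), "G")
  expect_equal(sum(strsplit(un, "")[[1]] != strsplit(ed, "")[[1]]), 1L)

  # minus-strand: reverse-complement pair, center T on the genome
  g2 <- Biostrings::DNAStringSet(
    c(chr1 = paste(c(rep("C", 100), "T", rep("G", 100)), collapse = "")))
  pr2 <- extract_structure_pairs(
    data.frame(chrom = "chr1", pos = 101L, strand = "-"), g2, window = 5L)
  un2 <- as.character(pr2[[1]])
  expect_equal(substr(un2, 6, 6), "A")
  expect_equal(substr(un2, 1, 5), "CCCCC")   # revcomp of downstream G run

  # clipping at the contig edge warns but keeps the pair consistent
  expect_warning(
    pr3 <- extract_structure_pairs(
      data.frame(chrom = "chr1", pos = 101L, strand = "+"), g, window = 150L),
    "clipped")
  expect_equal(Biostrings::width(pr3)[1], Biostrings::width(pr3)[2])
  # center base not A after strand resolution is an error
  expect_error(extract_structure_pairs(
    data.frame(chrom = "chr1", pos = 100L, strand = "+"), g, window = 5L),
    "not A")
})

test_that("delta-MFE harness summarizes external folding results", {
  mfe <- data.frame(key = c("a", "b", "c"),
                    mfe_unedited = c(-10, -20, -30),
                    mfe_edited = c(-12.5, -20.5, -35))
  s <- summarize_delta_mfe(mfe, threshold = 1)
  expect_equal(s$table$delta_mfe, c(-2.5, -0.5, -5))
  expect_equal(s$fraction_above, 2 / 3)
  expect_error(summarize_delta_mfe(mfe[, 1:2]), "mfe_edited")
})
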