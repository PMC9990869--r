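# independent oracle: exhaustive enumeration of the hypergeometric
# distribution over all 2x2 tables with the observed margins
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  x <- lo:hi
  pr <- dhyper(x, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

test_that("group classification respects the coverage boundary rules", {
  samples <- make_samples(12)
  tid <- samples$sample_id[samples$condition == "tumor"]
  nid <- samples$sample_id[samples$condition == "normal"]
  lv <- function(t, n) {
    v <- c(rep(0.3, t), rep(0.2, n))
    names(v) <- c(tid[seq_len(t)], nid[seq_len(n)])
    v
  }
  em <- make_editing_matrix(list(
    "chr1:100" = lv(12, 11),   # shared
    "chr1:200" = lv(10, 10),   # shared at the inclusive boundary
    "chr1:300" = lv(10, 9),    # below shared rule in normal -> dropped
    "chr1:400" = lv(5, 0),     # tumor-specific
    "chr1:500" = lv(4, 0),     # tumor-specific at the boundary
    "chr1:600" = lv(3, 0),     # below the specific rule -> dropped
    "chr1:700" = lv(0, 4)),    # normal-specific
    samples)
  g <- classify_groups(em)
  expect_equal(g$group,
               c("shared", "shared", "dropped", "tumor_specific",
                 "tumor_specific", "dropped", "normal_specific"))
  # strict '>' reading is selectable
  gs <- classify_groups(em, shared_strict = TRUE)
  expect_equal(gs$group[2], "dropped")
  expect_equal(gs$group[1], "shared")

  # conservation: groups plus dropped partition the matrix
  expect_equal(sum(table(g$group)), nrow(em$sites))
  expect_true(all(!is.na(g$drop_reason[g$group == "dropped"])))
})

test_that("Fisher p-values match exhaustive hypergeometric enumeration", {
  # identical proportions give p = 1
  expect_equal(fisher_differential(10, 90, 10, 90)$p, 1.0)
  # a complete flip has an analytically tiny tail
  expect_lt(fisher_differential(100, 0, 0, 100)$p, 1e-20)
  # frozen spec example against the oracle
  expect_equal(fisher_differential(30, 70, 10, 90)$p,
               fisher_oracle(30, 70, 10, 90), tolerance = 1e-12)
  # zero-margin tables are degenerate with p = 1
  r <- fisher_differential(0, 0, 5, 5)
  expect_equal(r$p, 1)
  expect_true(r$degenerate)

  # 200 random tables with margins <= 200
  set.seed(123)
  for (i in 1:200) {
    a <- rbinom(1, 100, 0.3); b <- rbinom(1, 100, 0.5)
    c_ <- rbinom(1, 100, 0.3); d <- rbinom(1, 100, 0.5)
    if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0)
      next
    expect_equal(fisher_differential(a, b, c_, d)$p,
                 fisher_oracle(a, b, c_, d), tolerance = 1e-9,
                 info = paste(a, b, c_, d))
  }
})

test_that("the DRE table pools counts and flags significance", {
  samples <- make_samples(10)
  tid <- samples$sample_id[samples$condition == "tumor"]
  nid <- samples$sample_id[samples$condition == "normal"]
  lv_all <- function(t_level, n_level)
    setNames(c(rep(t_level, 10), rep(n_level, 10)), c(tid, nid))
  em <- make_editing_matrix(list(
    "chr1:100" = lv_all(0.4, 0.1),            # strong difference
    "chr1:200" = lv_all(0.2, 0.2),            # no difference
    "chr1:300" = setNames(rep(0.3, 5), tid[1:5])),  # tumor-specific
    samples)
  dre <- dre_table(em)
  expect_equal(dre$group, c("shared", "shared", "tumor_specific"))
  expect_equal(dre$tumor_edited[1], 10 * 20)   # 0.4 * depth 50 pooled
  expect_true(dre$significant[1])
  expect_false(dre$significant[2])
  expect_true(dre$is_dre[3])                   # specific sites are DREs
  expect_false(dre$is_dre[2])
  expect_equal(dre$mean_level_tumor[1], 0.4)
  # specific-group site: zero-margin pooled table is degenerate
  expect_true(dre$degenerate[3])
})

test_that("per-sample summaries and paired tests behave at the boundaries", {
  samples <- make_samples(10)
  tid <- samples$sample_id[samples$condition == "tumor"]
  nid <- samples$sample_id[samples$condition == "normal"]
  # planted shift +0.1 with sd 0.01: paired t is decisive
  set.seed(5)
  lv <- lapply(1:8, function(i)
    setNames(c(rnorm(10, 0.35, 0.01), rnorm(10, 0.25, 0.01)),
             c(tid, nid)))
  names(lv) <- sprintf("chr1:%d", 100 * (1:8))
  em <- make_editing_matrix(lv, samples)
  dre <- dre_table(em)
  s <- summarize_dre(em, dre)
  expect_equal(nrow(s$per_sample), 20L)
  ml <- s$tests[s$tests$quantity == "mean_level", ]
  expect_lt(ml$p, 0.001)
  expect_equal(ml$df, 9)

  # identical tumor and normal levels: t = 0, p = 1
  lv_eq <- lapply(1:4, function(i)
    setNames(rep(0.3, 20), c(tid, nid)))
  names(lv_eq) <- sprintf("chr1:%d", 100 * (1:4))
  em_eq <- make_editing_matrix(lv_eq, samples)
  s_eq <- summarize_dre(em_eq, dre_table(em_eq))
  expect_equal(s_eq$tests$p[s_eq$tests$quantity == "mean_level"], 1)

  # a single pair: summaries only, no tests
  s1 <- make_samples(1)
  em1 <- make_editing_matrix(list("chr1:100" = setNames(c(0.4, 0.2),
                                                        s1$sample_id)), s1)
  expect_message(s_one <- summarize_dre(em1, dre_table(em1)), "skipped")
  expect_null(s_one$tests)
  expect_equal(nrow(s_one$per_sample), 2L)
})

test_that("DRE profiles separate tumor from normal samples", {
  sim <- simulate_dataset(small_cfg(seed = 17L))
  em <- call_editing(sim$rna, sim$dna, sim$samples,
                     snp_mask = as_snp_mask(sim$truth$snps),
                     ann = sim$reference$annotation)
  dre <- dre_table(em)
  hm <- dre_heatmap_matrix(em, dre)
  expect_identical(attr(hm, "missing_policy"), "missing")
  expect_true(anyNA(hm))
  hz <- dre_heatmap_matrix(em, dre, zero_fill = TRUE)
  expect_false(anyNA(hz))

  cl <- cluster_samples(hz, k = 2)
  cond <- sim$samples$condition[match(names(cl), sim$samples$sample_id)]
  purity <- max(mean(cond[cl == 1] == "tumor") +
                  mean(cond[cl == 2] == "normal"),
                mean(cond[cl == 1] == "normal") +
                  mean(cond[cl == 2] == "tumor")) / 2
  expect_gte(purity, 0.9)

  # no DREs and one DRE edge cases
  dre0 <- dre; dre0$is_dre <- FALSE
  expect_equal(nrow(dre_heatmap_matrix(em, dre0)), 0L)
  dre1 <- dre; dre1$is_dre <- c(TRUE, rep(FALSE, nrow(dre) - 1L))
  expect_equal(nrow(dre_heatmap_matrix(em, dre1)), 1L)
})
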