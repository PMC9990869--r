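## Differential-editing layer: three-mode classification and pooled Fisher
## exact tests.

#' Classify sites into shared / tumor-specific / normal-specific groups
#'
#' A site observed in both conditions with per-condition sample coverage
#' at or above `min_shared_cov` is `shared`; a site observed in only one
#' condition with coverage at or above `min_specific_cov` there is
#' `tumor_specific` or `normal_specific`; everything else is `dropped`
#' with a reason.
#'
#' @param em An `editing_matrix`.
#' @param min_shared_cov Per-condition coverage for the shared group
#'   (inclusive by default; set `shared_strict = TRUE` for a strict
#'   greater-than reading).
#' @param min_specific_cov Coverage in the present condition for the
#'   specific groups.
#' @param shared_strict Use `> min_shared_cov` instead of `>=`.
#' @return A data frame: `key`, `cov_tumor`, `cov_normal`, `group`,
#'   `drop_reason`.
#' @export
classify_groups <- function(em, min_shared_cov = 10L, min_specific_cov = 4L,
                            shared_strict = FALSE) {
  s <- em$sites
  ct <- s$cov_tumor; cn <- s$cov_normal
  shared_ok <- if (shared_strict) ct > min_shared_cov & cn > min_shared_cov
               else ct >= min_shared_cov & cn >= min_shared_cov
  group <- rep("dropped", nrow(s))
  reason <- rep(NA_character_, nrow(s))
  group[ct > 0L & cn > 0L & shared_ok] <- "shared"
  group[cn == 0L & ct >= min_specific_cov] <- "tumor_specific"
  group[ct == 0L & cn >= min_specific_cov] <- "normal_specific"
  dropped <- group == "dropped"
  reason[dropped & ct > 0L & cn > 0L] <- "shared_coverage_below_threshold"
  reason[dropped & (cn == 0L | ct == 0L)] <- "specific_coverage_below_threshold"
  reason[dropped & ct == 0L & cn == 0L] <- "no_observation"
  data.frame(key = s$key, cov_tumor = ct, cov_normal = cn, group = group,
             drop_reason = reason, stringsAsFactors = FALSE)
}

#' Two-sided Fisher exact test on pooled editing counts
#'
#' One 2x2 table per site: tumor edited/unedited read counts versus normal
#' edited/unedited, pooled over the samples in which the site passed. A
#' zero-margin table is degenerate and reported with p = 1.
#'
#' @param tumor_edited,tumor_unedited,normal_edited,normal_unedited
#'   Parallel non-negative integer vectors.
#' @return Data frame with `p` and `degenerate`.
#' @export
fisher_differential <- function(tumor_edited, tumor_unedited,
                                normal_edited, normal_unedited) {
  n <- length(tumor_edited)
  p <- rep(NA_real_, n)
  degenerate <- rep(FALSE, n)
  for (i in seq_len(n)) {
    tab <- matrix(c(tumor_edited[i], tumor_unedited[i],
                    normal_edited[i], normal_unedited[i]), 2L, 2L)
    if (anyNA(tab) || any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
      p[i] <- 1
      degenerate[i] <- TRUE
    } else {
      p[i] <- fisher.test(tab)$p.value
    }
  }
  data.frame(p = p, degenerate = degenerate)
}

#' Build the differential-editing (DRE) table
#'
#' Pools edited/unedited read counts per condition, runs the per-site
#' Fisher test, and flags DREs: shared-group sites significant at `alpha`
#' (no multiplicity correction, a BH-adjusted column is emitted
#' alongside), plus every coverage-qualified specific-group site.
#'
#' @param em An `editing_matrix`.
#' @param groups Output of [classify_groups()]; computed with defaults if
#'   missing.
#' @param alpha Significance level for the shared group.
#' @return A `dre_table` data frame: site annotation, group, pooled
#'   counts, per-condition mean levels, `fisher_p`, `bh_q`,
#'   `significant`, `is_dre`, and placeholder `fst`/`known` columns.
#' @export
dre_table <- function(em, groups = classify_groups(em), alpha = 0.05) {
  s <- em$sites
  tumor_cols <- em$samples$condition == "tumor"
  pool <- function(m, cols) {
    v <- rowSums(m[, cols, drop = FALSE], na.rm = TRUE)
    as.integer(round(v))
  }
  te <- pool(em$alt, tumor_cols); tu <- pool(em$ref, tumor_cols)
  ne <- pool(em$alt, !tumor_cols); nu <- pool(em$ref, !tumor_cols)
  mean_lv <- function(cols)
    rowMeans(em$level[, cols, drop = FALSE], na.rm = TRUE)
  out <- data.frame(
    key = s$key, chrom = s$chrom, pos = s$pos, strand = s$strand,
    gene_id = s$gene_id, region = s$region, edit_type = s$edit_type,
    group = groups$group[match(s$key, groups$key)],
    cov_tumor = s$cov_tumor, cov_normal = s$cov_normal,
    tumor_edited = te, tumor_unedited = tu,
    normal_edited = ne, normal_unedited = nu,
    mean_level_tumor = ifelse(s$cov_tumor > 0, mean_lv(tumor_cols), NA),
    mean_level_normal = ifelse(s$cov_normal > 0, mean_lv(!tumor_cols), NA),
    stringsAsFactors = FALSE)
  classified <- out$group != "dropped"
  ft <- fisher_differential(te, tu, ne, nu)
  out$fisher_p <- ifelse(classified, ft$p, NA)
  out$degenerate <- ifelse(classified, ft$degenerate, NA)
  out$bh_q <- NA_real_
  sh <- which(out$group == "shared")
  out$bh_q[sh] <- p.adjust(out$fisher_p[sh], method = "BH")
  out$significant <- !is.na(out$fisher_p) & out$fisher_p < alpha
  out$is_dre <- (out$group == "shared" & out$significant) |
    out$group %in% c("tumor_specific", "normal_specific")
  out$fst <- NA_real_
  out$known <- NA
  class(out) <- c("dre_table", "data.frame")
  out
}

#' Per-sample and per-gene DRE summaries with paired tests
#'
#' Per sample: mean editing level over DREs observed in that sample and
#' the number of DREs observed. Tumor-versus-normal paired two-sided
#' t-tests on both quantities (df = number of pairs - 1). Per gene: DRE
#' count per condition.
#'
#' @param em An `editing_matrix` whose `samples` carry a `pair` column.
#' @param dre A `dre_table`.
#' @return A list: `per_sample`, `tests` (NULL when fewer than 2 pairs),
#'   `per_gene`.
#' @export
summarize_dre <- function(em, dre) {
  keys <- dre$key[dre$is_dre]
  idx <- match(keys, rownames(em$level))
  lv <- em$level[idx, , drop = FALSE]
  per_sample <- data.frame(
    em$samples,
    mean_level = colMeans(lv, na.rm = TRUE),
    dre_count = colSums(!is.na(lv)),
    stringsAsFactors = FALSE)
  per_sample$mean_level[is.nan(per_sample$mean_level)] <- NA
  tests <- NULL
  pairs <- unique(em$samples$pair)
  if (!is.null(em$samples$pair) && length(pairs) >= 2L) {
    paired_t <- function(col) {
      t_val <- per_sample[[col]][match(
        paste(pairs, "tumor"),
        paste(per_sample$pair, per_sample$condition))]
      n_val <- per_sample[[col]][match(
        paste(pairs, "normal"),
        paste(per_sample$pair, per_sample$condition))]
      ok <- complete.cases(t_val, n_val)
      if (sum(ok) < 2L || sd(t_val[ok] - n_val[ok]) == 0)
        return(data.frame(statistic = 0, df = sum(ok) - 1L, p = 1))
      tt <- t.test(t_val[ok], n_val[ok], paired = TRUE)
      data.frame(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value)
    }
    tests <- rbind(cbind(quantity = "mean_level", paired_t("mean_level")),
                   cbind(quantity = "dre_count", paired_t("dre_count")))
  } else {
    message("summarize_dre: fewer than 2 pairs, paired tests skipped")
  }
  d <- dre[dre$is_dre & !is.na(dre$gene_id), , drop = FALSE]
  per_gene <- if (nrow(d)) {
    agg <- aggregate(cbind(tumor = cov_tumor > 0, normal = cov_normal > 0)
                     ~ gene_id, data = d, FUN = sum)
    names(agg) <- c("gene_id", "n_sites_tumor", "n_sites_normal")
    agg
  } else {
    data.frame(gene_id = character(), n_sites_tumor = integer(),
               n_sites_normal = integer(), stringsAsFactors = FALSE)
  }
  list(per_sample = per_sample, tests = tests, per_gene = per_gene)
}

#' Editing-level matrix over DREs for heatmaps and clustering
#'
#' @param em An `editing_matrix`.
#' @param dre A `dre_table`.
#' @param zero_fill Export missing observations as 0 instead of NA. The
#'   default keeps them missing: zero-filling conflates "not edited" with
#'   "not covered". The policy used is recorded in the `missing_policy`
#'   attribute.
#' @return Sites x samples numeric matrix restricted to DREs.
#' @export
dre_heatmap_matrix <- function(em, dre, zero_fill = FALSE) {
  keys <- dre$key[dre$is_dre]
  m <- em$level[match(keys, rownames(em$level)), , drop = FALSE]
  rownames(m) <- keys
  if (zero_fill) m[is.na(m)] <- 0
  attr(m, "missing_policy") <- if (zero_fill) "zero" else "missing"
  m
}

#' Two-group sample clustering on a DRE level matrix
#'
#' Average-linkage hierarchical clustering on Euclidean distances between
#' sample columns (missing values zero-filled first), cut at `k` clusters.
#' A report-layer convenience for checking that DRE profiles separate
#' tumor from normal samples.
#'
#' @param m Matrix from [dre_heatmap_matrix()].
#' @param k Number of clusters.
#' @return Integer cluster assignment named by sample.
#' @export
cluster_samples <- function(m, k = 2L) {
  m[is.na(m)] <- 0
  hc <- hclust(dist(t(m)), method = "average")
  cutree(hc, k = k)
}
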