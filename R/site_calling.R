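## Candidate RNA-DNA difference calling and the high-confidence filter
## cascade.  All thresholds are per sample and per site: a site may pass in
## some samples and be missing in others.

#' Default filter thresholds
#'
#' `min_base_quality` (mean Phred at the site), `min_depth` (RNA reads),
#' editing level in `[min_level, max_level)`, at most one RNA alternative
#' allele (a non-reference base with at least `multi_allele_min_count`
#' reads counts as an allele), DNA-variant evidence (alternative fraction
#' above `dna_alt_frac` together with at least `dna_alt_count` reads), and
#' a minimum DNA depth for a position to count as genotyped.
#'
#' @return Named list of thresholds.
#' @export
default_thresholds <- function() {
  list(min_base_quality = 30, min_depth = 10L, min_level = 0.1,
       max_level = 1, multi_allele_min_count = 2L,
       dna_alt_frac = 0.01, dna_alt_count = 2L, min_dna_depth = 5L)
}

REMOVAL_FLAGS <- c("low_quality_removed", "low_depth_removed",
                   "multi_allelic_removed", "dna_variant_removed",
                   "snp_removed", "level_out_of_range_removed")

#' Call candidate RNA-DNA differences for one sample
#'
#' A candidate is any position with at least one non-reference RNA read
#' and a genotyped DNA position (DNA depth at or above `min_dna_depth`).
#' RNA positions absent from the DNA table (or with insufficient DNA
#' depth) are excluded and counted in the `n_no_dna_evidence` attribute.
#'
#' @param rna,dna `site_counts` tables for the same sample.
#' @param min_dna_depth Minimum DNA depth for a position to be genotyped.
#' @return A `candidate` data frame: per position, RNA ref/alt counts, the
#'   top alternative base, the number of alternative alleles, the editing
#'   level `alt/(ref+alt)`, and the DNA alternative count/fraction.
#' @export
call_candidates <- function(rna, dna, min_dna_depth = 5L) {
  stopifnot(inherits(rna, "site_counts"), inherits(dna, "site_counts"))
  if (!identical(attr(rna, "sample_id"), attr(dna, "sample_id")))
    warning("RNA and DNA tables carry different sample_ids")
  cm <- as.matrix(rna[, paste0("count_", BASES)])
  ridx <- match(rna$ref, BASES)
  n <- nrow(rna)
  if (n == 0L) return(empty_candidates(attr(rna, "sample_id")))
  ref_count <- cm[cbind(seq_len(n), ridx)]
  altm <- cm
  altm[cbind(seq_len(n), ridx)] <- -1L   # mask the reference column
  aidx <- max.col(altm, ties.method = "first")
  alt_count <- altm[cbind(seq_len(n), aidx)]
  has_alt <- alt_count >= 1L
  ## alleles with real support; the top alternative always counts
  n_alleles <- rowSums(altm >= default_thresholds()$multi_allele_min_count)
  n_alleles <- pmax(n_alleles, as.integer(has_alt))

  dkey <- site_key(dna$chrom, dna$pos)
  dm <- as.matrix(dna[, paste0("count_", BASES)])
  d_ref_count <- dm[cbind(seq_len(nrow(dna)), match(dna$ref, BASES))]
  d_alt_total <- dna$depth - d_ref_count
  idx <- match(site_key(rna$chrom, rna$pos), dkey)
  genotyped <- !is.na(idx) & dna$depth[idx] >= min_dna_depth

  keep <- which(has_alt & genotyped)
  n_no_dna <- sum(has_alt & !genotyped)
  out <- data.frame(
    chrom = rna$chrom[keep], pos = rna$pos[keep], ref = rna$ref[keep],
    alt = BASES[aidx[keep]],
    strand_hint = rna$strand[keep],
    mean_quality = rna$mean_quality[keep],
    rna_depth = rna$depth[keep],
    rna_ref_count = ref_count[keep],
    rna_alt_count = alt_count[keep],
    n_alt_alleles = n_alleles[keep],
    level = alt_count[keep] / (ref_count[keep] + alt_count[keep]),
    dna_depth = dna$depth[idx[keep]],
    dna_alt_count = d_alt_total[idx[keep]],
    dna_alt_frac = d_alt_total[idx[keep]] / dna$depth[idx[keep]],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, sample_id = attr(rna, "sample_id"),
            n_no_dna_evidence = n_no_dna,
            class = c("candidates", "data.frame"))
}

empty_candidates <- function(sample_id) {
  out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                    alt = character(), strand_hint = character(),
                    mean_quality = numeric(), rna_depth = integer(),
                    rna_ref_count = integer(), rna_alt_count = integer(),
                    n_alt_alleles = integer(), level = numeric(),
                    dna_depth = integer(), dna_alt_count = integer(),
                    dna_alt_frac = numeric(), stringsAsFactors = FALSE)
  structure(out, sample_id = sample_id, n_no_dna_evidence = 0L,
            class = c("candidates", "data.frame"))
}

#' Apply the high-confidence filter cascade
#'
#' Filters are applied in a fixed order -- base quality, depth,
#' multi-allelic, DNA variant, SNP, editing-level range -- and each
#' rejected candidate keeps the flag of the first filter it failed, so the
#' flags partition the candidates.
#'
#' @param cands A `candidates` table from [call_candidates()].
#' @param snp_mask Optional `snp_mask` from [read_snp_mask()].
#' @param thresholds Threshold list; see [default_thresholds()].
#' @return The candidate table with columns `flag` (a removal flag or
#'   `"passed"`) and `passed`; attribute `filter_log` records every
#'   threshold actually applied and the per-flag counts.
#' @export
apply_filters <- function(cands, snp_mask = NULL,
                          thresholds = default_thresholds()) {
  th <- utils::modifyList(default_thresholds(), as.list(thresholds))
  n <- nrow(cands)
  flag <- rep(NA_character_, n)
  set_flag <- function(flag, fail, name) {
    ifelse(is.na(flag) & fail, name, flag)
  }
  flag <- set_flag(flag, cands$mean_quality < th$min_base_quality,
                   "low_quality_removed")
  flag <- set_flag(flag, cands$rna_depth < th$min_depth,
                   "low_depth_removed")
  flag <- set_flag(flag, cands$n_alt_alleles > 1L, "multi_allelic_removed")
  dna_var <- cands$dna_alt_frac > th$dna_alt_frac &
    cands$dna_alt_count >= th$dna_alt_count
  flag <- set_flag(flag, dna_var, "dna_variant_removed")
  flag <- set_flag(flag, in_snp_mask(snp_mask, cands$chrom, cands$pos),
                   "snp_removed")
  flag <- set_flag(flag, cands$level < th$min_level |
                     cands$level >= th$max_level,
                   "level_out_of_range_removed")
  flag[is.na(flag)] <- "passed"
  out <- cands
  out$flag <- flag
  out$passed <- flag == "passed"
  counts <- table(factor(flag, levels = c(REMOVAL_FLAGS, "passed")))
  attr(out, "filter_log") <- list(thresholds = th, flag_counts = counts)
  class(out) <- c("filtered_candidates", "data.frame")
  out
}

#' Resolve strand and editing type from gene annotation
#'
#' Unstranded pileups report the mismatch on the genomic plus strand. A
#' site inside exactly one gene inherits the gene strand, and the mismatch
#' is complemented for minus-strand genes (a raw T>C in a minus-strand
#' gene is an A>G, i.e. A-to-I, event). Intergenic or gene-ambiguous sites
#' keep strand `"unknown"` and the raw mismatch.
#'
#' @param sites Data frame with `chrom`, `pos`, `ref`, `alt`.
#' @param ann An `annotation_index`, or NULL to skip resolution.
#' @return `sites` with `strand`, `gene_id`, `region` and `edit_type`
#'   columns.
#' @export
resolve_strand <- function(sites, ann = NULL) {
  n <- nrow(sites)
  if (n == 0L) {
    sites$strand <- character()
    sites$gene_id <- character()
    sites$region <- character()
    sites$edit_type <- character()
    return(sites)
  }
  if (is.null(ann)) {
    sites$strand <- rep("unknown", n)
    sites$gene_id <- rep(NA_character_, n)
    sites$region <- rep(NA_character_, n)
    sites$edit_type <- paste0(sites$ref, ">", sites$alt)
    return(sites)
  }
  cls <- classify_positions(ann, sites$chrom, sites$pos)
  resolved <- !is.na(cls$gene_id) & !cls$ambiguous &
    cls$strand %in% c("+", "-")
  strand <- ifelse(resolved, cls$strand, "unknown")
  flip <- resolved & strand == "-"
  ref_res <- ifelse(flip, COMPLEMENT[sites$ref], sites$ref)
  alt_res <- ifelse(flip, COMPLEMENT[sites$alt], sites$alt)
  sites$strand <- strand
  sites$gene_id <- cls$gene_id
  sites$region <- cls$region
  sites$edit_type <- paste0(ref_res, ">", alt_res)
  sites
}

#' Merge per-sample passing sites into an editing matrix
#'
#' Takes the union of passing positions over samples and arranges levels,
#' depths and ref/alt read counts as sites x samples matrices (NA where a
#' site has no passing observation in a sample). Per-condition sample
#' coverage is the number of samples with a passing observation.
#'
#' @param filtered Named list of `filtered_candidates` (one per sample);
#'   names must match `samples$sample_id`.
#' @param samples Data frame with `sample_id`, `condition`
#'   (`"tumor"`/`"normal"`) and optionally `pair`.
#' @param ann Optional `annotation_index` for strand resolution.
#' @return An `editing_matrix`.
#' @export
merge_samples <- function(filtered, samples, ann = NULL) {
  stopifnot(is.list(filtered), all(samples$sample_id %in% names(filtered)))
  passed <- lapply(samples$sample_id, function(id) {
    x <- filtered[[id]]
    x <- x[x$passed, , drop = FALSE]
    if (anyDuplicated(site_key(x$chrom, x$pos)))
      stop_fmt("duplicate (chrom,pos) within sample %s", id)
    x
  })
  all_sites <- unique(do.call(rbind, c(
    lapply(passed, function(x)
      x[, c("chrom", "pos", "ref", "alt"), drop = FALSE]),
    list(make.row.names = FALSE))))
  ## one row per position; if samples disagree on the top alt base keep the
  ## lexicographically first (rare: error reads at a true site)
  key_all <- site_key(all_sites$chrom, all_sites$pos)
  ord <- order(all_sites$chrom, all_sites$pos, all_sites$alt)
  all_sites <- all_sites[ord, , drop = FALSE]
  key_all <- key_all[ord]
  first <- !duplicated(key_all)
  sites <- all_sites[first, , drop = FALSE]
  keys <- key_all[first]
  rownames(sites) <- NULL
  nsite <- nrow(sites)
  nsamp <- nrow(samples)
  mk <- function() matrix(NA_real_, nsite, nsamp,
                          dimnames = list(keys, samples$sample_id))
  level <- depth <- altc <- refc <- mk()
  for (j in seq_len(nsamp)) {
    x <- passed[[j]]
    i <- match(site_key(x$chrom, x$pos), keys)
    level[i, j] <- x$level
    depth[i, j] <- x$rna_depth
    altc[i, j] <- x$rna_alt_count
    refc[i, j] <- x$rna_ref_count
  }
  sites <- resolve_strand(sites, ann)
  sites$key <- keys
  obs <- !is.na(level)
  cov_t <- rowSums(obs[, samples$condition == "tumor", drop = FALSE])
  cov_n <- rowSums(obs[, samples$condition == "normal", drop = FALSE])
  sites$cov_tumor <- as.integer(cov_t)
  sites$cov_normal <- as.integer(cov_n)
  structure(list(sites = sites, samples = samples, level = level,
                 depth = depth, alt = altc, ref = refc),
            class = "editing_matrix")
}

#' @export
print.editing_matrix <- function(x, ...) {
  cat(sprintf("editing_matrix: %d sites x %d samples (%d tumor, %d normal)\n",
              nrow(x$sites), nrow(x$samples),
              sum(x$samples$condition == "tumor"),
              sum(x$samples$condition == "normal")))
  invisible(x)
}

#' Run calling and filtering for a set of samples
#'
#' Convenience wrapper: candidates, filter cascade and merge for matched
#' RNA/DNA tables of many samples.
#'
#' @param rna,dna Named lists of `site_counts` keyed by sample id.
#' @param samples Sample sheet (`sample_id`, `condition`, `pair`).
#' @param snp_mask Optional `snp_mask`.
#' @param ann Optional `annotation_index`.
#' @param thresholds Threshold list; see [default_thresholds()].
#' @param cohort_dna_veto Remove a site from every sample when any sample
#'   shows DNA-variant evidence there. A DNA mutation is a property of
#'   the position, not of one library: a shallow DNA library in one
#'   sample must not let a variant position pass as an editing site.
#' @return An `editing_matrix`; per-sample filter logs are kept in the
#'   `filter_logs` attribute.
#' @export
call_editing <- function(rna, dna, samples, snp_mask = NULL, ann = NULL,
                         thresholds = default_thresholds(),
                         cohort_dna_veto = TRUE) {
  th <- utils::modifyList(default_thresholds(), as.list(thresholds))
  filtered <- lapply(samples$sample_id, function(id) {
    apply_filters(call_candidates(rna[[id]], dna[[id]],
                                  min_dna_depth = th$min_dna_depth),
                  snp_mask = snp_mask, thresholds = th)
  })
  names(filtered) <- samples$sample_id
  if (cohort_dna_veto) {
    veto <- unique(unlist(lapply(filtered, function(x)
      site_key(x$chrom, x$pos)[x$flag == "dna_variant_removed"])))
    if (length(veto)) {
      filtered <- lapply(filtered, function(x) {
        hit <- x$passed & site_key(x$chrom, x$pos) %in% veto
        x$flag[hit] <- "dna_variant_removed"
        x$passed[hit] <- FALSE
        x
      })
    }
  }
  em <- merge_samples(filtered, samples, ann = ann)
  attr(em, "filter_logs") <- lapply(filtered, attr, "filter_log")
  em
}
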