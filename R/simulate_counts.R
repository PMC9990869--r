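## Count-level simulation on top of a simulate_reference() scaffold.

#' Simulate matched RNA/DNA base counts and the ground-truth set
#'
#' Draws per-site editing levels hierarchically (site-level Beta mean,
#' sample-level Beta around it, scaled by each sample's ADAR-coupled
#' global multiplier), negative-binomial depths and per-base errors, and
#' emits one RNA and one DNA `site_counts` table per sample, plus a gene
#' expression matrix, a differential-splicing event table, and the
#' complete truth set.
#'
#' At a planted site the RNA alternative-base count is
#' Binomial(depth, phi) with phi the sample's true level clipped to
#' [0, 0.99]; DNA carries error-rate mismatches only. Germline SNPs are
#' variant in the DNA (and RNA) of every sample; somatic DNA variants are
#' variant in tumor samples only; background positions carry error-only
#' mismatches.
#'
#' @param ref A `sim_reference` from [simulate_reference()].
#' @return A `sim_data` list: `samples`, `rna`/`dna` (named lists of
#'   `site_counts`), `expression` (genes x samples matrix including ADAR,
#'   ADARB1, ADARB2 rows), `splicing` (event table), `truth`.
#' @export
simulate_counts <- function(ref) {
  stopifnot(inherits(ref, "sim_reference"))
  cfg <- ref$cfg
  set.seed(cfg$seed + 1L)
  n <- cfg$n_pairs
  samples <- data.frame(
    sample_id = c(sprintf("T%02d", seq_len(n)), sprintf("N%02d", seq_len(n))),
    pair = rep(sprintf("P%02d", seq_len(n)), 2L),
    condition = rep(c("tumor", "normal"), each = n),
    stringsAsFactors = FALSE)
  ns_amp <- nrow(samples)
  a_dev <- rnorm(ns_amp, 0, cfg$adar_sd) +
    (samples$condition == "tumor") * cfg$adar_tumor_lfc
  samples$adar1 <- round(50 * 2^a_dev, 4)
  samples$adar2 <- round(20 * 2^rnorm(ns_amp, 0, 0.3), 4)
  samples$adar3 <- round(5 * 2^rnorm(ns_amp, 0, 0.3), 4)
  samples$multiplier <- 2^(cfg$adar_coupling * a_dev)

  mu <- site_condition_means(cfg, ref$sites)
  phi <- per_sample_levels(cfg, mu, samples)

  tables <- draw_count_tables(cfg, ref, phi, samples)
  expression <- simulate_expression(cfg, ref, samples)
  splicing <- simulate_splicing(cfg, ref, mu)

  truth_sites <- cbind(ref$sites,
                       data.frame(true_tumor = mu$tumor,
                                  true_normal = mu$normal))
  truth <- list(sites = truth_sites, samples = samples, snps = ref$snps,
                dna_variants = ref$dna_variants,
                de_genes = expression$de_genes,
                splicing = splicing$truth, phi = phi)
  structure(list(cfg = cfg, reference = ref, samples = samples,
                 rna = tables$rna, dna = tables$dna,
                 expression = expression$matrix,
                 splicing = splicing$events, truth = truth),
            class = "sim_data")
}

#' One-call simulation
#'
#' @param cfg A [sim_config()].
#' @return A `sim_data` object (see [simulate_counts()]).
#' @export
simulate_dataset <- function(cfg) simulate_counts(simulate_reference(cfg))

site_condition_means <- function(cfg, sites) {
  ns <- nrow(sites)
  a <- cfg$beta_shape[1L]; b <- cfg$beta_shape[2L]
  mu_t <- mu_n <- numeric(ns)
  base <- if (ns) rbeta(ns, a, b) else numeric()
  sh <- which(sites$group == "shared")
  diff_idx <- sh[seq_len(cfg$n_diff_shared)]
  fst_idx <- sh[cfg$n_diff_shared + seq_len(cfg$n_fst_sites)]
  null_idx <- setdiff(sh, c(diff_idx, fst_idx))
  mu_t[null_idx] <- mu_n[null_idx] <- base[null_idx]
  if (length(diff_idx)) {
    mu_n[diff_idx] <- pmin(base[diff_idx], 0.75)
    mu_t[diff_idx] <- mu_n[diff_idx] + cfg$diff_effect
  }
  if (length(fst_idx)) {
    mu_t[fst_idx] <- cfg$fst_freqs[["tumor"]]
    mu_n[fst_idx] <- cfg$fst_freqs[["normal"]]
  }
  ts <- sites$group == "tumor_specific"
  mu_t[ts] <- base[ts]; mu_n[ts] <- 0
  nsp <- sites$group == "normal_specific"
  mu_n[nsp] <- base[nsp]; mu_t[nsp] <- 0
  list(tumor = mu_t, normal = mu_n)
}

per_sample_levels <- function(cfg, mu, samples) {
  ns <- length(mu$tumor)
  phi <- matrix(0, ns, nrow(samples),
                dimnames = list(NULL, samples$sample_id))
  if (ns == 0L) return(phi)
  rho <- cfg$sample_dispersion
  kappa <- if (rho > 0) (1 - rho) / rho else Inf
  for (j in seq_len(nrow(samples))) {
    m <- if (samples$condition[j] == "tumor") mu$tumor else mu$normal
    pos <- which(m > 0)
    lv <- numeric(ns)
    if (length(pos)) {
      lv[pos] <- if (is.finite(kappa))
        rbeta(length(pos), m[pos] * kappa, (1 - m[pos]) * kappa)
      else m[pos]
    }
    phi[, j] <- pmin(lv * samples$multiplier[j], 0.99)
  }
  phi
}

draw_count_tables <- function(cfg, ref, phi, samples) {
  sites <- ref$sites
  pos_df <- rbind(
    if (nrow(sites)) data.frame(chrom = sites$chrom, pos = sites$pos,
                                type = "site", stringsAsFactors = FALSE),
    if (nrow(ref$snps)) data.frame(chrom = ref$snps$chrom,
                                   pos = ref$snps$pos, type = "snp",
                                   stringsAsFactors = FALSE),
    if (nrow(ref$dna_variants)) data.frame(chrom = ref$dna_variants$chrom,
                                           pos = ref$dna_variants$pos,
                                           type = "dnav",
                                           stringsAsFactors = FALSE),
    if (nrow(ref$background)) data.frame(chrom = ref$background$chrom,
                                         pos = ref$background$pos,
                                         type = "bg",
                                         stringsAsFactors = FALSE))
  np <- nrow(pos_df)
  ref_base <- genome_base(ref$genome, pos_df$chrom, pos_df$pos)
  alt_base <- rep(NA_character_, np)
  is_site <- pos_df$type == "site"
  if (any(is_site))
    alt_base[is_site] <- ifelse(sites$strand == "-", "C", "G")
  if (any(pos_df$type == "snp")) alt_base[pos_df$type == "snp"] <- ref$snps$alt
  if (any(pos_df$type == "dnav"))
    alt_base[pos_df$type == "dnav"] <- ref$dna_variants$alt
  snp_gt <- numeric(np)
  if (any(pos_df$type == "snp")) snp_gt[pos_df$type == "snp"] <- ref$snps$gt

  size <- 1 / cfg$depth_dispersion
  rna <- dna <- stats::setNames(vector("list", nrow(samples)),
                                samples$sample_id)
  for (j in seq_len(nrow(samples))) {
    tumor <- samples$condition[j] == "tumor"
    for (assay in c("RNA", "DNA")) {
      f <- numeric(np)
      f[pos_df$type == "snp"] <- snp_gt[pos_df$type == "snp"]
      if (tumor) f[pos_df$type == "dnav"] <- 0.35
      if (assay == "RNA" && any(is_site)) f[is_site] <- phi[, j]
      mu_d <- if (assay == "RNA") cfg$depth_mean else cfg$dna_depth_mean
      depth <- rnbinom(np, size = size, mu = mu_d)
      n_alt <- rbinom(np, depth, f)
      n_err <- rbinom(np, depth - n_alt, cfg$error_rate)
      e1 <- rbinom(np, n_err, 1 / 3)
      e2 <- rbinom(np, n_err - e1, 1 / 2)
      e3 <- n_err - e1 - e2
      cm <- matrix(0L, np, 4L, dimnames = list(NULL, BASES))
      ridx <- match(ref_base, BASES)

      cm[cbind(seq_len(np), ridx)] <- depth - n_alt - n_err
      for (bi in 1:4) {
        rows <- which(ridx == bi)
        if (!length(rows)) next
        ob <- setdiff(1:4, bi)
        cm[rows, ob[1L]] <- cm[rows, ob[1L]] + e1[rows]
        cm[rows, ob[2L]] <- cm[rows, ob[2L]] + e2[rows]
        cm[rows, ob[3L]] <- cm[rows, ob[3L]] + e3[rows]
      }
      aidx <- match(alt_base, BASES)
      has_alt <- !is.na(aidx)
      cm[cbind(which(has_alt), aidx[has_alt])] <-
        cm[cbind(which(has_alt), aidx[has_alt])] + n_alt[has_alt]
      keep <- depth >= 1L
      df <- data.frame(
        chrom = pos_df$chrom[keep], pos = pos_df$pos[keep],
        ref = ref_base[keep], strand = "unknown",
        depth = depth[keep],
        mean_quality = round(runif(sum(keep), 33, 40), 1),
        count_A = cm[keep, "A"], count_C = cm[keep, "C"],
        count_G = cm[keep, "G"], count_T = cm[keep, "T"],
        stringsAsFactors = FALSE)
      df <- df[order(df$chrom, df$pos), , drop = FALSE]
      rownames(df) <- NULL
      tab <- new_site_counts(df, samples$sample_id[j], assay)
      if (assay == "RNA") rna[[j]] <- tab else dna[[j]] <- tab
    }
  }
  list(rna = rna, dna = dna)
}

simulate_expression <- function(cfg, ref, samples) {
  ann <- ref$annotation
  gids <- if (length(ann$genes)) ann$genes$gene_id else character()
  de_genes <- data.frame(gene_id = character(), true_lfc = numeric(),
                         stringsAsFactors = FALSE)
  mat <- NULL
  if (length(gids)) {
    base <- 100 * 2^rnorm(length(gids), 0, 1)
    lfc <- setNames(numeric(length(gids)), gids)
    carriers <- unique(ref$sites$gene_id[!is.na(ref$sites$gene_id)])
    n_de <- min(cfg$n_de_genes, length(carriers))
    if (n_de > 0L) {
      chosen <- sample(carriers, n_de)
      lfc[chosen] <- cfg$de_lfc * rep_len(c(1, -1), n_de)
      de_genes <- data.frame(gene_id = chosen, true_lfc = lfc[chosen],
                             stringsAsFactors = FALSE)
    }
    tumor <- samples$condition == "tumor"
    mat <- outer(base, rep(1, nrow(samples))) *
      2^(outer(lfc, as.numeric(tumor))) *
      2^matrix(rnorm(length(gids) * nrow(samples), 0, 0.2),
               length(gids))
    dimnames(mat) <- list(gids, samples$sample_id)
  }
  adar <- rbind(ADAR = samples$adar1, ADARB1 = samples$adar2,
                ADARB2 = samples$adar3)
  colnames(adar) <- samples$sample_id
  mat <- if (is.null(mat)) adar else rbind(mat, adar)
  list(matrix = round(mat, 4), de_genes = de_genes)
}

simulate_splicing <- function(cfg, ref, mu) {
  empty <- data.frame(
    event_id = character(), gene_id = character(), chrom = character(),
    strand = character(), event_type = character(), exon_start = integer(),
    exon_end = integer(), upstream_start = integer(),
    upstream_end = integer(), downstream_start = integer(),
    downstream_end = integer(), inc_diff = numeric(), pvalue = numeric(),
    stringsAsFactors = FALSE)
  genes <- ref$annotation$genes
  n_ev <- if (length(genes) == 0L) 0L else cfg$n_splice_events
  if (n_ev == 0L)
    return(list(events = empty,
                truth = cbind(empty, contains_site = logical(),
                              anchor = character())))
  sites <- ref$sites
  n_anchor <- round(cfg$splice_overlap * n_ev)
  eligible <- which(sites$group %in% c("tumor_specific", "normal_specific") &
                      !is.na(sites$gene_id) &
                      pmax(mu$tumor, mu$normal) >= 0.2)
  if (length(eligible) < n_anchor)
    stop_fmt("simulate_counts: only %d sites eligible to anchor %d splicing events",
             length(eligible), n_anchor)
  anchors <- sample(eligible, n_anchor)
  planted_keys <- c(site_key(sites$chrom, sites$pos),
                    site_key(ref$snps$chrom, ref$snps$pos),
                    site_key(ref$dna_variants$chrom, ref$dna_variants$pos))
  gene_span <- data.frame(
    gene_id = genes$gene_id,
    chrom = as.character(GenomicRanges::seqnames(genes)),
    start = GenomicRanges::start(genes), end = GenomicRanges::end(genes),
    strand = as.character(GenomicRanges::strand(genes)),
    stringsAsFactors = FALSE)
  types <- c("SE", "A5SS", "A3SS", "MXE", "RI")
  rows <- vector("list", n_ev)
  for (i in seq_len(n_ev)) {
    if (i <= n_anchor) {
      s <- anchors[i]
      g <- gene_span[gene_span$gene_id == sites$gene_id[s], ]
      lo <- max(g$start, sites$pos[s] - sample(200:600, 1L))
      hi <- min(g$end, sites$pos[s] + sample(200:600, 1L))
    } else {
      repeat {
        g <- gene_span[sample(nrow(gene_span), 1L), ]
        c0 <- sample(seq(g$start, g$end), 1L)
        lo <- max(g$start, c0 - sample(200:600, 1L))
        hi <- min(g$end, c0 + sample(200:600, 1L))
        span_keys <- site_key(g$chrom, lo:hi)
        if (!any(span_keys %in% planted_keys)) break
      }
    }
    w <- hi - lo + 1L
    b1 <- lo + w %/% 3L
    b2 <- lo + (2L * w) %/% 3L
    rows[[i]] <- data.frame(
      event_id = sprintf("EV%04d", i), gene_id = g$gene_id, chrom = g$chrom,
      strand = g$strand, event_type = sample(types, 1L,
        prob = c(0.5, 0.12, 0.12, 0.13, 0.13)),
      exon_start = b1, exon_end = b2 - 1L,
      upstream_start = lo, upstream_end = b1 - 1L,
      downstream_start = b2, downstream_end = hi,
      inc_diff = round(runif(1L, -0.5, 0.5), 4),
      pvalue = signif(10^runif(1L, -6, -2), 4),
      stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, rows)
  truth <- events
  truth$contains_site <- seq_len(n_ev) <= n_anchor
  truth$anchor <- NA_character_
  if (n_anchor > 0L)
    truth$anchor[seq_len(n_anchor)] <-
      site_key(sites$chrom[anchors], sites$pos[anchors])
  list(events = events, truth = truth)
}
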