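## Synthetic paired tumor/normal editing data with planted ground truth.
##
## The generator emulates the data regime the pipeline is built for:
## matched RNA/DNA per-site base counts over a small synthetic genome,
## Beta-distributed editing levels with hierarchical (site then sample)
## draws, negative-binomial sequencing depth, per-base error, SNP and
## somatic DNA-variant confounders, ADAR-coupled global editing activity,
## ADAR-motif-biased sequence context, and planted shared/tumor-specific/
## normal-specific differential sites, some with strongly diverged
## tumor/normal frequencies for the selection scan.

#' Simulation configuration
#'
#' Builds the parameter list consumed by [simulate_reference()] and
#' [simulate_counts()]. Defaults describe a desk-scale study: 10
#' tumor/normal pairs, a 200 kb two-chromosome genome with 30 genes, site
#' editing levels drawn from Beta(2, 8) (mean 0.2, most mass between 0.1
#' and 0.3), negative-binomial depth with mean 50, and per-base error 1e-3.
#'
#' @param n_pairs Number of tumor/normal sample pairs.
#' @param n_chroms,genome_length Number of chromosomes and total genome
#'   length (split evenly across chromosomes).
#' @param n_genes Number of genes laid out on the genome.
#' @param n_sites Named integer vector: planted site counts for the
#'   `shared`, `tumor_specific` and `normal_specific` groups.
#' @param n_diff_shared How many shared sites carry a planted tumor/normal
#'   editing-level difference of `diff_effect`.
#' @param n_fst_sites How many shared sites are planted with the strongly
#'   diverged frequencies in `fst_freqs` (selection-scan positives).
#' @param diff_effect Additive tumor-minus-normal mean-level difference at
#'   differential shared sites.
#' @param fst_freqs Named vector `c(tumor=, normal=)` of true editing
#'   frequencies at selection-planted sites.
#' @param beta_shape Beta(alpha, beta) shape for site-level mean editing.
#' @param sample_dispersion Spread of per-sample levels around the site
#'   mean, as the rho parameter of a Beta with concentration
#'   `(1-rho)/rho`; 0 means every sample sits exactly at the site mean.
#' @param depth_mean,dna_depth_mean,depth_dispersion Negative-binomial
#'   depth model (mean per assay, common dispersion; size = 1/dispersion).
#' @param error_rate Per-read probability of a sequencing error.
#' @param n_snps,n_dna_variants,n_background Numbers of planted germline
#'   SNPs, somatic (tumor-only) DNA variants, and error-only background
#'   positions.
#' @param adar_coupling Slope linking a sample's log2 ADAR1 deviation to
#'   its global editing multiplier (multiplier = 2^(coupling * deviation)).
#' @param adar_tumor_lfc True log2 fold-change of ADAR1 in tumors.
#' @param adar_sd Per-sample sd of the log2 ADAR1 deviation.
#' @param motif_bias Probability that a planted site carries the ADAR
#'   neighbor preference (no G at -1, G at +1, on the edited strand).
#' @param n_de_genes,de_lfc Planted differentially expressed genes (chosen
#'   among genes that carry planted sites) and their |log2FC|.
#' @param n_splice_events,splice_overlap Number of differential splicing
#'   events to emit and the fraction anchored to contain a planted site.
#' @param repeat_coverage Fraction of the genome covered by Alu-like
#'   repeat intervals.
#' @param region_weights Sampling weights over region classes for planted
#'   site placement.
#' @param seed Integer seed; the full simulation is a deterministic
#'   function of the configuration including the seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_pairs = 10L,
                       n_chroms = 2L,
                       genome_length = 200000L,
                       n_genes = 30L,
                       n_sites = c(shared = 150L, tumor_specific = 60L,
                                   normal_specific = 60L),
                       n_diff_shared = 50L,
                       n_fst_sites = 40L,
                       diff_effect = 0.2,
                       fst_freqs = c(tumor = 0.8, normal = 0.2),
                       beta_shape = c(2, 8),
                       sample_dispersion = 0.01,
                       depth_mean = 50,
                       dna_depth_mean = 50,
                       depth_dispersion = 0.3,
                       error_rate = 0.001,
                       n_snps = 30L,
                       n_dna_variants = 30L,
                       n_background = 2000L,
                       adar_coupling = 0.5,
                       adar_tumor_lfc = 1,
                       adar_sd = 0.5,
                       motif_bias = 0.8,
                       n_de_genes = 10L,
                       de_lfc = 2,
                       n_splice_events = 50L,
                       splice_overlap = 0.42,
                       repeat_coverage = 0.3,
                       region_weights = c(intronic = 0.78, exonic = 0.06,
                                          `3'UTR` = 0.04, `5'UTR` = 0.02,
                                          intergenic = 0.10),
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(all(c("shared", "tumor_specific", "normal_specific") %in%
                  names(n_sites)))
  if (any(n_sites < 0L) || n_pairs < 1L || n_background < 0L)
    stop_fmt("sim_config: counts must be non-negative, n_pairs >= 1")
  if (any(beta_shape <= 0))
    stop_fmt("sim_config: Beta shapes must be positive")
  probs <- c(error_rate, motif_bias, sample_dispersion, splice_overlap,
             repeat_coverage, fst_freqs)
  if (any(probs < 0 | probs > 1))
    stop_fmt("sim_config: probabilities must lie in [0, 1]")
  if (n_diff_shared + n_fst_sites > n_sites[["shared"]])
    stop_fmt("sim_config: n_diff_shared + n_fst_sites exceeds shared sites")
  structure(cfg, class = "sim_config")
}

#' Simulate the reference genome, annotation and planted-site scaffold
#'
#' Lays out genes (exons, introns, UTRs) on a uniformly random genome,
#' chooses planted editing-site, SNP, DNA-variant and background positions,
#' and plants the site center base (an A on the editing strand) and, at
#' motif-flagged sites, the ADAR neighbor preference. Base composition is
#' uniform elsewhere.
#'
#' @param cfg A [sim_config()].
#' @return A `sim_reference` list: `genome` (DNAStringSet), `annotation`
#'   (`annotation_index`), `sites` (planted scaffold with group, strand,
#'   region and motif flags), `snps`, `dna_variants`, `background`,
#'   `repeats` (GRanges).
#' @export
simulate_reference <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  chrom_len <- rep(cfg$genome_length %/% cfg$n_chroms, cfg$n_chroms)
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  seqs <- lapply(chrom_len, function(L) sample(BASES, L, replace = TRUE))
  names(seqs) <- chroms

  layout <- layout_genes(cfg, chroms, chrom_len)
  ann <- layout$annotation

  sites <- place_sites(cfg, layout, chroms, chrom_len)
  used <- site_key(sites$chrom, sites$pos)
  aux <- place_aux_positions(cfg, chroms, chrom_len, used, sites)

  ## plant center bases and motif neighbors on the raw base vectors
  for (i in seq_len(nrow(sites))) {
    ch <- sites$chrom[i]; p <- sites$pos[i]; s <- sites$strand[i]
    seqs[[ch]][p] <- if (s == "-") "T" else "A"
    if (sites$motif[i]) {
      up <- sample(c("A", "C", "T"), 1L)    # no G immediately 5' of the A
      if (s == "-") {
        seqs[[ch]][p + 1L] <- COMPLEMENT[[up]]
        seqs[[ch]][p - 1L] <- "C"           # G at +1 on the minus strand
      } else {
        seqs[[ch]][p - 1L] <- up
        seqs[[ch]][p + 1L] <- "G"
      }
    }
  }
  genome <- Biostrings::DNAStringSet(
    vapply(seqs, paste, character(1), collapse = ""))
  names(genome) <- chroms
  ## alleles resolved after planting so they match the final sequence
  aux$snps$ref <- if (nrow(aux$snps))
    genome_base(genome, aux$snps$chrom, aux$snps$pos) else character()
  aux$snps$alt <- if (nrow(aux$snps))
    vapply(aux$snps$ref, function(r) sample(setdiff(BASES, r), 1L),
           character(1)) else character()
  aux$dna_variants$ref <- if (nrow(aux$dna_variants))
    genome_base(genome, aux$dna_variants$chrom, aux$dna_variants$pos)
    else character()
  aux$dna_variants$alt <- if (nrow(aux$dna_variants))
    vapply(aux$dna_variants$ref, function(r) sample(setdiff(BASES, r), 1L),
           character(1)) else character()

  repeats <- place_repeats(cfg, chroms, chrom_len)
  if (nrow(sites)) {
    q <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(sites$pos, width = 1L))
    sites$in_repeat <- suppressWarnings(
      IRanges::overlapsAny(q, repeats, ignore.strand = TRUE))
  } else sites$in_repeat <- logical()

  structure(list(cfg = cfg, genome = genome, annotation = ann,
                 sites = sites, snps = aux$snps,
                 dna_variants = aux$dna_variants,
                 background = aux$background, repeats = repeats),
            class = "sim_reference")
}

## sequential gene layout: alternating exon/intron blocks, UTR ends
layout_genes <- function(cfg, chroms, chrom_len) {
  genes <- exons <- utr5 <- utr3 <- list()
  pools <- list()
  n_genes <- cfg$n_genes
  if (n_genes > 0L) {
    per_chrom <- table(factor(rep_len(chroms, n_genes), levels = chroms))
    gi <- 0L
    for (ci in seq_along(chroms)) {
      cursor <- 200L
      n_here <- per_chrom[[ci]]
      if (n_here == 0L) next
      slot <- (chrom_len[ci] - 400L) %/% n_here   # per-gene budget
      for (g in seq_len(n_here)) {
        gi <- gi + 1L
        gap <- min(sample(500:1500, 1L), slot %/% 4L)
        n_ex <- sample(3:6, 1L)
        ex_len <- sample(150:400, n_ex, replace = TRUE)
        in_len <- sample(300:900, n_ex - 1L, replace = TRUE)
        avail <- slot - gap
        span <- sum(ex_len) + sum(in_len)
        if (span > avail) {          # shrink to the slot, keep proportions
          sc <- avail / span
          ex_len <- pmax(60L, as.integer(floor(ex_len * sc)))
          in_len <- pmax(80L, as.integer(floor(in_len * sc)))
          span <- sum(ex_len) + sum(in_len)
        }
        start <- cursor + gap
        if (start + span > chrom_len[ci] - 200L)
          stop_fmt("simulate_reference: gene layout infeasible for genome length")
        strand <- if (gi %% 2L == 0L) "-" else "+"
        gid <- sprintf("G%03d", gi)
        ex_start <- start + c(0L, cumsum(ex_len + c(in_len, 0L))[-n_ex])
        ex_end <- ex_start + ex_len - 1L
        w5 <- min(sample(50:100, 1L), ex_len[1L] %/% 3L)
        w3 <- min(sample(50:100, 1L), ex_len[n_ex] %/% 3L)
        if (strand == "+") {
          u5 <- c(ex_start[1L], ex_start[1L] + w5 - 1L)
          u3 <- c(ex_end[n_ex] - w3 + 1L, ex_end[n_ex])
        } else {
          u5 <- c(ex_end[n_ex] - w5 + 1L, ex_end[n_ex])
          u3 <- c(ex_start[1L], ex_start[1L] + w3 - 1L)
        }
        genes[[gi]] <- data.frame(chrom = chroms[ci], start = start,
                                  end = start + span - 1L, strand = strand,
                                  gene_id = gid)
        exons[[gi]] <- data.frame(chrom = chroms[ci], start = ex_start,
                                  end = ex_end, strand = strand,
                                  gene_id = gid)
        utr5[[gi]] <- data.frame(chrom = chroms[ci], start = u5[1L],
                                 end = u5[2L], strand = strand,
                                 gene_id = gid)
        utr3[[gi]] <- data.frame(chrom = chroms[ci], start = u3[1L],
                                 end = u3[2L], strand = strand,
                                 gene_id = gid)
        cursor <- start + span
      }
    }
  }
  df2gr <- function(lst) {
    if (!length(lst)) return(GenomicRanges::GRanges())
    df <- do.call(rbind, lst)
    GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                           strand = df$strand, gene_id = df$gene_id)
  }
  ann <- build_annotation_index(df2gr(genes), df2gr(exons), df2gr(utr5),
                                df2gr(utr3))
  list(annotation = ann,
       genes = if (length(genes)) do.call(rbind, genes) else NULL)
}

## draw planted editing-site positions by region class
place_sites <- function(cfg, layout, chroms, chrom_len) {
  n_total <- sum(cfg$n_sites)
  groups <- rep(names(cfg$n_sites), cfg$n_sites)
  empty <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), gene_id = character(),
                      region = character(), group = character(),
                      motif = logical(), selected = logical(),
                      stringsAsFactors = FALSE)
  if (n_total == 0L) return(empty)
  ann <- layout$annotation
  w <- cfg$region_weights
  if (cfg$n_genes == 0L) w <- c(intergenic = 1)
  pool <- list(
    intronic = ann$intronic, exonic = ann$exonic,
    `3'UTR` = ann$utr3, `5'UTR` = ann$utr5)
  genic_cls <- names(pool)[vapply(pool, length, 1L) > 0L]
  w <- w[names(w) %in% c(genic_cls, "intergenic")]
  used <- integer(0)  # encoded positions to keep windows disjoint
  enc <- function(chrom, pos) match(chrom, chroms) * 10^9 + pos
  rows <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    for (attempt in 1:200) {
      cls <- sample(names(w), 1L, prob = w)
      if (cls == "intergenic") {
        ch <- sample(chroms, 1L)
        p <- sample(seq(1010L, chrom_len[match(ch, chroms)] - 1010L), 1L)
        ## reject if inside a gene
        if (cfg$n_genes > 0L) {
          hit <- classify_positions(ann, ch, p)
          if (hit$region != "intergenic") next
        }
        strand <- "+"; gid <- NA_character_
      } else {
        gr <- pool[[cls]]
        j <- sample(length(gr), 1L)
        lo <- GenomicRanges::start(gr)[j]; hi <- GenomicRanges::end(gr)[j]
        if (hi - lo < 4L) next
        p <- sample(seq(lo + 1L, hi - 1L), 1L)
        ch <- as.character(GenomicRanges::seqnames(gr))[j]
        strand <- as.character(GenomicRanges::strand(gr))[j]
        gid <- gr$gene_id[j]
      }
      e <- enc(ch, p)
      if (any(abs(used - e) < 12)) next
      used <- c(used, e)
      rows[[i]] <- data.frame(chrom = ch, pos = p, strand = strand,
                              gene_id = gid, region = cls,
                              stringsAsFactors = FALSE)
      break
    }
    if (is.null(rows[[i]]))
      stop_fmt("simulate_reference: could not place %d sites (genome too small)",
               n_total)
  }
  sites <- do.call(rbind, rows)
  sites$group <- groups
  sites$motif <- runif(n_total) < cfg$motif_bias
  ## first n_diff_shared shared sites are differential, next n_fst_sites
  ## carry the diverged selection frequencies
  sites$selected <- FALSE
  sh <- which(sites$group == "shared")
  if (cfg$n_fst_sites > 0L)
    sites$selected[sh[cfg$n_diff_shared + seq_len(cfg$n_fst_sites)]] <- TRUE
  sites
}

place_aux_positions <- function(cfg, chroms, chrom_len, used_keys, sites) {
  draw <- function(n, avoid) {
    if (n == 0L)
      return(data.frame(chrom = character(), pos = integer(),
                        stringsAsFactors = FALSE))
    out <- vector("list", n)
    for (i in seq_len(n)) {
      repeat {
        ch <- sample(chroms, 1L)
        p <- sample(seq(1010L, chrom_len[match(ch, chroms)] - 1010L), 1L)
        k <- site_key(ch, p)
        near <- site_key(ch, (p - 6L):(p + 6L))
        if (!any(near %in% avoid)) { out[[i]] <- c(ch, p); break }
      }
      avoid <- c(avoid, site_key(out[[i]][1L], out[[i]][2L]))
    }
    m <- do.call(rbind, out)
    data.frame(chrom = m[, 1L], pos = as.integer(m[, 2L]),
               stringsAsFactors = FALSE)
  }
  avoid <- unlist(lapply(seq_len(nrow(sites)), function(i)
    site_key(sites$chrom[i], (sites$pos[i] - 6L):(sites$pos[i] + 6L))))
  snps <- draw(cfg$n_snps, avoid)
  avoid <- c(avoid, if (nrow(snps)) site_key(snps$chrom, snps$pos))
  dnav <- draw(cfg$n_dna_variants, avoid)
  avoid <- c(avoid, if (nrow(dnav)) site_key(dnav$chrom, dnav$pos))
  bg <- draw(cfg$n_background, avoid)
  snps$gt <- if (nrow(snps)) sample(c(0.5, 1), nrow(snps), replace = TRUE,
                                    prob = c(0.7, 0.3)) else numeric()
  list(snps = snps, dna_variants = dnav, background = bg)
}

place_repeats <- function(cfg, chroms, chrom_len) {
  if (cfg$repeat_coverage <= 0) return(GenomicRanges::GRanges())
  grl <- lapply(seq_along(chroms), function(ci) {
    target <- cfg$repeat_coverage * chrom_len[ci]
    covered <- 0
    starts <- integer(0); ends <- integer(0)
    while (covered < target) {
      w <- sample(250:350, 1L)
      s <- sample(seq_len(chrom_len[ci] - w), 1L)
      starts <- c(starts, s); ends <- c(ends, s + w - 1L)
      covered <- covered + w
    }
    GenomicRanges::reduce(GenomicRanges::GRanges(
      chroms[ci], IRanges::IRanges(starts, ends)))
  })
  suppressWarnings(sort(do.call(c, grl)))
}
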