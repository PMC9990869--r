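## Sequence-context and genomic-distribution analyses.

#' Neighbor-base preference profile around edited adenosines
#'
#' For strand-resolved A>G sites, reads the reference window -k..+k on the
#' editing strand (minus-strand sites use reverse-complemented windows)
#' and tabulates per-offset base frequencies, against a background of
#' gene-matched adenosines (a seeded subsample of all A positions, on the
#' gene strand, inside the same genes, matched in count). Enrichment is
#' log2(edited/background) with a Laplace pseudocount of 0.5 per base.
#'
#' @param sites Data frame with `chrom`, `pos`, `strand` (`"+"`/`"-"`;
#'   `"unknown"` sites are treated as plus-strand), and optionally
#'   `gene_id`.
#' @param genome A [Biostrings::DNAStringSet].
#' @param ann Optional `annotation_index`; without it the background is
#'   drawn genome-wide.
#' @param k Window half-width in nucleotides.
#' @param seed Seed for the background subsample (only used with a finite
#'   `bg_multiple`).
#' @param bg_multiple Background size as a multiple of the edited-site
#'   count. The default `Inf` uses every gene-matched adenosine, which
#'   keeps the background frequencies essentially noise-free; a finite
#'   value draws a seeded subsample (ordered by transcript-relative
#'   offset, so the draw does not depend on the genome's coordinate
#'   orientation).
#' @return A `context_profile` list: `offsets`, `edited` and `background`
#'   (offset x base frequency matrices), `enrichment` (log2), `n_sites`,
#'   `n_background`, `n_skipped` (windows beyond contig edges).
#' @export
context_profile <- function(sites, genome, ann = NULL, k = 5L, seed = 1L,
                            bg_multiple = Inf) {
  strand <- ifelse(sites$strand %in% c("+", "-"), sites$strand, "+")
  win <- extract_windows(genome, sites$chrom, sites$pos, strand, k)
  n_skipped <- sum(is.na(win))
  win <- win[!is.na(win)]
  bg_pos <- background_a_positions(genome, ann,
                                   genes = unique(sites$gene_id))
  n_bg <- min(nrow(bg_pos),
              if (is.finite(bg_multiple))
                ceiling(bg_multiple * length(win)) else nrow(bg_pos))
  if (n_bg > 0L) {
    if (n_bg < nrow(bg_pos)) {
      set.seed(seed)
      bi <- sample(nrow(bg_pos), n_bg)
    } else bi <- seq_len(nrow(bg_pos))
    bwin <- extract_windows(genome, bg_pos$chrom[bi], bg_pos$pos[bi],
                            bg_pos$strand[bi], k)
    bwin <- bwin[!is.na(bwin)]
  } else bwin <- character()
  offsets <- seq(-k, k)
  freq <- function(w) {
    m <- matrix(0, length(offsets), 4L,
                dimnames = list(offsets, BASES))
    if (!length(w)) return(m)
    chars <- do.call(rbind, strsplit(w, ""))
    for (i in seq_along(offsets)) {
      tab <- table(factor(chars[, i], levels = BASES))
      m[i, ] <- as.numeric(tab) / sum(tab)
    }
    m
  }
  fe <- freq(win); fb <- freq(bwin)
  pse <- function(m, n) (m * n + 0.5) / (n + 2)   # Laplace 0.5 per base
  enr <- log2(pse(fe, length(win)) / pse(fb, length(bwin)))
  structure(list(offsets = offsets, edited = fe, background = fb,
                 enrichment = enr, n_sites = length(win),
                 n_background = length(bwin), n_skipped = n_skipped),
            class = "context_profile")
}

## windows on the given strand; NA where the window crosses a contig edge
extract_windows <- function(genome, chrom, pos, strand, k) {
  n <- length(pos)
  out <- rep(NA_character_, n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    if (!ch %in% names(genome)) stop_fmt("contig %s not in reference", ch)
    L <- Biostrings::nchar(genome[[ch]])
    ok <- pos[i] - k >= 1L & pos[i] + k <= L
    ii <- i[ok]
    if (!length(ii)) next
    v <- Biostrings::extractAt(genome[[ch]],
                               IRanges::IRanges(pos[ii] - k, pos[ii] + k))
    v <- as.character(v)
    minus <- strand[ii] == "-"
    if (any(minus))
      v[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(v[minus])))
    out[ii] <- v
  }
  out
}

## all adenosines on the coding strand of the given genes (or genome-wide
## plus-strand A's when no annotation)
background_a_positions <- function(genome, ann = NULL, genes = NULL) {
  rows <- list()
  if (!is.null(ann) && length(ann$genes)) {
    g <- ann$genes
    if (!is.null(genes)) {
      keep <- g$gene_id %in% genes[!is.na(genes)]
      if (any(keep)) g <- g[keep]
    }
    for (j in seq_along(g)) {
      ch <- as.character(GenomicRanges::seqnames(g))[j]
      s <- as.character(GenomicRanges::strand(g))[j]
      lo <- GenomicRanges::start(g)[j]; hi <- GenomicRanges::end(g)[j]
      seq <- Biostrings::subseq(genome[[ch]], lo, hi)
      target <- if (s == "-") "T" else "A"
      p <- lo - 1L +
        Biostrings::start(Biostrings::matchPattern(target, seq))
      if (length(p)) {
        ## transcript-relative offset: invariant under coordinate flips
        txo <- if (s == "-") hi - p else p - lo
        rows[[length(rows) + 1L]] <-
          data.frame(chrom = ch, pos = p[order(txo)], strand = s,
                     stringsAsFactors = FALSE)
      }
    }
  } else {
    for (ch in names(genome)) {
      p <- Biostrings::start(Biostrings::matchPattern("A", genome[[ch]]))
      if (length(p))
        rows[[length(rows) + 1L]] <-
          data.frame(chrom = ch, pos = p, strand = "+",
                     stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Distribution of sites over region classes
#'
#' @param sites Data frame with `chrom`, `pos` (a `region` column, e.g.
#'   from [resolve_strand()], is used directly if present).
#' @param ann An `annotation_index`; required when `sites` lacks `region`.
#' @return Data frame of counts and fractions per region class; fractions
#'   sum to 1 over non-empty input.
#' @export
region_distribution <- function(sites, ann = NULL) {
  region <- sites$region
  if (is.null(region)) {
    if (is.null(ann)) stop_fmt("region_distribution needs an annotation")
    region <- classify_positions(ann, sites$chrom, sites$pos)$region
  }
  counts <- table(factor(region, levels = REGION_CLASSES))
  data.frame(region = REGION_CLASSES, count = as.integer(counts),
             fraction = if (sum(counts) > 0)
               as.numeric(counts) / sum(counts) else rep(0, length(counts)),
             stringsAsFactors = FALSE)
}

#' Distribution of sites over chromosomes
#'
#' @param sites Data frame with `chrom`, `pos`.
#' @param genome [Biostrings::DNAStringSet] giving chromosome order and
#'   lengths.
#' @param normalization `"raw"` counts, `"per_mb"` (per megabase of
#'   chromosome), or `"per_gene"` (per annotated gene on the chromosome).
#' @param ann Required for `"per_gene"`.
#' @return Data frame ordered by the reference chromosome order.
#' @export
chromosome_distribution <- function(sites, genome,
                                    normalization = c("raw", "per_mb",
                                                      "per_gene"),
                                    ann = NULL) {
  normalization <- match.arg(normalization)
  chroms <- names(genome)
  bad <- setdiff(unique(sites$chrom), chroms)
  if (length(bad))
    stop_fmt("site contig(s) absent from reference: %s",
             paste(bad, collapse = ", "))
  counts <- table(factor(sites$chrom, levels = chroms))
  out <- data.frame(chrom = chroms, count = as.integer(counts),
                    stringsAsFactors = FALSE)
  if (normalization == "per_mb") {
    out$value <- out$count / (Biostrings::width(genome) / 1e6)
  } else if (normalization == "per_gene") {
    if (is.null(ann)) stop_fmt("per_gene normalization needs an annotation")
    ng <- table(factor(as.character(GenomicRanges::seqnames(ann$genes)),
                       levels = chroms))
    out$value <- ifelse(ng > 0, out$count / as.numeric(ng), NA)
  } else out$value <- out$count
  out
}

#' Fraction of sites inside repeat intervals
#'
#' @param sites Data frame with `chrom`, `pos`, optional `group`.
#' @param repeats A GRanges of repeat intervals (e.g. imported from an
#'   Alu-class BED), or a BED path.
#' @return Data frame with the overlap fraction per group (plus `all`).
#' @export
repeat_overlap <- function(sites, repeats) {
  if (is.character(repeats))
    repeats <- rtracklayer::import(repeats, format = "bed")
  if (nrow(sites) == 0L)
    return(data.frame(group = "all", n = 0L, fraction = NA,
                      stringsAsFactors = FALSE))
  q <- GenomicRanges::GRanges(sites$chrom,
                              IRanges::IRanges(sites$pos, width = 1L))
  hit <- suppressWarnings(
    IRanges::overlapsAny(q, repeats, ignore.strand = TRUE))
  grp <- sites$group %||% rep("all", nrow(sites))
  agg <- aggregate(hit, by = list(group = grp),
                   FUN = function(v) c(n = length(v), fraction = mean(v)))
  out <- data.frame(group = c("all", agg$group),
                    n = c(length(hit), agg$x[, "n"]),
                    fraction = c(mean(hit), agg$x[, "fraction"]),
                    stringsAsFactors = FALSE)
  out
}

#' Export sequence windows around sites for external motif tools
#'
#' Writes strand-resolved windows (default +/- 25 nt) as FASTA for de novo
#' motif discovery.
#'
#' @param sites Data frame with `chrom`, `pos`, `strand`.
#' @param genome A [Biostrings::DNAStringSet].
#' @param path Output FASTA path.
#' @param flank Half-width of the window.
#' @return `path`, invisibly.
#' @export
write_motif_windows <- function(sites, genome, path, flank = 25L) {
  strand <- ifelse(sites$strand %in% c("+", "-"), sites$strand, "+")
  w <- extract_windows(genome, sites$chrom, sites$pos, strand, flank)
  keep <- !is.na(w)
  seqs <- Biostrings::DNAStringSet(w[keep])
  names(seqs) <- paste0(site_key(sites$chrom[keep], sites$pos[keep]),
                        "(", strand[keep], ")")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
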