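## Intersections of DREs with differential expression (eDREs/edDEGs) and
## differential alternative splicing (sDREs/edDSGs), plus edited/unedited
## sequence-pair extraction for external structure prediction.

#' Paired log2 fold-change differential-expression stand-in
#'
#' A deliberately simple paired analysis for when no external
#' differential-expression table is available: per-gene median paired
#' log2 fold-change (log2(x+1) transform) and a paired two-sided t-test
#' with Benjamini-Hochberg correction. It is a stand-in with the same
#' output schema as a DESeq2 result, not a reimplementation of one.
#'
#' @param expr Expression matrix (genes x samples).
#' @param samples Sample sheet with `sample_id`, `condition`, `pair`.
#' @return Data frame with `gene_id`, `log2fc`, `pvalue`, `padj`.
#' @export
paired_log2fc <- function(expr, samples) {
  pairs <- unique(samples$pair)
  tid <- samples$sample_id[match(paste(pairs, "tumor"),
                                 paste(samples$pair, samples$condition))]
  nid <- samples$sample_id[match(paste(pairs, "normal"),
                                 paste(samples$pair, samples$condition))]
  lt <- log2(expr[, tid, drop = FALSE] + 1)
  ln <- log2(expr[, nid, drop = FALSE] + 1)
  d <- lt - ln
  lfc <- apply(d, 1L, stats::median)
  pv <- apply(d, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L || sd(v) == 0) return(1)
    t.test(v)$p.value
  })
  data.frame(gene_id = rownames(expr), log2fc = unname(lfc),
             pvalue = unname(pv), padj = p.adjust(pv, method = "BH"),
             stringsAsFactors = FALSE)
}

#' Intersect DREs with differentially expressed genes (eDREs)
#'
#' A DRE is an eDRE when its gene passes the differential-expression
#' thresholds; the genes carrying both signals are the edDEGs.
#'
#' @param dre A `dre_table`.
#' @param deg Data frame with `gene_id`, `log2fc`, `padj` (external run or
#'   [paired_log2fc()] output).
#' @param lfc_threshold,padj_threshold DEG thresholds
#'   (|log2FC| >= 1, padj < 0.05 by default).
#' @return List: `edres` (the qualifying DRE rows joined with their DEG
#'   evidence), `eddegs` (per-gene, per-group gene table), `summary`
#'   (gene and site counts per DRE group).
#' @export
intersect_expression <- function(dre, deg, lfc_threshold = 1,
                                 padj_threshold = 0.05) {
  needed <- c("gene_id", "log2fc", "padj")
  missing <- setdiff(needed, names(deg))
  if (length(missing))
    stop_fmt("DEG table missing column(s): %s", paste(missing, collapse = ", "))
  d <- dre[dre$is_dre & !is.na(dre$gene_id), , drop = FALSE]
  if (nrow(d) && !any(d$gene_id %in% deg$gene_id)) {
    miss <- unique(d$gene_id)
    stop_fmt("gene-id namespaces do not match; unmatched DRE gene(s): %s%s",
             paste(head(miss, 5L), collapse = ", "),
             if (length(miss) > 5L) ", ..." else "")
  }
  sig <- deg[abs(deg$log2fc) >= lfc_threshold &
               !is.na(deg$padj) & deg$padj < padj_threshold, , drop = FALSE]
  hit <- d$gene_id %in% sig$gene_id
  edres <- d[hit, , drop = FALSE]
  m <- match(edres$gene_id, sig$gene_id)
  edres$de_log2fc <- sig$log2fc[m]
  edres$de_padj <- sig$padj[m]
  edres$layer <- if (nrow(edres)) "eDRE" else character()
  eddegs <- unique(edres[, c("gene_id", "group")])
  summary <- if (nrow(edres)) {
    agg <- aggregate(key ~ group, data = edres, FUN = length)
    ag2 <- aggregate(gene_id ~ group, data = edres,
                     FUN = function(g) length(unique(g)))
    merge(setNames(agg, c("group", "n_sites")),
          setNames(ag2, c("group", "n_genes")))
  } else data.frame(group = character(), n_sites = integer(),
                    n_genes = integer(), stringsAsFactors = FALSE)
  list(edres = edres, eddegs = eddegs, summary = summary)
}

#' Correlate a site's editing level with its gene's expression
#'
#' Spearman across the samples carrying both a passing editing
#' observation and an expression value.
#'
#' @param em An `editing_matrix`.
#' @param expr Expression matrix.
#' @param key Site key (`"chrom:pos"`).
#' @param gene_id Gene to correlate against; default: the site's own gene.
#' @param min_obs Minimum number of paired observations.
#' @return One-row data frame with `key`, `gene_id`, `rho`, `p`, `n`;
#'   `rho`/`p` are NA for degenerate (constant) input, and fewer than
#'   `min_obs` (or 3) observations are refused with NA as well.
#' @export
editing_expression_correlation <- function(em, expr, key, gene_id = NULL,
                                           min_obs = 10L) {
  i <- match(key, rownames(em$level))
  if (is.na(i)) stop_fmt("unknown site key %s", key)
  gene_id <- gene_id %||% em$sites$gene_id[i]
  if (is.na(gene_id) || !gene_id %in% rownames(expr))
    stop_fmt("gene %s not in the expression matrix", gene_id)
  common <- intersect(colnames(expr), colnames(em$level))
  lv <- em$level[i, common]
  ex <- expr[gene_id, common]
  ok <- !is.na(lv) & !is.na(ex)
  out <- data.frame(key = key, gene_id = gene_id, rho = NA_real_,
                    p = NA_real_, n = sum(ok), stringsAsFactors = FALSE)
  if (sum(ok) < max(min_obs, 3L)) return(out)
  if (sd(lv[ok]) == 0 || sd(ex[ok]) == 0) return(out)
  ct <- suppressWarnings(
    cor.test(ex[ok], lv[ok], method = "spearman", exact = FALSE))
  out$rho <- unname(ct$estimate)
  out$p <- ct$p.value
  out
}

## per-event containment span (1-based closed): every event type spans its
## defining exons plus the flanking/internal introns, so edits in the
## upstream intron of a skipped exon are captured
event_span <- function(ev) {
  bad <- setdiff(unique(ev$event_type), SPLICE_TYPES)
  if (length(bad))
    stop_fmt("unknown splicing event type(s): %s", paste(bad, collapse = ", "))
  lo <- pmin(ev$exon_start, ev$upstream_start, ev$downstream_start)
  hi <- pmax(ev$exon_end, ev$upstream_end, ev$downstream_end)
  data.frame(lo = lo, hi = hi)
}

#' Intersect DREs with differential splicing events (sDREs)
#'
#' A DRE is an sDRE when it lies inside an event's containment span (the
#' event's defining exons plus flanking introns); the genes of sDREs are
#' the edDSGs. Also reports the fraction of events containing at least
#' one DRE and per-event-type editing-level summaries.
#'
#' @param dre A `dre_table`.
#' @param events Splicing event table (see [read_splicing_events()]).
#' @return List: `sdres` (DRE rows joined with their event), `by_type`
#'   (event-type counts and mean tumor/normal editing levels of sDREs),
#'   `event_fraction` (events with >= 1 DRE), `eddsgs`.
#' @export
intersect_splicing <- function(dre, events) {
  d <- dre[dre$is_dre, , drop = FALSE]
  span <- event_span(events)
  ev_gr <- GenomicRanges::GRanges(events$chrom,
                                  IRanges::IRanges(span$lo, span$hi))
  site_gr <- GenomicRanges::GRanges(d$chrom,
                                    IRanges::IRanges(d$pos, width = 1L))
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(site_gr, ev_gr, ignore.strand = TRUE))
  si <- S4Vectors::queryHits(ov); ei <- S4Vectors::subjectHits(ov)
  sdres <- cbind(d[si, , drop = FALSE],
                 data.frame(event_id = events$event_id[ei],
                            event_type = events$event_type[ei],
                            event_gene = events$gene_id[ei],
                            inc_diff = events$inc_diff[ei],
                            event_p = events$pvalue[ei],
                            stringsAsFactors = FALSE))
  sdres$layer <- if (nrow(sdres)) "sDRE" else character()
  rownames(sdres) <- NULL
  by_type <- do.call(rbind, lapply(SPLICE_TYPES, function(ty) {
    x <- sdres[sdres$event_type == ty, , drop = FALSE]
    data.frame(event_type = ty, n_sdre = nrow(x),
               mean_level_tumor = if (nrow(x))
                 mean(x$mean_level_tumor, na.rm = TRUE) else NA,
               mean_level_normal = if (nrow(x))
                 mean(x$mean_level_normal, na.rm = TRUE) else NA,
               stringsAsFactors = FALSE)
  }))
  event_fraction <- if (nrow(events))
    length(unique(ei)) / nrow(events) else NA
  list(sdres = sdres, by_type = by_type, event_fraction = event_fraction,
       eddsgs = unique(sdres$event_gene))
}

#' Extract edited/unedited sequence pairs for structure prediction
#'
#' For each strand-resolved A>G site, emits the reference window and the
#' same window with the central A replaced by G (inosine read as
#' guanosine), on the editing strand. Windows are clipped at contig edges
#' with a warning; the pair differs at exactly one position.
#'
#' @param sites Data frame with `chrom`, `pos`, `strand` (`"+"`/`"-"`).
#' @param genome A [Biostrings::DNAStringSet].
#' @param window Half-width in nt (the study's two predictors used 250
#'   and 1000).
#' @return A [Biostrings::DNAStringSet] with two records per site,
#'   `<key>|unedited` and `<key>|edited`.
#' @export
extract_structure_pairs <- function(sites, genome, window = 250L) {
  out <- list()
  for (i in seq_len(nrow(sites))) {
    ch <- sites$chrom[i]; p <- sites$pos[i]
    strand <- sites$strand[i]
    if (!ch %in% names(genome)) stop_fmt("contig %s not in reference", ch)
    L <- Biostrings::nchar(genome[[ch]])
    lo <- max(1L, p - window); hi <- min(L, p + window)
    if (lo > p - window || hi < p + window)
      warning(sprintf("window clipped at contig edge for %s",
                      site_key(ch, p)))
    seq <- Biostrings::subseq(genome[[ch]], lo, hi)
    center <- p - lo + 1L
    un <- as.character(seq)
    base <- substr(un, center, center)
    if (strand == "-") {
      un <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(un)))
      center <- nchar(un) - center + 1L
      base <- substr(un, center, center)
    }
    if (base != "A")
      stop_fmt("center base at %s is %s, not A, after strand resolution",
               site_key(ch, p), base)
    ed <- un
    substr(ed, center, center) <- "G"
    key <- site_key(ch, p)
    out[[length(out) + 1L]] <- setNames(c(un, ed),
                                        paste0(key, "|",
                                               c("unedited", "edited")))
  }
  v <- unlist(out) %||% character()
  Biostrings::DNAStringSet(v)
}

#' Summarize external delta-MFE results over structure pairs
#'
#' Ingests the results of an external folding run on the pairs written by
#' [extract_structure_pairs()] and reports the fraction of sites whose
#' folding energy change exceeds a threshold.
#'
#' @param mfe Data frame with `key`, `mfe_unedited`, `mfe_edited`
#'   (kcal/mol).
#' @param threshold Absolute delta-MFE threshold.
#' @return List with the per-site table (`delta_mfe` column added) and
#'   `fraction_above`.
#' @export
summarize_delta_mfe <- function(mfe, threshold = 1) {
  needed <- c("key", "mfe_unedited", "mfe_edited")
  missing <- setdiff(needed, names(mfe))
  if (length(missing))
    stop_fmt("MFE table missing column(s): %s", paste(missing, collapse = ", "))
  mfe$delta_mfe <- mfe$mfe_edited - mfe$mfe_unedited
  list(table = mfe,
       fraction_above = if (nrow(mfe))
         mean(abs(mfe$delta_mfe) > threshold) else NA)
}
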