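## Gene annotation index: gene/exon/UTR/intron intervals with a fast
## position -> (gene, region class) lookup.  Intervals are held as
## GenomicRanges; GFF3 (1-based closed) and BED12 (0-based half-open)
## dialects are converted on import by rtracklayer.

REGION_CLASSES <- c("exonic", "3'UTR", "5'UTR", "intronic", "intergenic")

#' Read a gene annotation into an interval index
#'
#' Accepts GFF3 (`gene`/`exon`/`five_prime_UTR`/`three_prime_UTR` features,
#' exons tied to genes by `Parent`) or BED12 (one gene per line, blocks as
#' exons, no UTR information). Returns an index that resolves positions to
#' `(gene_id, region_class, strand)`.
#'
#' @param path Path to a `.gff3`/`.gff` or `.bed` file.
#' @param format Force `"gff3"` or `"bed"`; by default inferred from the
#'   file extension.
#' @return An `annotation_index` object.
#' @export
read_annotation <- function(path, format = NULL) {
  if (!file.exists(path)) stop_fmt("annotation file not found: %s", path)
  format <- format %||% switch(tolower(tools::file_ext(path)),
                               gff = , gff3 = "gff3", bed = "bed",
                               stop_fmt("unknown annotation dialect: %s", path))
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    annotation_from_gff(gr)
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    annotation_from_bed(gr)
  }
}

annotation_from_gff <- function(gr) {
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  gid <- as.character(genes$ID %||% genes$gene_id)
  if (anyNA(gid)) stop_fmt("GFF3 gene features must carry an ID attribute")
  names(genes) <- gid
  feat_gene <- function(f) {
    sub <- gr[type == f]
    if (length(sub) == 0L) return(sub)
    parent <- as.character(unlist(sub$Parent))
    S4Vectors::mcols(sub) <- NULL
    sub$gene_id <- parent
    sub
  }
  build_annotation_index(
    genes = granges_bare(genes, gene_id = gid),
    exons = feat_gene("exon"),
    utr5 = feat_gene("five_prime_UTR"),
    utr3 = feat_gene("three_prime_UTR")
  )
}

annotation_from_bed <- function(gr) {
  if (is.null(gr$name)) stop_fmt("BED annotation needs a name column")
  gid <- as.character(gr$name)
  exons <- if (!is.null(gr$blocks)) {
    bl <- gr$blocks   # IRangesList of block offsets relative to chromStart
    n <- lengths(bl)
    GenomicRanges::GRanges(
      rep(GenomicRanges::seqnames(gr), n),
      IRanges::shift(unlist(bl), rep(GenomicRanges::start(gr), n) - 1L),
      strand = rep(GenomicRanges::strand(gr), n),
      gene_id = rep(gid, n))
  } else {
    granges_bare(gr, gene_id = gid)
  }
  build_annotation_index(
    genes = granges_bare(gr, gene_id = gid),
    exons = exons,
    utr5 = GenomicRanges::GRanges(),
    utr3 = GenomicRanges::GRanges()
  )
}

granges_bare <- function(gr, ...) {
  out <- GenomicRanges::granges(gr)
  mc <- list(...)
  for (nm in names(mc)) S4Vectors::mcols(out)[[nm]] <- mc[[nm]]
  out
}

## assemble the index; introns = gene span minus exons, exonic = exon minus
## UTRs (a CDS-exonic hit outranks a UTR annotation on the same bases)
build_annotation_index <- function(genes, exons, utr5, utr3) {
  ## strand-blind global setdiff, then re-attach gene ids and strands by
  ## intersecting the pieces with the gene spans they fall in
  global_setdiff <- function(a, b, by_gene) {
    if (length(a) == 0L) return(a)
    d <- suppressWarnings(GenomicRanges::setdiff(
      GenomicRanges::reduce(GenomicRanges::granges(a), ignore.strand = TRUE),
      GenomicRanges::reduce(GenomicRanges::granges(b), ignore.strand = TRUE),
      ignore.strand = TRUE))
    if (length(d) == 0L || length(by_gene) == 0L)
      return(GenomicRanges::GRanges())
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(d, by_gene, ignore.strand = TRUE))
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    piece <- IRanges::pintersect(
      IRanges::ranges(d)[qi], IRanges::ranges(by_gene)[si])
    GenomicRanges::GRanges(
      GenomicRanges::seqnames(by_gene)[si], piece,
      strand = GenomicRanges::strand(by_gene)[si],
      gene_id = by_gene$gene_id[si])
  }
  utrs <- c(granges_bare(utr5, gene_id = utr5$gene_id %||% character()),
            granges_bare(utr3, gene_id = utr3$gene_id %||% character()))
  exonic <- global_setdiff(exons, utrs, exons)
  intronic <- global_setdiff(genes, exons, genes)
  structure(list(genes = genes, exons = exons,
                 exonic = exonic, utr5 = utr5, utr3 = utr3,
                 intronic = intronic),
            class = "annotation_index")
}

#' @export
print.annotation_index <- function(x, ...) {
  cat(sprintf("annotation_index: %d genes, %d exons, %d/%d UTR5/UTR3 blocks\n",
              length(x$genes), length(x$exons), length(x$utr5),
              length(x$utr3)))
  invisible(x)
}

#' Resolve positions to gene, region class and strand
#'
#' Region-class precedence for overlapping annotations is
#' exonic > 3'UTR > 5'UTR > intronic > intergenic; ties between genes are
#' broken by lexicographic `gene_id`, and a position hit by more than one
#' gene is reported with `ambiguous = TRUE`.
#'
#' @param ann An `annotation_index`.
#' @param chrom,pos Parallel vectors of chromosome and 1-based position.
#' @return A data frame with `gene_id` (NA when intergenic), `region`,
#'   `strand` (`"*"` when intergenic or ambiguous) and `ambiguous`.
#' @export
classify_positions <- function(ann, chrom, pos) {
  stopifnot(inherits(ann, "annotation_index"), length(chrom) == length(pos))
  n <- length(pos)
  region <- rep("intergenic", n)
  gene <- rep(NA_character_, n)
  strand <- rep("*", n)
  ambiguous <- rep(FALSE, n)
  if (n == 0L)
    return(data.frame(gene_id = gene, region = region, strand = strand,
                      ambiguous = ambiguous, stringsAsFactors = FALSE))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  layers <- list(exonic = ann$exonic, `3'UTR` = ann$utr3,
                 `5'UTR` = ann$utr5, intronic = ann$intronic)
  unresolved <- rep(TRUE, n)
  for (nm in names(layers)) {
    gr <- layers[[nm]]
    if (length(gr) == 0L) next
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(q, gr, ignore.strand = TRUE))
    qh <- S4Vectors::queryHits(hits)
    keep <- qh %in% which(unresolved)
    if (!any(keep)) next
    qh <- qh[keep]
    sh <- S4Vectors::subjectHits(hits)[keep]
    gid <- gr$gene_id[sh]
    ord <- order(qh, gid)        # lexicographic gene tie-break
    qh <- qh[ord]; sh <- sh[ord]; gid <- gid[ord]
    first <- !duplicated(qh)
    idx <- qh[first]
    region[idx] <- nm
    gene[idx] <- gid[first]
    strand[idx] <- as.character(GenomicRanges::strand(gr))[sh[first]]
    multi <- tapply(gid, qh, function(g) length(unique(g)) > 1L)
    ambiguous[as.integer(names(multi))] <- ambiguous[as.integer(names(multi))] | multi
    unresolved[idx] <- FALSE
  }
  ## gene-level ambiguity across layers: a position inside two gene spans
  if (length(ann$genes)) {
    gh <- suppressWarnings(
      GenomicRanges::findOverlaps(q, ann$genes, ignore.strand = TRUE))
    ng <- tapply(ann$genes$gene_id[S4Vectors::subjectHits(gh)],
                 S4Vectors::queryHits(gh),
                 function(g) length(unique(g)))
    amb_idx <- as.integer(names(ng))[ng > 1L]
    ambiguous[amb_idx] <- TRUE
  }
  strand[ambiguous] <- "*"
  data.frame(gene_id = gene, region = region, strand = strand,
             ambiguous = ambiguous, stringsAsFactors = FALSE)
}

#' Write an annotation index back to GFF3
#'
#' @param ann An `annotation_index`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(ann, path) {
  feat <- function(gr, type, id = NULL, parent = NULL) {
    if (length(gr) == 0L) return(NULL)
    df <- data.frame(
      seqid = as.character(GenomicRanges::seqnames(gr)),
      source = "editscape",
      type = type,
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      score = ".",
      strand = as.character(GenomicRanges::strand(gr)),
      phase = ".",
      attributes = if (is.null(parent)) paste0("ID=", id)
                   else paste0("Parent=", parent),
      stringsAsFactors = FALSE)
    df
  }
  rows <- rbind(
    feat(ann$genes, "gene", id = ann$genes$gene_id),
    feat(ann$exons, "exon", parent = ann$exons$gene_id),
    feat(ann$utr5, "five_prime_UTR", parent = ann$utr5$gene_id),
    feat(ann$utr3, "three_prime_UTR", parent = ann$utr3$gene_id))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (!is.null(rows)) {
    rows <- rows[order(rows$seqid, rows$start, rows$type != "gene"), ]
    writeLines(do.call(paste, c(rows, sep = "\t")), con)
  }
  invisible(path)
}
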