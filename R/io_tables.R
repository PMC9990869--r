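## Expression matrices, splicing-event tables, and the on-disk layout of a
## simulated dataset.

#' Read a gene-expression matrix
#'
#' @param path TSV with a `gene_id` column followed by one numeric column
#'   per sample (normalized units as supplied, e.g. TPM).
#' @return A numeric matrix, genes x samples.
#' @export
read_expression_matrix <- function(path) {
  df <- read_tsv(path)
  if (!"gene_id" %in% names(df))
    stop_fmt("expression table %s needs a gene_id column", path)
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  if (any(m < 0, na.rm = TRUE))
    stop_fmt("expression table %s has negative values", path)
  rownames(m) <- df$gene_id
  m
}

#' @rdname read_expression_matrix
#' @param x Matrix to write.
#' @export
write_expression_matrix <- function(x, path) {
  write_tsv(data.frame(gene_id = rownames(x), x, check.names = FALSE,
                       stringsAsFactors = FALSE), path)
}

SPLICE_TYPES <- c("SE", "A5SS", "A3SS", "MXE", "RI")

SPLICE_COLS <- c("event_id", "gene_id", "chrom", "strand", "event_type",
                 "exon_start", "exon_end", "upstream_start", "upstream_end",
                 "downstream_start", "downstream_end", "inc_diff", "pvalue")

#' Read a differential alternative-splicing event table
#'
#' rMATS-dialect TSV: one event per row with the event type
#' (SE/A5SS/A3SS/MXE/RI), a 1-based closed coordinate block (central exon
#' plus upstream/downstream flanks), the inclusion-level difference and a
#' p-value.
#'
#' @param path TSV path.
#' @return A data frame with the columns in `SPLICE_COLS`.
#' @export
read_splicing_events <- function(path) {
  df <- read_tsv(path)
  missing <- setdiff(SPLICE_COLS, names(df))
  if (length(missing))
    stop_fmt("splicing table %s missing column(s): %s", path,
             paste(missing, collapse = ", "))
  bad <- setdiff(unique(df$event_type), SPLICE_TYPES)
  if (length(bad))
    stop_fmt("unknown splicing event type(s): %s", paste(bad, collapse = ", "))
  df[, SPLICE_COLS]
}

#' @rdname read_splicing_events
#' @param x Event data frame to write.
#' @export
write_splicing_events <- function(x, path) write_tsv(x[, SPLICE_COLS], path)

#' Write a simulated dataset to a directory
#'
#' Emits the same dialects the readers consume: reference FASTA, GFF3
#' annotation, repeat BED, per-sample RNA/DNA count TSVs, SNP-mask VCF,
#' expression TSV, splicing TSV and the truth set. Output is a
#' deterministic function of the simulation object.
#'
#' @param sim A `sim_data` from [simulate_counts()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "counts"), showWarnings = FALSE)
  ref <- sim$reference
  Biostrings::writeXStringSet(ref$genome, file.path(dir, "genome.fa"))
  write_annotation_gff3(ref$annotation, file.path(dir, "annotation.gff3"))
  if (length(ref$repeats))
    rtracklayer::export(ref$repeats, file.path(dir, "repeats.bed"),
                        format = "bed")
  for (id in names(sim$rna)) {
    write_site_counts(sim$rna[[id]],
                      file.path(dir, "counts", paste0(id, ".RNA.tsv")))
    write_site_counts(sim$dna[[id]],
                      file.path(dir, "counts", paste0(id, ".DNA.tsv")))
  }
  write_tsv(sim$samples, file.path(dir, "samples.tsv"))
  write_expression_matrix(sim$expression, file.path(dir, "expression.tsv"))
  write_splicing_events(sim$splicing, file.path(dir, "splicing.tsv"))
  write_simple_vcf(sim$truth$snps, file.path(dir, "snp_mask.vcf"))
  write_truth(sim$truth, file.path(dir, "truth"))
  invisible(dir)
}

#' Write the simulation truth set
#'
#' TSV tables for planted sites, samples, differentially expressed genes
#' and splicing-event truth; VCFs for SNPs and somatic DNA variants.
#'
#' @param truth The `truth` element of a `sim_data`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(truth$sites, file.path(dir, "sites.tsv"))
  write_tsv(truth$samples, file.path(dir, "samples.tsv"))
  write_tsv(truth$de_genes, file.path(dir, "de_genes.tsv"))
  write_tsv(truth$splicing, file.path(dir, "splicing.tsv"))
  write_simple_vcf(truth$snps, file.path(dir, "snps.vcf"))
  write_simple_vcf(truth$dna_variants, file.path(dir, "dna_variants.vcf"),
                   info = "SOMATIC")
  invisible(dir)
}
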