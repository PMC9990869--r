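## Per-site base-count tables (REDItools-style TSV dialect).
##
## Columns: chrom, pos (1-based), ref, strand, depth, mean_quality,
## base_counts ("A,C,G,T" comma-joined). One table per sample per assay.

#' Read a per-site base-count table
#'
#' Reads the tab-separated per-site evidence table emitted by pileup-based
#' RNA/DNA variant callers: one row per covered position with the reference
#' base, the read depth, the mean base quality and the A/C/G/T read counts
#' (comma-joined, in that order).
#'
#' @param path Path to a TSV file with columns `chrom`, `pos`, `ref`,
#'   `strand`, `depth`, `mean_quality`, `base_counts`.
#' @param assay `"RNA"` or `"DNA"`.
#' @param sample_id Sample identifier attached to the table; defaults to the
#'   file name without extension.
#' @return A `site_counts` data frame with one row per position and integer
#'   columns `count_A`, `count_C`, `count_G`, `count_T`; attributes
#'   `sample_id` and `assay` record provenance.
#' @details Malformed rows are reported with their line numbers. A `depth`
#'   that does not equal the sum of the four base counts is an integrity
#'   error, not a warning: these tables are the sole evidence downstream.
#' @export
read_site_counts <- function(path, assay = c("RNA", "DNA"),
                             sample_id = NULL) {
  assay <- match.arg(assay)
  if (!file.exists(path)) stop_fmt("site-count file not found: %s", path)
  raw <- read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
  required <- c("chrom", "pos", "ref", "strand", "depth", "mean_quality",
                "base_counts")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop_fmt("site-count file %s is missing column(s): %s", path,
             paste(missing, collapse = ", "))
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  if (nrow(raw) == 0L)
    return(new_site_counts(empty_site_counts_df(), sample_id, assay))
  counts <- strsplit(raw$base_counts, ",", fixed = TRUE)
  bad_len <- which(lengths(counts) != 4L)
  if (length(bad_len))
    stop_fmt("site-count file %s: base_counts must have 4 fields (line %s)",
             path, paste(bad_len + 1L, collapse = ", "))
  cm <- matrix(as.integer(unlist(counts)), ncol = 4L, byrow = TRUE)
  df <- data.frame(
    chrom = raw$chrom,
    pos = as.integer(raw$pos),
    ref = toupper(raw$ref),
    strand = raw$strand,
    depth = as.integer(raw$depth),
    mean_quality = as.numeric(raw$mean_quality),
    count_A = cm[, 1L], count_C = cm[, 2L], count_G = cm[, 3L],
    count_T = cm[, 4L],
    stringsAsFactors = FALSE
  )
  validate_site_counts(df, path)
  new_site_counts(df, sample_id, assay)
}

empty_site_counts_df <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             strand = character(), depth = integer(),
             mean_quality = numeric(), count_A = integer(),
             count_C = integer(), count_G = integer(), count_T = integer(),
             stringsAsFactors = FALSE)
}

new_site_counts <- function(df, sample_id, assay) {
  structure(df, sample_id = sample_id, assay = assay,
            class = c("site_counts", "data.frame"))
}

validate_site_counts <- function(df, path = "<site_counts>") {
  if (nrow(df) == 0L) return(invisible(df))
  bad_ref <- which(!df$ref %in% BASES)
  if (length(bad_ref))
    stop_fmt("%s: ref base not in A/C/G/T (line %s)", path,
             paste(bad_ref + 1L, collapse = ", "))
  bad_pos <- which(is.na(df$pos) | df$pos < 1L)
  if (length(bad_pos))
    stop_fmt("%s: pos must be a positive integer (line %s)", path,
             paste(bad_pos + 1L, collapse = ", "))
  sums <- df$count_A + df$count_C + df$count_G + df$count_T
  bad_depth <- which(df$depth != sums)
  if (length(bad_depth))
    stop_fmt("%s: depth does not equal the base-count sum (line %s)", path,
             paste(bad_depth + 1L, collapse = ", "))
  bad_q <- which(is.na(df$mean_quality) | df$mean_quality < 0 |
                   df$mean_quality > 60)
  if (length(bad_q))
    stop_fmt("%s: mean_quality outside [0, 60] (line %s)", path,
             paste(bad_q + 1L, collapse = ", "))
  invisible(df)
}

#' Write a per-site base-count table
#'
#' Inverse of [read_site_counts()]; round-trips all fields.
#'
#' @param x A `site_counts` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_site_counts <- function(x, path) {
  stopifnot(inherits(x, "site_counts"))
  out <- data.frame(
    chrom = x$chrom, pos = x$pos, ref = x$ref, strand = x$strand,
    depth = x$depth, mean_quality = x$mean_quality,
    base_counts = paste(x$count_A, x$count_C, x$count_G, x$count_T,
                        sep = ","),
    stringsAsFactors = FALSE
  )
  write_tsv(out, path)
}

#' Check the reference base of a count table against a genome
#'
#' @param x A `site_counts` object.
#' @param genome A [Biostrings::DNAStringSet] keyed by chromosome.
#' @return `x`, invisibly; mismatching rows raise an error.
#' @export
check_reference <- function(x, genome) {
  if (nrow(x) == 0L) return(invisible(x))
  ref <- genome_base(genome, x$chrom, x$pos)
  bad <- which(ref != x$ref)
  if (length(bad))
    stop_fmt("ref base disagrees with the reference FASTA at %s",
             paste(site_key(x$chrom[bad], x$pos[bad]), collapse = ", "))
  invisible(x)
}

## vectorised single-base lookup, 1-based positions
genome_base <- function(genome, chrom, pos) {
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    if (!ch %in% names(genome)) stop_fmt("contig %s not in reference", ch)
    out[i] <- as.character(Biostrings::extractAt(
      genome[[ch]], IRanges::IRanges(pos[i], width = 1L)))
  }
  out
}
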