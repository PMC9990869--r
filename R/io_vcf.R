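## SNP mask: positions excluded from editing calls because they are known
## polymorphisms.  Matching is on (chrom, pos) only -- conservative removal
## without allele bookkeeping.

#' Read a SNP mask from a VCF
#'
#' Keeps single-nucleotide records only; indels are dropped with a logged
#' count and multi-allelic records collapse to one masked position.
#'
#' @param path Path to a VCF (v4.x, plain text or bgzipped).
#' @return A `snp_mask` data frame with columns `chrom`, `pos`, `ref`,
#'   `alt`; attribute `n_indels_ignored` records dropped records.
#' @export
read_snp_mask <- function(path) {
  if (!file.exists(path)) stop_fmt("VCF file not found: %s", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop_fmt("unreadable VCF %s: %s", path,
                                             conditionMessage(e)))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    out <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE)
    return(structure(out, n_indels_ignored = 0L,
                     class = c("snp_mask", "data.frame")))
  }
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  snv <- mapply(function(ref, alt) nchar(ref) == 1L && any(nchar(alt) == 1L),
                fix$REF, alts)
  n_indel <- sum(!snv)
  if (n_indel > 0L)
    message(sprintf("read_snp_mask: ignored %d non-SNV record(s)", n_indel))
  keep <- fix[snv, , drop = FALSE]
  keep_alts <- lapply(alts[snv], function(a) a[nchar(a) == 1L])
  out <- data.frame(
    chrom = keep$CHROM,
    pos = as.integer(keep$POS),
    ref = keep$REF,
    alt = vapply(keep_alts, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  out <- out[!duplicated(site_key(out$chrom, out$pos)), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_indels_ignored = n_indel,
            class = c("snp_mask", "data.frame"))
}

#' Test positions against a SNP mask
#'
#' @param mask A `snp_mask`.
#' @param chrom,pos Parallel vectors.
#' @return Logical vector: `TRUE` where (chrom, pos) is masked.
#' @export
in_snp_mask <- function(mask, chrom, pos) {
  if (is.null(mask) || nrow(mask) == 0L) return(rep(FALSE, length(pos)))
  site_key(chrom, pos) %in% site_key(mask$chrom, mask$pos)
}

## Minimal VCF v4.2 writer for simulator truth sets and DRE pseudo-genotype
## export; fixed columns only, deterministic row order.
write_simple_vcf <- function(df, path, info = ".") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(df)) {
    df$.info <- rep_len(info, nrow(df))
    df <- df[order(df$chrom, df$pos), , drop = FALSE]
    writeLines(paste(df$chrom, df$pos, ".", df$ref, df$alt, ".", "PASS",
                     df$.info, sep = "\t"), con)
  }
  invisible(path)
}
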