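BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Site key used for joins across all result tables
#'
#' @param chrom,pos Parallel chromosome and 1-based position vectors.
#' @return Character vector `"chrom:pos"`.
#' @export
site_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

## write a data.frame as TSV with a stable column order and no quoting
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}
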