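## Editing-frequency F_ST between tumor and normal sample groups, used as
## a genetic signature of candidate positive selection on editing.

#' Weir-Cockerham F_ST from two groups of per-sample frequencies
#'
#' Each sample contributes its editing frequency as one observation; the
#' estimator is the Weir-Cockerham variance-component ratio a/(a+b+c)
#' computed from the one-way layout of per-sample frequencies in the two
#' groups (method-of-moments on the between- and within-group mean
#' squares, with the unbalanced-design average sample size n_c). An
#' all-equal configuration has no differentiation and returns 0.
#'
#' @param x,y Numeric vectors of per-sample frequencies in the two groups
#'   (each of length >= 2).
#' @return The raw estimate (can be slightly negative by sampling noise).
#' @export
fst_weir_cockerham <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop_fmt("fst_weir_cockerham needs >= 2 samples per group")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2; r <- 2L
  xb1 <- mean(x); xb2 <- mean(y)
  gm <- (n1 * xb1 + n2 * xb2) / N
  msb <- (n1 * (xb1 - gm)^2 + n2 * (xb2 - gm)^2) / (r - 1)
  msw <- (sum((x - xb1)^2) + sum((y - xb2)^2)) / (N - r)
  nc <- (N - (n1^2 + n2^2) / N) / (r - 1)
  denom <- msb + (nc - 1) * msw
  if (denom == 0) return(0)
  (msb - msw) / denom
}

#' Hudson-style F_ST from pooled read counts
#'
#' Uses the pooled edited-read frequencies of the two groups with the
#' Bhatia-Hudson sample-size correction on read counts.
#'
#' @param edited1,total1,edited2,total2 Pooled edited and total read
#'   counts per group.
#' @return Raw estimate in `[-1, 1]`.
#' @export
fst_hudson <- function(edited1, total1, edited2, total2) {
  if (total1 < 2 || total2 < 2)
    stop_fmt("fst_hudson needs >= 2 reads per group")
  p1 <- edited1 / total1; p2 <- edited2 / total2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (total1 - 1) -
    p2 * (1 - p2) / (total2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  if (den == 0) return(0)
  max(min(num / den, 1), -1)
}

#' Per-site editing-frequency F_ST over an editing matrix
#'
#' Treats each sample's editing level as a biallelic allele frequency with
#' one observation per sample and contrasts the tumor and normal groups.
#' The raw estimate is preserved (`fst_raw`) and clamped to [0, 1] for the
#' headline column.
#'
#' @param em An `editing_matrix`.
#' @param keys Site keys to score (default: all sites with at least 2
#'   observations per condition).
#' @param estimator `"weir_cockerham"` (per-sample frequencies) or
#'   `"hudson"` (pooled read counts).
#' @return Data frame with per-condition sample sizes, `fst_raw` and
#'   `fst`; sites with fewer than 2 observations in either condition get
#'   NA.
#' @export
fst_per_site <- function(em, keys = NULL,
                         estimator = c("weir_cockerham", "hudson")) {
  estimator <- match.arg(estimator)
  keys <- keys %||% rownames(em$level)
  idx <- match(keys, rownames(em$level))
  if (anyNA(idx)) stop_fmt("unknown site key(s) in fst_per_site")
  tcol <- em$samples$condition == "tumor"
  out <- data.frame(key = keys, n_tumor = 0L, n_normal = 0L,
                    fst_raw = NA_real_, fst = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(idx)) {
    lt <- em$level[idx[i], tcol]; ln <- em$level[idx[i], !tcol]
    lt <- lt[!is.na(lt)]; ln <- ln[!is.na(ln)]
    out$n_tumor[i] <- length(lt); out$n_normal[i] <- length(ln)
    if (length(lt) < 2L || length(ln) < 2L) next
    raw <- if (estimator == "weir_cockerham") {
      fst_weir_cockerham(lt, ln)
    } else {
      at <- sum(em$alt[idx[i], tcol], na.rm = TRUE)
      rt <- sum(em$ref[idx[i], tcol], na.rm = TRUE)
      an <- sum(em$alt[idx[i], !tcol], na.rm = TRUE)
      rn <- sum(em$ref[idx[i], !tcol], na.rm = TRUE)
      fst_hudson(at, at + rt, an, an + rn)
    }
    out$fst_raw[i] <- raw
    out$fst[i] <- min(max(raw, 0), 1)
  }
  out
}

#' Selection scan over a DRE table
#'
#' Scores every DRE with the editing-frequency F_ST, flags candidates at
#' `fst >= threshold`, and summarizes flagged sites by chromosome, gene
#' and group; optionally intersects flagged genes with a user gene set
#' (e.g. immune genes).
#'
#' @param em An `editing_matrix`.
#' @param dre A `dre_table`.
#' @param threshold Selection threshold on the clamped F_ST.
#' @param estimator Passed to [fst_per_site()].
#' @param gene_set Optional character vector of gene ids.
#' @return List: `table` (the DRE rows with `fst_raw`, `fst`,
#'   `positive_selected`), `by_chrom`, `by_gene`, `by_group`, and
#'   `gene_set_hits` when a gene set was supplied.
#' @export
selection_scan <- function(em, dre, threshold = 0.25,
                           estimator = "weir_cockerham",
                           gene_set = NULL) {
  d <- dre[dre$is_dre, , drop = FALSE]
  fs <- fst_per_site(em, keys = d$key, estimator = estimator)
  d$fst_raw <- fs$fst_raw
  d$fst <- fs$fst
  d$positive_selected <- !is.na(d$fst) & d$fst >= threshold
  flagged <- d[d$positive_selected, , drop = FALSE]
  count_by <- function(v) {
    if (!nrow(flagged))
      return(data.frame(key = character(), n = integer(),
                        stringsAsFactors = FALSE))
    tb <- table(flagged[[v]], useNA = "no")
    data.frame(key = names(tb), n = as.integer(tb), stringsAsFactors = FALSE)
  }
  out <- list(table = d, threshold = threshold,
              by_chrom = count_by("chrom"),
              by_gene = count_by("gene_id"),
              by_group = count_by("group"))
  if (!is.null(gene_set))
    out$gene_set_hits <- intersect(unique(flagged$gene_id), gene_set)
  out
}

#' Export DREs with per-sample editing frequencies as a VCF-like file
#'
#' Writes one record per DRE with the per-sample editing frequencies in
#' the INFO field, so external F_ST tools can be cross-checked against
#' the built-in estimator.
#'
#' @param em An `editing_matrix`.
#' @param dre A `dre_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_dre_vcf <- function(em, dre, path) {
  d <- dre[dre$is_dre, , drop = FALSE]
  idx <- match(d$key, rownames(em$level))
  freqs <- apply(em$level[idx, , drop = FALSE], 1L, function(v)
    paste(ifelse(is.na(v), ".", sprintf("%.4f", v)), collapse = ","))
  ref <- substr(d$edit_type, 1L, 1L)
  alt <- substr(d$edit_type, 3L, 3L)
  df <- data.frame(chrom = d$chrom, pos = d$pos, ref = ref, alt = alt,
                   stringsAsFactors = FALSE)
  write_simple_vcf(df, path, info = paste0("EF=", freqs))
}
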