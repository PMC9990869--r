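## Deaminase-expression association: ADAR1/2/3 versus global and per-site
## editing.

ADAR_ALIASES <- list(
  ADAR1 = c("ADAR", "ADAR1"),
  ADAR2 = c("ADARB1", "ADAR2"),
  ADAR3 = c("ADARB2", "ADAR3"))

resolve_adar_row <- function(expr, adar) {
  aliases <- ADAR_ALIASES[[adar]] %||% adar
  hit <- intersect(aliases, rownames(expr))
  if (!length(hit)) return(NULL)
  expr[hit[1L], ]
}

#' Per-sample mean editing level
#'
#' Averages over passing sites observed in each sample (missing
#' observations are excluded, not zero-filled).
#'
#' @param em An `editing_matrix`.
#' @return Named numeric vector, one value per sample.
#' @export
sample_mean_level <- function(em) colMeans(em$level, na.rm = TRUE)

#' Global correlation of ADAR expression with mean editing level
#'
#' Spearman rank correlation (ties mid-ranked) of each sample's mean
#' editing level against its ADAR1/2/3 expression, across all samples of
#' both conditions.
#'
#' @param expr Expression matrix (genes x samples); ADAR rows are found
#'   under the gene symbols ADAR/ADARB1/ADARB2 or the ADAR1/2/3 aliases.
#' @param em An `editing_matrix` with the same samples.
#' @param adars Which deaminases to test.
#' @return Data frame with `adar`, `rho`, `p`, `n`.
#' @export
global_adar_correlation <- function(expr, em,
                                    adars = c("ADAR1", "ADAR2", "ADAR3")) {
  common <- intersect(colnames(expr), em$samples$sample_id)
  if (length(common) < 3L)
    stop_fmt("global_adar_correlation needs at least 3 aligned samples")
  ml <- sample_mean_level(em)[common]
  rows <- lapply(adars, function(a) {
    e <- resolve_adar_row(expr, a)
    if (is.null(e))
      return(data.frame(adar = a, rho = NA, p = NA, n = 0L))
    ct <- suppressWarnings(
      cor.test(e[common], ml, method = "spearman", exact = FALSE))
    data.frame(adar = a, rho = unname(ct$estimate), p = ct$p.value,
               n = length(common), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-site correlation of editing level with ADAR1 expression
#'
#' @param expr Expression matrix.
#' @param em An `editing_matrix`.
#' @param adar Deaminase to correlate against.
#' @param min_obs Minimum number of samples with a passing observation.
#' @return Data frame with `key`, `rho`, `p`, `n`; sites with fewer than
#'   `min_obs` observations or a constant level vector are reported with
#'   NA.
#' @export
per_site_adar_correlation <- function(expr, em, adar = "ADAR1",
                                      min_obs = 10L) {
  e <- resolve_adar_row(expr, adar)
  if (is.null(e)) stop_fmt("no %s row in the expression matrix", adar)
  common <- intersect(colnames(expr), em$samples$sample_id)
  lv <- em$level[, common, drop = FALSE]
  e <- e[common]
  out <- data.frame(key = rownames(lv), rho = NA_real_, p = NA_real_,
                    n = 0L, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(lv))) {
    ok <- !is.na(lv[i, ])
    out$n[i] <- sum(ok)
    if (sum(ok) < min_obs) next
    x <- lv[i, ok]
    if (sd(x) == 0 || sd(e[ok]) == 0) next   # undefined: reported missing
    ct <- suppressWarnings(
      cor.test(e[ok], x, method = "spearman", exact = FALSE))
    out$rho[i] <- unname(ct$estimate)
    out$p[i] <- ct$p.value
  }
  out
}

#' Paired differential expression of the ADAR deaminases
#'
#' Paired two-sided t-test on log2(x + 1) expression, tumor versus normal.
#'
#' @param expr Expression matrix.
#' @param samples Sample sheet with `sample_id`, `condition`, `pair`.
#' @param adars Which deaminases to test.
#' @return Data frame with `adar`, `log2fc` (mean paired difference),
#'   `statistic`, `p`.
#' @export
adar_expression_test <- function(expr, samples,
                                 adars = c("ADAR1", "ADAR2", "ADAR3")) {
  pairs <- unique(samples$pair)
  rows <- lapply(adars, function(a) {
    e <- resolve_adar_row(expr, a)
    if (is.null(e))
      return(data.frame(adar = a, log2fc = NA, statistic = NA, p = NA))
    tv <- log2(e[samples$sample_id[match(paste(pairs, "tumor"),
             paste(samples$pair, samples$condition))]] + 1)
    nv <- log2(e[samples$sample_id[match(paste(pairs, "normal"),
             paste(samples$pair, samples$condition))]] + 1)
    tt <- t.test(tv, nv, paired = TRUE)
    data.frame(adar = a, log2fc = mean(tv - nv),
               statistic = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Stratify pairs by ADAR1 direction and correlate level with site count
#'
#' A pair is `upregulated` when its tumor sample expresses more ADAR1 than
#' its normal sample. Within each stratum, the per-sample mean editing
#' level is correlated (Spearman by default) with the per-sample passing
#' site count across the tumor samples of the stratum.
#'
#' @param expr Expression matrix.
#' @param em An `editing_matrix` whose `samples` carry `pair`.
#' @param method `"spearman"` or `"pearson"`.
#' @return List with the pair assignment and one `(rho, p, n)` row per
#'   stratum (NA when a stratum has fewer than 3 pairs).
#' @export
stratify_by_adar1 <- function(expr, em, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  e <- resolve_adar_row(expr, "ADAR1")
  if (is.null(e)) stop_fmt("no ADAR1 row in the expression matrix")
  s <- em$samples
  pairs <- unique(s$pair)
  tid <- s$sample_id[match(paste(pairs, "tumor"),
                           paste(s$pair, s$condition))]
  nid <- s$sample_id[match(paste(pairs, "normal"),
                           paste(s$pair, s$condition))]
  up <- e[tid] > e[nid]
  ml <- sample_mean_level(em)
  sc <- colSums(!is.na(em$level))
  strat_cor <- function(ids) {
    ids <- ids[!is.na(ids)]
    if (length(ids) < 3L)
      return(data.frame(rho = NA, p = NA, n = length(ids)))
    x <- ml[ids]; y <- sc[ids]
    if (sd(x, na.rm = TRUE) == 0 || sd(y) == 0)
      return(data.frame(rho = NA, p = NA, n = length(ids)))
    ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
    data.frame(rho = unname(ct$estimate), p = ct$p.value, n = length(ids))
  }
  res <- rbind(cbind(stratum = "upregulated", strat_cor(tid[up])),
               cbind(stratum = "downregulated", strat_cor(tid[!up])))
  list(pairs = data.frame(pair = pairs, tumor = tid, normal = nid,
                          adar1_up = unname(up), stringsAsFactors = FALSE),
       correlations = res)
}
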