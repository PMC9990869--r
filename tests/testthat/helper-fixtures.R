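# fixtures built in code: tiny count tables, genomes, annotations

make_site_counts <- function(rows, sample_id = "S1", assay = "RNA") {
  # rows: list of c(chrom, pos, ref, strand, quality, A, C, G, T)
  df <- do.call(rbind, lapply(rows, function(r) {
    counts <- as.integer(r[6:9])
    data.frame(chrom = r[[1]], pos = as.integer(r[[2]]), ref = r[[3]],
               strand = r[[4]], depth = sum(counts),
               mean_quality = as.numeric(r[[5]]),
               count_A = counts[1], count_C = counts[2],
               count_G = counts[3], count_T = counts[4],
               stringsAsFactors = FALSE)
  }))
  editscape:::new_site_counts(df, sample_id, assay)
}

write_counts_file <- function(lines, path = tempfile(fileext = ".tsv")) {
  header <- "chrom\tpos\tref\tstrand\tdepth\tmean_quality\tbase_counts"
  writeLines(c(header, lines), path)
  path
}

write_gff3_file <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

write_vcf_file <- function(body, path = tempfile(fileext = ".vcf")) {
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", body), path)
  path
}

# two-gene annotation on a 10 kb toy chromosome:
#   GA (+): exons 101-200, 301-400 (5'UTR 101-130, 3'UTR 371-400)
#   GB (-): exons 1001-1100, 1201-1300
toy_annotation <- function() {
  gff <- c(
    "chr1\ttest\tgene\t101\t400\t.\t+\t.\tID=GA",
    "chr1\ttest\texon\t101\t200\t.\t+\t.\tParent=GA",
    "chr1\ttest\texon\t301\t400\t.\t+\t.\tParent=GA",
    "chr1\ttest\tfive_prime_UTR\t101\t130\t.\t+\t.\tParent=GA",
    "chr1\ttest\tthree_prime_UTR\t371\t400\t.\t+\t.\tParent=GA",
    "chr1\ttest\tgene\t1001\t1300\t.\t-\t.\tID=GB",
    "chr1\ttest\texon\t1001\t1100\t.\t-\t.\tParent=GB",
    "chr1\ttest\texon\t1201\t1300\t.\t-\t.\tParent=GB")
  read_annotation(write_gff3_file(gff))
}

toy_genome <- function(seqs = c(chr1 = paste(rep("ACGT", 2500),
                                             collapse = ""))) {
  Biostrings::DNAStringSet(seqs)
}

# minimal editing matrix built directly (levels list: key -> named vector)
make_editing_matrix <- function(levels, samples, depth = 50) {
  keys <- names(levels)
  parts <- strsplit(keys, ":", fixed = TRUE)
  lv <- matrix(NA_real_, length(keys), nrow(samples),
               dimnames = list(keys, samples$sample_id))
  for (k in seq_along(levels)) lv[k, names(levels[[k]])] <- levels[[k]]
  dp <- ifelse(is.na(lv), NA_real_, depth)
  alt <- round(lv * depth)
  refc <- dp - alt
  obs <- !is.na(lv)
  sites <- data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    pos = as.integer(vapply(parts, `[`, "", 2L)),
    ref = "A", alt = "G", strand = "+", gene_id = NA_character_,
    region = NA_character_, edit_type = "A>G", key = keys,
    cov_tumor = as.integer(rowSums(
      obs[, samples$condition == "tumor", drop = FALSE])),
    cov_normal = as.integer(rowSums(
      obs[, samples$condition == "normal", drop = FALSE])),
    stringsAsFactors = FALSE)
  structure(list(sites = sites, samples = samples, level = lv, depth = dp,
                 alt = alt, ref = refc),
            class = "editing_matrix")
}

make_samples <- function(n_pairs) {
  data.frame(
    sample_id = c(sprintf("T%02d", seq_len(n_pairs)),
                  sprintf("N%02d", seq_len(n_pairs))),
    pair = rep(sprintf("P%02d", seq_len(n_pairs)), 2L),
    condition = rep(c("tumor", "normal"), each = n_pairs),
    stringsAsFactors = FALSE)
}

as_snp_mask <- function(df) {
  structure(df, class = c("snp_mask", "data.frame"))
}

# small, fast simulation configuration for tests
small_cfg <- function(...) {
  sim_config(n_pairs = 6L, genome_length = 60000L, n_genes = 12L,
             n_sites = c(shared = 40L, tumor_specific = 20L,
                         normal_specific = 20L),
             n_diff_shared = 10L, n_fst_sites = 10L,
             n_snps = 10L, n_dna_variants = 10L, n_background = 300L,
             n_splice_events = 20L, n_de_genes = 5L, ...)
}
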