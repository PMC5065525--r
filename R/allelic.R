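#' Genes informative for allele-specific expression
#'
#' Keeps genes with at least `min_reads` total reads (ref + alt) in every
#' sample under comparison - the "at least ten reads in all samples" filter.
#'
#' @param table long allelic count table (gene_id, sample_id, ref_reads,
#'   alt_reads)
#' @param samples sample ids under comparison (default: all in table)
#' @param min_reads minimum total reads per sample
#' @return character vector of informative gene ids
#' @export
filter_informative <- function(table, samples = NULL, min_reads = 10L) {
  if (is.null(samples)) samples <- unique(table$sample_id)
  tb <- table[table$sample_id %in% samples, , drop = FALSE]
  tot <- tb$ref_reads + tb$alt_reads
  ok <- tapply(tot >= min_reads, tb$gene_id, all)
  n_samp <- tapply(tb$sample_id, tb$gene_id, function(x) length(unique(x)))
  genes <- names(ok)[ok & n_samp == length(samples)]
  if (!length(genes)) warn_nb("no informative genes at min_reads = %d",
                              min_reads)
  genes
}

#' Classify allelic expression per gene and sample
#'
#' Allelic ratio = alt/(ref+alt). Calls are `biallelic` when the
#' minor-allele fraction is at least `biallelic_band` (0.20 by default),
#' otherwise monoallelic toward the major allele; observations under
#' `min_reads` are `uninformative` with a null ratio. The classifier is
#' symmetric under ref/alt swap.
#'
#' @param table long allelic count table
#' @param biallelic_band minimum minor-allele fraction for biallelic
#' @param min_reads minimum total reads per observation
#' @return list with `calls` (gene_id, sample_id, allelic_ratio, class) and
#'   `per_sample` biallelic fraction among informative calls
#' @export
classify_allelic <- function(table, biallelic_band = 0.20, min_reads = 10L) {
  tot <- table$ref_reads + table$alt_reads
  ratio <- ifelse(tot >= min_reads, table$alt_reads / tot, NA_real_)
  minor <- pmin(ratio, 1 - ratio)
  class <- ifelse(is.na(ratio), "uninformative",
                  ifelse(minor >= biallelic_band, "biallelic",
                         ifelse(ratio < 0.5, "monoallelic_ref",
                                "monoallelic_alt")))
  calls <- data.frame(gene_id = table$gene_id, sample_id = table$sample_id,
                      allelic_ratio = ratio, class = class,
                      stringsAsFactors = FALSE)
  inf <- calls[calls$class != "uninformative", , drop = FALSE]
  per_sample <- if (nrow(inf))
    vapply(split(inf$class, inf$sample_id),
           function(cl) mean(cl == "biallelic"), numeric(1))
  else setNames(numeric(0), character(0))
  list(calls = calls, per_sample = per_sample)
}

#' X:autosome dosage-compensation ratio between two groups
#'
#' (sum X-linked / sum autosomal expression) in group 1, divided by the same
#' quantity in group 2, on normalized counts by default (`normalized =
#' FALSE` compares raw totals).
#'
#' @param counts gene count matrix
#' @param group1,group2 sample id vectors
#' @param x_genes,autosome_genes gene id sets (non-empty)
#' @param normalized use median-of-ratios normalized counts
#' @return scalar ratio
#' @export
dosage_ratio <- function(counts, group1, group2, x_genes, autosome_genes,
                         normalized = TRUE) {
  if (!length(x_genes) || !length(autosome_genes))
    stop_nb("both gene sets must be non-empty")
  m <- if (normalized) normalize_counts(counts)$normalized else counts
  xg <- intersect(x_genes, rownames(m))
  ag <- intersect(autosome_genes, rownames(m))
  xa <- function(grp) {
    x <- sum(m[xg, grp, drop = FALSE])
    a <- sum(m[ag, grp, drop = FALSE])
    if (a == 0) stop_nb("zero autosomal denominator")
    x / a
  }
  r2 <- xa(group2)
  if (r2 == 0) stop_nb("zero X-linked expression in group 2")
  xa(group1) / r2
}
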