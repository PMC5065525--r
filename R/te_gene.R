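#' TE-gene expression correlation by distance bin
#'
#' Pearson (or Spearman) correlation of log2(normalized + 1) expression
#' across samples for each TE-gene pair, summarized per distance bin and,
#' for in-gene pairs, per orientation. The permuted "random" pairs provide
#' the null. Pairs with a zero-variance member or fewer than
#' `min_informative` shared samples are dropped and counted.
#'
#' @param pairs data.frame from [assign_te_to_gene()]
#' @param te_expr,gene_expr normalized (or raw count) matrices; log2(x+1)
#'   is taken internally
#' @param method "pearson" or "spearman"
#' @param min_informative minimum shared samples per pair
#' @return list with `per_pair` (te_id, gene_id, distance_bin, orientation,
#'   r), `summary` (bin x orientation medians), `n_dropped`
#' @export
te_gene_correlation <- function(pairs, te_expr, gene_expr,
                                method = c("pearson", "spearman"),
                                min_informative = 3L) {
  method <- match.arg(method)
  shared <- intersect(colnames(te_expr), colnames(gene_expr))
  if (length(shared) < min_informative)
    stop_nb("only %d shared samples", length(shared))
  keep <- pairs$te_id %in% rownames(te_expr) &
    pairs$gene_id %in% rownames(gene_expr) & !is.na(pairs$distance_bin)
  pr <- pairs[keep, , drop = FALSE]
  lt <- log2(te_expr[pr$te_id, shared, drop = FALSE] + 1)
  lgn <- log2(gene_expr[pr$gene_id, shared, drop = FALSE] + 1)
  if (method == "spearman") {
    lt <- t(apply(lt, 1L, rank)); lgn <- t(apply(lgn, 1L, rank))
  }
  ct <- lt - rowMeans(lt); cg <- lgn - rowMeans(lgn)
  num <- rowSums(ct * cg)
  den <- sqrt(rowSums(ct^2) * rowSums(cg^2))
  r <- ifelse(den > 0, num / den, NA_real_)
  dropped <- is.na(r)
  per_pair <- data.frame(te_id = pr$te_id, gene_id = pr$gene_id,
                         distance_bin = pr$distance_bin,
                         orientation = pr$orientation, r = r,
                         stringsAsFactors = FALSE)[!dropped, , drop = FALSE]
  med_row <- function(d, label)
    data.frame(bin = label, n_pairs = nrow(d), median_r = median(d$r),
               stringsAsFactors = FALSE)
  rows <- list()
  for (b in c("in_gene", "lt2.5kb", "2.5_5kb", "5_10kb", "10_20kb",
              "random")) {
    d <- per_pair[per_pair$distance_bin == b, , drop = FALSE]
    if (nrow(d)) rows[[b]] <- med_row(d, b)
  }
  for (o in c("sense", "antisense")) {
    d <- per_pair[per_pair$distance_bin == "in_gene" &
                    per_pair$orientation == o, , drop = FALSE]
    if (nrow(d)) rows[[paste0("in_gene_", o)]] <- med_row(d, paste0("in_gene_", o))
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(per_pair = per_pair, summary = summary, n_dropped = sum(dropped))
}
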