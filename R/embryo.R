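#' Stage-specific features in single-cell embryo profiles
#'
#' Per feature and stage: two-sided Wilcoxon rank-sum of the stage's cells
#' against all other cells on log2(normalized + 1), plus a mean-fold gate.
#' A feature is stage-specific when p < p_cutoff and the mean log2 fold vs
#' the rest is >= log2(fold_cutoff); a feature may be specific to several
#' stages. Stages with fewer than 3 cells are excluded with a warning.
#'
#' @param counts embryo count matrix (cells in columns)
#' @param sheet sample sheet with embryo stages
#' @param thresholds [nb_thresholds()]
#' @param method normalization; median-of-ratios resists the compositional
#'   fold compression a large marker set causes (it falls back to
#'   library-size scaling on matrices with no all-positive feature)
#' @return named list of data.frames (stage -> feature_id, log2fc, p)
#' @export
stage_specific_features <- function(counts, sheet,
                                    thresholds = nb_thresholds(),
                                    method = "median_ratio") {
  sheet <- validate_sample_sheet(sheet)
  sheet <- sheet[match(colnames(counts), sheet$sample_id), ]
  if (anyNA(sheet$sample_id)) stop_nb("matrix samples missing from sheet")
  stages <- unique(sheet$stage[!is.na(sheet$stage)])
  if (length(stages) < 2L) stop_nb("need >= 2 stages")
  sizes <- table(sheet$stage)
  small <- names(sizes)[sizes < 3L]
  if (length(small)) {
    warn_nb("stage(s) with < 3 cells excluded: %s",
            paste(small, collapse = ", "))
    stages <- setdiff(stages, small)
  }
  lg <- log2(normalize_counts(counts, method)$normalized + 1)
  out <- list()
  for (st in stages) {
    idx <- which(sheet$stage == st)
    rs <- ranksum_rows(lg, idx)
    lfc <- rowMeans(lg[, idx, drop = FALSE]) -
      rowMeans(lg[, -idx, drop = FALSE])
    hit <- rs$p < thresholds$p_cutoff & lfc >= log2(thresholds$fold_cutoff)
    out[[st]] <- data.frame(feature_id = rownames(counts)[hit],
                            log2fc = lfc[hit], p = rs$p[hit],
                            row.names = NULL, stringsAsFactors = FALSE)
  }
  out
}

#' Concordance of stage-specific features with the naive/primed axis
#'
#' For each stage set, the fraction of members called up-in-naive,
#' up-in-primed, or unchanged in the ESC differential-expression result
#' (e.g. 62% of morula-enriched TEs up in naive).
#'
#' @param stage_sets result of [stage_specific_features()]
#' @param de result of [differential_expression()]
#' @param naive_call,primed_call call labels
#' @return data.frame: stage, n_specific, frac_up_naive, frac_up_primed,
#'   frac_no_change
#' @export
concordance <- function(stage_sets, de, naive_call = "up_in_naive",
                        primed_call = "up_in_primed") {
  calls <- setNames(de$call, de$feature_id)
  rows <- lapply(names(stage_sets), function(st) {
    ids <- stage_sets[[st]]$feature_id
    n <- length(ids)
    if (n == 0L)
      return(data.frame(stage = st, n_specific = 0L,
                        frac_up_naive = NA_real_, frac_up_primed = NA_real_,
                        frac_no_change = NA_real_))
    cl <- calls[ids]
    cl[is.na(cl)] <- "no_change"                 # absent from DE result
    data.frame(stage = st, n_specific = n,
               frac_up_naive = sum(cl == naive_call) / n,
               frac_up_primed = sum(cl == primed_call) / n,
               frac_no_change = sum(cl != naive_call & cl != primed_call) / n)
  })
  do.call(rbind, rows)
}

#' Joint clustering of embryo cells and ESC samples on a TE family
#'
#' Subsets both matrices to the requested families, quantile-normalizes the
#' joined log-expression columns to a common distribution (the two datasets
#' have no shared scale), then clusters samples as in [top_sd_cluster()].
#' On the simulated world, naive ESC samples co-cluster with morula cells on
#' SVA features.
#'
#' @param esc_counts,embryo_counts count matrices sharing feature ids
#' @param families character vector of family names to keep
#' @param annotation GRanges TE annotation (mcols id, family)
#' @param k number of clusters to cut (default 2)
#' @return list with `hclust`, `labels`, `features`
#' @export
family_cluster <- function(esc_counts, embryo_counts, families, annotation,
                           k = 2L) {
  keep <- annotation$id[annotation$family %in% families]
  shared <- intersect(intersect(keep, rownames(esc_counts)),
                      rownames(embryo_counts))
  if (!length(shared)) stop_nb("no features in the requested families")
  if (ncol(esc_counts) + ncol(embryo_counts) < 3L)
    stop_nb("need >= 3 samples in total")
  lg1 <- log2(normalize_counts(esc_counts)$normalized[shared, , drop = FALSE] + 1)
  lg2 <- log2(normalize_counts(embryo_counts,
                               "library_size")$normalized[shared, , drop = FALSE] + 1)
  m <- cbind(lg1, lg2)
  # quantile normalization across all columns
  rk <- apply(m, 2L, rank, ties.method = "average")
  ref <- rowMeans(apply(m, 2L, sort))
  qn <- apply(rk, 2L, function(r) stats::approx(seq_along(ref), ref, r)$y)
  dimnames(qn) <- dimnames(m)
  cc <- suppressWarnings(cor(qn))
  cc[!is.finite(cc)] <- 0
  hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
  list(hclust = hc, labels = stats::cutree(hc, k = k), features = shared)
}
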