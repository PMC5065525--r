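#' Median-of-ratios normalization
#'
#' Size factor per sample = median over features (with all-positive counts)
#' of the ratio to the per-feature geometric mean, the standard RNA-seq
#' convention. When no feature is positive in every sample (sparse
#' single-cell matrices) the function falls back to library-size scaling
#' with a warning, or silently when `method = "library_size"`.
#'
#' @param counts feature x sample count matrix (>= 2 samples)
#' @param method "median_ratio" (default) or "library_size"
#' @return list with `normalized` matrix and `size_factors`
#' @export
normalize_counts <- function(counts, method = c("median_ratio",
                                                "library_size")) {
  method <- match.arg(method)
  if (ncol(counts) < 2L) stop_nb("normalization needs >= 2 samples")
  libsize_factors <- function() {
    ls <- colSums(counts)
    if (any(ls == 0)) stop_nb("sample(s) with zero total counts")
    ls / exp(mean(log(ls)))
  }
  sf <- if (method == "library_size") libsize_factors() else {
    pos <- rowSums(counts > 0) == ncol(counts)
    if (!any(pos)) {
      warn_nb("no feature positive in all samples; falling back to library-size scaling")
      libsize_factors()
    } else {
      lgm <- rowMeans(log(counts[pos, , drop = FALSE]))
      apply(counts[pos, , drop = FALSE], 2L,
            function(col) median(exp(log(col) - lgm)))
    }
  }
  list(normalized = sweep(counts, 2L, sf, "/"), size_factors = sf)
}

#' Differential expression between two sample groups
#'
#' Per feature: detection requires a normalized group mean >= `detect_min`
#' in at least one group; detected features get a two-sided Welch t-test on
#' log2(normalized + 1) with BH adjustment across detected features. A call
#' requires |log2fc| >= log2(fold_cutoff) and the p gate (adjusted p by
#' default; `use_raw_p = TRUE` gates on the raw p as in per-stage
#' concordance scoring).
#'
#' @param counts count matrix containing both groups
#' @param groupA,groupB sample id vectors (>= 2 each)
#' @param thresholds [nb_thresholds()] object
#' @param nameA,nameB labels used in the `call` column
#'   (`up_in_<nameB>` means higher in groupB)
#' @param use_raw_p gate on raw p < p_cutoff instead of padj
#' @param detect_min normalized-mean detection threshold
#' @return data.frame: feature_id, base_mean, log2fc (B over A), p, padj,
#'   call, detected
#' @export
differential_expression <- function(counts, groupA, groupB,
                                    thresholds = nb_thresholds(),
                                    nameA = "primed", nameB = "naive",
                                    use_raw_p = FALSE, detect_min = 1) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop_nb("each group needs >= 2 samples")
  miss <- setdiff(c(groupA, groupB), colnames(counts))
  if (length(miss)) stop_nb("sample(s) not in matrix: %s",
                            paste(miss, collapse = ", "))
  sub <- counts[, c(groupA, groupB), drop = FALSE]
  nrm <- normalize_counts(sub)$normalized
  ia <- match(groupA, colnames(nrm)); ib <- match(groupB, colnames(nrm))
  mA <- rowMeans(nrm[, ia, drop = FALSE])
  mB <- rowMeans(nrm[, ib, drop = FALSE])
  detected <- pmax(mA, mB) >= detect_min
  lg <- log2(nrm + 1)
  wt <- welch_t_rows(lg, ia, ib)
  log2fc <- wt$diff
  p <- ifelse(detected, wt$p, NA_real_)
  padj <- rep(NA_real_, length(p))
  padj[detected] <- bh_adjust(p[detected])
  gate <- if (use_raw_p) p < thresholds$p_cutoff
          else padj < thresholds$padj_cutoff
  gate[is.na(gate)] <- FALSE
  call <- rep("no_change", nrow(sub))
  up <- gate & log2fc >= log2(thresholds$fold_cutoff)
  dn <- gate & log2fc <= -log2(thresholds$fold_cutoff)
  call[up] <- paste0("up_in_", nameB)
  call[dn] <- paste0("up_in_", nameA)
  data.frame(feature_id = rownames(sub), base_mean = (mA + mB) / 2,
             log2fc = log2fc, p = p, padj = padj, call = call,
             detected = detected, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Per-family polarization of differential expression
#'
#' For each TE family: how many integrants were detected, how many of those
#' were differentially expressed, and how the DE calls split between the
#' naive and primed directions. Percentages are half-up rounded to one
#' decimal (e.g. 610 DE of 847 detected HERVH-int = 72.0% DE, of which
#' 546 primed-higher = 89.5%).
#'
#' @param de result of [differential_expression()]
#' @param families named character vector feature_id -> family
#' @param naive_call,primed_call call labels counted as naive/primed-up
#' @return data.frame, one row per family
#' @export
polarization_summary <- function(de, families,
                                 naive_call = "up_in_naive",
                                 primed_call = "up_in_primed") {
  miss <- setdiff(de$feature_id, names(families))
  if (length(miss)) stop_nb("no family label for %d feature(s), e.g. %s",
                            length(miss), miss[1])
  fam <- families[de$feature_id]
  out <- lapply(sort(unique(fam)), function(f) {
    d <- de[fam == f, , drop = FALSE]
    n_detected <- sum(d$detected)
    n_up_naive <- sum(d$call == naive_call)
    n_up_primed <- sum(d$call == primed_call)
    n_de <- n_up_naive + n_up_primed
    data.frame(family = f, n_detected = n_detected, n_de = n_de,
               pct_de = round_half_up(100 * n_de / max(n_detected, 1), 1),
               n_up_naive = n_up_naive, n_up_primed = n_up_primed,
               pct_up_naive_of_de =
                 round_half_up(100 * n_up_naive / max(n_de, 1), 1),
               pct_up_primed_of_de =
                 round_half_up(100 * n_up_primed / max(n_de, 1), 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Subfamily composition of the top-n differential integrants
#'
#' Ranks DE-called features by |log2fc| (or signed log2fc toward one state
#' with `rank_key = "signed"`) and tallies subfamily membership among the
#' top n. Ties at rank n are all included and the realized n reported.
#'
#' @param de result of [differential_expression()]
#' @param n number of top features
#' @param subfamilies named character vector feature_id -> subfamily
#' @param rank_key "abs" or "signed" (descending signed log2fc)
#' @return list with `tally` (named counts), `n_requested`, `n_actual`
#' @export
top_n_composition <- function(de, n, subfamilies, rank_key = c("abs",
                                                               "signed")) {
  rank_key <- match.arg(rank_key)
  d <- de[de$call != "no_change", , drop = FALSE]
  if (n > nrow(d)) stop_nb("n = %d exceeds the %d DE features", n, nrow(d))
  key <- if (rank_key == "abs") abs(d$log2fc) else d$log2fc
  o <- order(key, decreasing = TRUE)
  cut <- key[o][n]
  sel <- d$feature_id[key >= cut]          # include all tied at rank n
  tal <- table(subfamilies[sel])
  list(tally = sort(tal, decreasing = TRUE), n_requested = n,
       n_actual = length(sel))
}

#' Cluster samples on the top-SD features
#'
#' Selects the `n_top` features with the largest SD of log2(normalized + 1),
#' then average-linkage hierarchical clustering of samples on
#' 1 - Pearson correlation distance; cluster labels at k = 2 are returned
#' (the naive/primed split on the default simulated world).
#'
#' @param counts count matrix
#' @param n_top number of features to keep (<= nrow)
#' @param method normalization method passed to [normalize_counts()]
#' @return list with `features`, `hclust`, `labels` (k = 2)
#' @export
top_sd_cluster <- function(counts, n_top, method = "median_ratio") {
  if (n_top > nrow(counts)) stop_nb("n_top exceeds feature count")
  lg <- log2(normalize_counts(counts, method)$normalized + 1)
  sds <- matrixStats::rowSds(lg)
  if (all(sds == 0)) stop_nb("zero variance: constant matrix")
  o <- order(sds, decreasing = TRUE)[seq_len(n_top)]
  sel <- lg[o, , drop = FALSE]
  cc <- suppressWarnings(cor(sel))
  cc[!is.finite(cc)] <- 0
  hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
  list(features = rownames(counts)[o], hclust = hc,
       labels = stats::cutree(hc, k = 2))
}

#' Sample PCA on log-normalized expression
#'
#' SVD of feature-centered log2(normalized + 1); deterministic sign
#' convention (the largest-magnitude loading of each component is positive).
#'
#' @param counts count matrix (>= 3 samples)
#' @param features optional feature subset (>= 2 features)
#' @param method normalization method
#' @return list with `coords` (sample x PC1/PC2), `var_explained`
#' @export
pca_samples <- function(counts, features = NULL, method = "median_ratio") {
  if (ncol(counts) < 3L) stop_nb("PCA needs >= 3 samples")
  lg <- log2(normalize_counts(counts, method)$normalized + 1)
  if (!is.null(features)) lg <- lg[features, , drop = FALSE]
  if (nrow(lg) < 2L) stop_nb("PCA needs >= 2 features")
  pc <- stats::prcomp(t(lg), center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  for (j in seq_len(k)) {
    flip <- sign(pc$rotation[which.max(abs(pc$rotation[, j])), j])
    if (flip < 0) { pc$x[, j] <- -pc$x[, j]
                    pc$rotation[, j] <- -pc$rotation[, j] }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(coords = pc$x[, seq_len(k), drop = FALSE],
       var_explained = ve[seq_len(k)])
}
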