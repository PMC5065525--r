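#' Analysis thresholds
#'
#' Bundle of the cutoffs used across the pipeline, with the study's defaults:
#' a 2-fold expression cutoff with p / adjusted-p gates at 0.05, a 1% FDR for
#' the "overexpressed" TE set, the 0.30 hypomethylation cutoff and the
#' (0.30, 0.70) intermediate-methylation band used by the imprinted-DMR
#' erasure rule and the X-CGI flag, a minimum of 10 allelic reads per sample,
#' a +/- 20 kb metaprofile window, the top-10,000-SD feature selection for
#' clustering, and the 1:10,000 human:mouse chimera detection limit.
#'
#' @param fold_cutoff minimum fold change called differential (> 1)
#' @param p_cutoff raw p-value gate
#' @param padj_cutoff BH-adjusted p-value gate
#' @param overexpr_fdr FDR for the overexpressed-TE methylation contrast
#' @param erase_level methylation level below which a region counts as
#'   hypomethylated (mCpG/CpG < this)
#' @param intermediate_band closed interval of intermediate methylation
#' @param min_allelic_reads minimum reads per sample for an informative gene
#' @param metaprofile_halfwidth half-window around TE 5' ends, bp
#' @param top_sd_n number of highest-SD features used for clustering
#' @param detection_limit human:mouse cell ratio at the qPCR detection line
#' @return an object of class `nb_thresholds` (a validated list)
#' @export
nb_thresholds <- function(fold_cutoff = 2.0,
                          p_cutoff = 0.05,
                          padj_cutoff = 0.05,
                          overexpr_fdr = 0.01,
                          erase_level = 0.30,
                          intermediate_band = c(0.30, 0.70),
                          min_allelic_reads = 10L,
                          metaprofile_halfwidth = 20000L,
                          top_sd_n = 10000L,
                          detection_limit = 1e-4) {
  th <- list(fold_cutoff = fold_cutoff, p_cutoff = p_cutoff,
             padj_cutoff = padj_cutoff, overexpr_fdr = overexpr_fdr,
             erase_level = erase_level,
             intermediate_band = as.numeric(intermediate_band),
             min_allelic_reads = as.integer(min_allelic_reads),
             metaprofile_halfwidth = as.integer(metaprofile_halfwidth),
             top_sd_n = as.integer(top_sd_n),
             detection_limit = detection_limit)
  for (nm in c("p_cutoff", "padj_cutoff", "overexpr_fdr"))
    if (th[[nm]] <= 0 || th[[nm]] >= 1)
      stop_nb("%s must be in (0,1), got %g", nm, th[[nm]])
  if (th$fold_cutoff <= 1) stop_nb("fold_cutoff must be > 1")
  if (length(th$intermediate_band) != 2L ||
      th$intermediate_band[1] >= th$intermediate_band[2])
    stop_nb("intermediate_band must be an increasing interval")
  if (th$min_allelic_reads < 0L) stop_nb("min_allelic_reads must be >= 0")
  structure(th, class = "nb_thresholds")
}

#' @export
print.nb_thresholds <- function(x, ...) {
  cat("naivebench thresholds:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm,
                                   paste(format(x[[nm]]), collapse = "-")))
  invisible(x)
}

# Merge user overrides (a plain list, e.g. from YAML) into defaults.
resolve_thresholds <- function(overrides = NULL) {
  if (is.null(overrides)) return(nb_thresholds())
  if (inherits(overrides, "nb_thresholds")) return(overrides)
  do.call(nb_thresholds, overrides)
}
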