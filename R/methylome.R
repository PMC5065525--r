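#' Genome-wide weighted methylation level
#'
#' Coverage-weighted level sum(meth_reads)/sum(total_reads) over all sites
#' of one context (mCpG/CpG or mCH/CH).
#'
#' @param calls allc-style table (see [read_allc()])
#' @param context "CpG" or "CH"
#' @return fraction in `[0,1]`, or NA with a warning when no covered site
#' @export
global_level <- function(calls, context = "CpG") {
  calls <- as.data.frame(calls)   # a data.table would scope 'context' to itself
  d <- calls[calls$context == context & calls$total_reads > 0, , drop = FALSE]
  if (!nrow(d)) {
    warn_nb("no covered %s sites", context)
    return(NA_real_)
  }
  sum(as.numeric(d$meth_reads)) / sum(as.numeric(d$total_reads))
}

#' Weighted methylation level per region
#'
#' Sites are matched to regions by half-open interval membership of the
#' 0-based position (BED convention). Regions without covered sites get a
#' null (NA) level.
#'
#' @param calls allc-style table
#' @param regions GRanges with mcols `id` (or a BED path)
#' @param context "CpG" or "CH"
#' @return data.frame: region_id, context, weighted_level, n_sites,
#'   mean_coverage
#' @export
region_levels <- function(calls, regions, context = "CpG") {
  if (is.character(regions)) regions <- read_bed(regions)
  rid <- if (!is.null(regions$id)) regions$id
         else if (!is.null(regions$name)) regions$name
         else sprintf("region%05d", seq_along(regions))
  calls <- as.data.frame(calls)
  d <- calls[calls$context == context, , drop = FALSE]
  sites <- GenomicRanges::GRanges(d$chrom,
                                  IRanges::IRanges(start = d$pos, width = 1L),
                                  strand = "*")
  hits <- GenomicRanges::findOverlaps(sites, regions, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  meth <- tapply(as.numeric(d$meth_reads[q]), factor(s, seq_along(regions)),
                 sum, default = 0)
  tot <- tapply(as.numeric(d$total_reads[q]), factor(s, seq_along(regions)),
                sum, default = 0)
  n <- tapply(rep(1, length(q)), factor(s, seq_along(regions)), sum,
              default = 0)
  data.frame(region_id = rid, context = context,
             weighted_level = ifelse(tot > 0, meth / tot, NA_real_),
             n_sites = as.integer(n),
             mean_coverage = ifelse(n > 0, tot / n, NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Methylation contrast of overexpressed vs background TEs
#'
#' Two-sided Mann-Whitney U test comparing region methylation levels of the
#' naive-overexpressed set (called at 1% FDR upstream) against the family
#' background; medians are always reported, the p-value is null when either
#' set has fewer than 3 non-null levels.
#'
#' @param levels data.frame from [region_levels()]
#' @param over_ids,background_ids region_id sets
#' @return list: median_over, median_back, U, p, n_over, n_back
#' @export
overexpressed_te_methylation <- function(levels, over_ids, background_ids) {
  lv <- setNames(levels$weighted_level, levels$region_id)
  a <- lv[intersect(over_ids, names(lv))]
  b <- lv[intersect(background_ids, names(lv))]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop_nb("empty level set")
  res <- list(median_over = median(a), median_back = median(b),
              U = NA_real_, p = NA_real_,
              n_over = length(a), n_back = length(b))
  if (length(a) >= 3L && length(b) >= 3L) {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    res$U <- unname(wt$statistic)
    res$p <- wt$p.value
  }
  res
}

#' Classify imprinted-DMR methylation erasure
#'
#' A DMR is *eligible* when its primed-state level lies in the closed
#' intermediate band (0.30-0.70 by default) and each state has at least
#' `min_sites` covered CpGs. An eligible DMR is *erased* when both the naive
#' and the re-primed level drop below `erase_level` (< 0.30), otherwise
#' *retained*. `fraction_erased` uses eligible DMRs as denominator
#' (`denominator = "all"` divides by all DMRs instead).
#'
#' @param primed,naive,reprimed data.frames from [region_levels()] over the
#'   same DMR ids
#' @param thresholds [nb_thresholds()]
#' @param min_sites minimum covered CpGs per DMR and state
#' @param denominator "eligible" or "all"
#' @return list with `calls` (dmr_id, levels, eligible, verdict, reason) and
#'   `fraction_erased`
#' @export
classify_imprinted_dmrs <- function(primed, naive, reprimed,
                                    thresholds = nb_thresholds(),
                                    min_sites = 5L,
                                    denominator = c("eligible", "all")) {
  denominator <- match.arg(denominator)
  ids <- primed$region_id
  if (!setequal(ids, naive$region_id) || !setequal(ids, reprimed$region_id))
    stop_nb("the three states must cover the same DMR ids")
  pv <- primed[match(ids, primed$region_id), ]
  nv <- naive[match(ids, naive$region_id), ]
  rv <- reprimed[match(ids, reprimed$region_id), ]
  band <- thresholds$intermediate_band
  covered <- pv$n_sites >= min_sites & nv$n_sites >= min_sites &
    rv$n_sites >= min_sites & !is.na(pv$weighted_level) &
    !is.na(nv$weighted_level) & !is.na(rv$weighted_level)
  eligible <- covered & pv$weighted_level >= band[1] &
    pv$weighted_level <= band[2]
  erased <- eligible & nv$weighted_level < thresholds$erase_level &
    rv$weighted_level < thresholds$erase_level
  verdict <- ifelse(!eligible, "ineligible",
                    ifelse(erased, "erased", "retained"))
  reason <- ifelse(eligible, "",
                   ifelse(!covered, "insufficient coverage",
                          "primed level outside intermediate band"))
  calls <- data.frame(dmr_id = ids, primed_level = pv$weighted_level,
                      naive_level = nv$weighted_level,
                      reprimed_level = rv$weighted_level,
                      eligible = eligible, verdict = verdict,
                      reason = reason, row.names = NULL,
                      stringsAsFactors = FALSE)
  den <- if (denominator == "eligible") sum(eligible) else length(ids)
  list(calls = calls,
       fraction_erased = if (den > 0) sum(erased) / den else NA_real_)
}

#' X-linked promoter-CGI methylation per sample
#'
#' Distribution summary (median, quartiles) of X-linked promoter CGI
#' methylation per sample; samples whose median falls in the intermediate
#' band are flagged - the signature of an inactive X in primed female
#' lines.
#'
#' @param levels_by_sample named list of [region_levels()] data.frames over
#'   the X-linked promoter CGIs, one per sample
#' @param sheet sample sheet (sex labels required)
#' @param thresholds [nb_thresholds()]
#' @return data.frame: sample_id, sex, n_regions, median, q25, q75,
#'   flagged_intermediate
#' @export
xlinked_cgi_methylation <- function(levels_by_sample, sheet,
                                    thresholds = nb_thresholds()) {
  sheet <- validate_sample_sheet(sheet)
  band <- thresholds$intermediate_band
  rows <- lapply(names(levels_by_sample), function(sm) {
    lv <- levels_by_sample[[sm]]$weighted_level
    lv <- lv[!is.na(lv)]
    if (!length(lv)) stop_nb("sample %s has no covered CGI regions", sm)
    qs <- quantile(lv, c(0.25, 0.5, 0.75), names = FALSE)
    sex <- sheet$sex[match(sm, sheet$sample_id)]
    data.frame(sample_id = sm, sex = sex %||% NA_character_,
               n_regions = length(lv), median = qs[2], q25 = qs[1],
               q75 = qs[3],
               flagged_intermediate = qs[2] >= band[1] & qs[2] <= band[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
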