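#' ChIP/input log-ratio metaprofile at TE 5' ends
#'
#' Both tracks are depth-normalized to equal totals, a pseudocount is added
#' per bin, and the per-bin log2(ChIP/input) is averaged across anchor
#' windows of +/- `halfwidth` bp around each element's 5' end (start on +,
#' end on -; minus-strand windows are reversed so offsets read
#' 5' -> 3'). Windows running off a chromosome are truncated (missing bins
#' ignored) and counted.
#'
#' @param chip,input coverage tracks ([coverage_track()] /
#'   [read_bedgraph()]) on the same bin grid
#' @param anchors GRanges of elements with strands
#' @param halfwidth window half-width in bp
#' @param pseudo pseudocount per bin after depth normalization
#' @return list: `offsets` (bp), `mean_log_ratio`, `n_anchors`,
#'   `n_truncated`
#' @export
metaprofile <- function(chip, input, anchors, halfwidth = 20000L,
                        pseudo = 1) {
  if (chip$bin_width != input$bin_width)
    stop_nb("tracks are on different bin grids")
  bw <- chip$bin_width
  if (halfwidth %% bw != 0L)
    stop_nb("halfwidth must be a multiple of the bin width (%d)", bw)
  # fixed reference depth: makes the profile invariant to rescaling both
  # tracks (a mean-of-totals target would not be, via the pseudocount)
  target <- 1e6
  ratio_by_chrom <- function() {
    ch <- data.table::as.data.table(chip$bins)
    inp <- data.table::as.data.table(input$bins)
    data.table::setnames(inp, "count", "count_in")
    m <- merge(ch, inp, by = c("chrom", "start", "end"), all = TRUE)
    m[is.na(m$count), "count"] <- 0
    m[is.na(m$count_in), "count_in"] <- 0
    m$lr <- log2((m$count * target / chip$total_reads + pseudo) /
                   (m$count_in * target / input$total_reads + pseudo))
    split(m[, c("start", "lr")], m$chrom)
  }
  byc <- ratio_by_chrom()
  k <- halfwidth %/% bw
  offs <- seq.int(-k, k)
  minus <- as.character(GenomicRanges::strand(anchors)) == "-"
  a0 <- ifelse(minus, GenomicRanges::end(anchors) - 1L,
               GenomicRanges::start(anchors) - 1L)   # 0-based 5' position
  abin <- a0 %/% bw
  chrom <- as.character(GenomicRanges::seqnames(anchors))
  acc <- numeric(length(offs)); cnt <- numeric(length(offs))
  n_trunc <- 0L
  for (i in seq_along(anchors)) {
    tab <- byc[[chrom[i]]]
    if (is.null(tab)) { n_trunc <- n_trunc + 1L; next }
    lr_by_bin <- tab$lr[match((abin[i] + offs) * bw, tab$start)]
    if (minus[i]) lr_by_bin <- rev(lr_by_bin)
    ok <- !is.na(lr_by_bin)
    if (any(!ok)) n_trunc <- n_trunc + 1L
    acc[ok] <- acc[ok] + lr_by_bin[ok]
    cnt[ok] <- cnt[ok] + 1
  }
  list(offsets = offs * bw, mean_log_ratio = ifelse(cnt > 0, acc / cnt,
                                                    NA_real_),
       n_anchors = length(anchors), n_truncated = n_trunc)
}
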