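# Small in-code fixtures shared across test files.

toy_counts <- function(n_feat = 20L, n_samp = 6L, seed = 101L, mu = 60) {
  withr::with_seed(seed, {
    m <- matrix(rnbinom(n_feat * n_samp, size = 10, mu = mu), nrow = n_feat,
                dimnames = list(sprintf("f%03d", seq_len(n_feat)),
                                sprintf("s%02d", seq_len(n_samp))))
  })
  storage.mode(m) <- "integer"
  m
}

toy_sheet <- function(states, reps = 1L) {
  st <- rep(states, each = reps)
  data.frame(sample_id = paste0(st, "_r", rep(seq_len(reps),
                                              times = length(states))),
             state = st, stage = NA_character_, sex = "female",
             replicate = rep(seq_len(reps), times = length(states)),
             stringsAsFactors = FALSE)
}

toy_te <- function(chrom, start0, end0, strand, family, id = NULL) {
  gr <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = start0 + 1L, end = end0), strand = strand)
  gr$id <- id %||% sprintf("%s_%02d", family, seq_along(gr))
  gr$family <- family
  gr$subfamily <- family
  gr$merged <- FALSE
  gr$constituents <- ""
  gr
}

toy_genes <- function(chrom, start0, end0, strand = "+", id = NULL) {
  gr <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = start0 + 1L, end = end0), strand = strand)
  gr$id <- id %||% sprintf("g%02d", seq_along(gr))
  gr
}

toy_allc <- function(chrom, pos, meth, total, context = "CpG",
                     strand = "+") {
  data.frame(chrom = chrom, pos = pos, strand = strand, context = context,
             meth_reads = meth, total_reads = total,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ari <- naivebench:::adjusted_rand_index

# total bp covered by a set of loci (strand-blind union)
granges_span <- function(gr)
  sum(GenomicRanges::width(GenomicRanges::reduce(gr, ignore.strand = TRUE)))

# flat binned coverage track over one toy chromosome
flat_track <- function(count, n_bins = 600L, bw = 100L, chrom = "chr1") {
  if (length(count) > 1L) n_bins <- length(count)
  coverage_track(data.frame(chrom = chrom,
                            start = (seq_len(n_bins) - 1L) * bw,
                            end = seq_len(n_bins) * bw, count = count))
}
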