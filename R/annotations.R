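#' @importFrom GenomicRanges GRanges seqnames strand start end findOverlaps
#'   distance
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols
NULL

distance_bins <- c("in_gene", "lt2.5kb", "2.5_5kb", "5_10kb", "10_20kb",
                   "random")

# Internal: annotation data.frame (BED-style 0-based half-open) -> GRanges.
anno_to_granges <- function(df) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand)
  for (nm in setdiff(names(df), c("chrom", "start", "end", "strand")))
    S4Vectors::mcols(gr)[[nm]] <- df[[nm]]
  gr
}

granges_to_anno <- function(gr) {
  df <- data.frame(
    id = gr$id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)))
  cbind(df, as.data.frame(S4Vectors::mcols(gr))[
    , setdiff(colnames(S4Vectors::mcols(gr)), "id"), drop = FALSE])
}

#' Read / write a TE annotation table (TSV)
#'
#' Columns: id, family, subfamily, chrom, start, end (0-based half-open),
#' strand, merged, constituents.
#'
#' @param path TSV file
#' @return GRanges with mcols id, family, subfamily, merged, constituents
#' @export
read_te_annotation <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  if (!"merged" %in% names(df)) df$merged <- FALSE
  if (!"constituents" %in% names(df)) df$constituents <- ""
  anno_to_granges(df)
}

#' @rdname read_te_annotation
#' @param tes GRanges TE annotation
#' @export
write_te_annotation <- function(tes, path) {
  data.table::fwrite(granges_to_anno(tes), path, sep = "\t")
  invisible(path)
}

#' Read / write a gene annotation table (TSV)
#' @param path TSV with id, chrom, start, end, strand, is_krab_zfp,
#'   is_imprinted, is_x_linked
#' @return GRanges
#' @export
read_gene_annotation <- function(path) {
  anno_to_granges(as.data.frame(data.table::fread(path, sep = "\t")))
}

#' @rdname read_gene_annotation
#' @param genes GRanges gene annotation
#' @export
write_gene_annotation <- function(genes, path) {
  data.table::fwrite(granges_to_anno(genes), path, sep = "\t")
  invisible(path)
}

#' Merge LTR7 promoters with adjacent HERVH-int bodies
#'
#' RepeatMasker annotates the HERVH provirus as separate LTR and internal
#' fragments. An LTR7 element that sits 5'-adjacent to an HERVH-int on the
#' same strand (gap at most `max_gap` bp) is replaced together with that
#' internal fragment by one merged locus of family `LTR7-HERVH` spanning
#' both. Everything else passes through unchanged. Merging is idempotent and
#' preserves total covered span.
#'
#' @param tes GRanges TE annotation (mcols id, family, subfamily)
#' @param max_gap maximum gap in bp between LTR and internal fragment
#' @return GRanges with merged loci (`merged == TRUE`, constituents recorded)
#' @export
merge_ltr_int <- function(tes, max_gap = 50L) {
  tes <- GenomicRanges::sort(tes, ignore.strand = TRUE)
  if (is.null(tes$merged)) tes$merged <- FALSE
  if (is.null(tes$constituents)) tes$constituents <- ""
  # same-family overlapping duplicates: warn, keep both
  for (fam in unique(tes$family)) {
    sub <- tes[tes$family == fam]
    ov <- GenomicRanges::findOverlaps(sub, drop.self = TRUE,
                                      drop.redundant = TRUE,
                                      ignore.strand = TRUE)
    if (length(ov))
      warn_nb("%d overlapping same-family (%s) duplicate pair(s); keeping both",
              length(ov), fam)
  }
  li <- which(tes$family == "LTR7")
  hi <- which(tes$family == "HERVH-int")
  if (!length(li) || !length(hi)) return(tes)
  hits <- GenomicRanges::findOverlaps(tes[li], tes[hi], maxgap = max_gap,
                                      ignore.strand = TRUE)
  cand <- data.frame(l = li[S4Vectors::queryHits(hits)],
                     h = hi[S4Vectors::subjectHits(hits)])
  if (nrow(cand)) {
    same_strand <- as.character(GenomicRanges::strand(tes[cand$l])) ==
      as.character(GenomicRanges::strand(tes[cand$h]))
    gap <- GenomicRanges::distance(tes[cand$l], tes[cand$h],
                                   ignore.strand = TRUE)
    disjoint <- GenomicRanges::end(tes[cand$l]) <
      GenomicRanges::start(tes[cand$h]) |
      GenomicRanges::start(tes[cand$l]) > GenomicRanges::end(tes[cand$h])
    plus <- as.character(GenomicRanges::strand(tes[cand$l])) == "+"
    five_prime <- ifelse(plus,
      GenomicRanges::end(tes[cand$l]) < GenomicRanges::start(tes[cand$h]),
      GenomicRanges::start(tes[cand$l]) > GenomicRanges::end(tes[cand$h]))
    keep <- same_strand & disjoint & five_prime & !is.na(gap) & gap <= max_gap
    cand <- cand[keep, , drop = FALSE]
    cand$gap <- gap[keep]
  }
  if (!nrow(cand)) return(tes)
  # greedy: smallest gap first, each fragment used once
  cand <- cand[order(cand$gap), , drop = FALSE]
  used_l <- used_h <- integer(0)
  pairs <- list()
  for (k in seq_len(nrow(cand))) {
    if (cand$l[k] %in% used_l || cand$h[k] %in% used_h) next
    used_l <- c(used_l, cand$l[k]); used_h <- c(used_h, cand$h[k])
    pairs[[length(pairs) + 1L]] <- cand[k, ]
  }
  pairs <- do.call(rbind, pairs)
  merged <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(tes[pairs$l]),
    ranges = IRanges::IRanges(
      start = pmin(GenomicRanges::start(tes[pairs$l]),
                   GenomicRanges::start(tes[pairs$h])),
      end = pmax(GenomicRanges::end(tes[pairs$l]),
                 GenomicRanges::end(tes[pairs$h]))),
    strand = GenomicRanges::strand(tes[pairs$l]))
  merged$id <- paste0(tes$id[pairs$l], "|", tes$id[pairs$h])
  merged$family <- "LTR7-HERVH"
  merged$subfamily <- "LTR7-HERVH"
  merged$merged <- TRUE
  merged$constituents <- paste(tes$id[pairs$l], tes$id[pairs$h], sep = ",")
  out <- c(tes[-c(pairs$l, pairs$h)], merged)
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

# Edge-to-edge distance bin for non-overlapping pairs (bp between
# intervals); half-open [lo, hi) bins. Pairs beyond 20 kb get NA.
bin_distance <- function(d, overlapping) {
  out <- rep(NA_character_, length(d))
  out[overlapping] <- "in_gene"
  idx <- !overlapping & !is.na(d)
  brk <- c(0, 2500, 5000, 10000, 20000)
  lab <- c("lt2.5kb", "2.5_5kb", "5_10kb", "10_20kb")
  for (k in seq_along(lab))
    out[idx & d >= brk[k] & d < brk[k + 1]] <- lab[k]
  out
}

#' Pair each TE with its closest gene and a distance bin
#'
#' Distance is edge-to-edge (bases strictly between the intervals); a TE
#' overlapping any part of a gene is `in_gene` at distance 0. Ties are broken
#' toward the lexicographically smaller gene id. Orientation is `sense` when
#' strands are equal. A "random" control set with the same TEs but permuted
#' gene assignments (seeded) is appended with bin `random`. TEs on a
#' chromosome without genes are reported in `attr(,"unpaired")`.
#'
#' @param tes,genes GRanges annotations with mcols `id`
#' @param seed seed for the permuted random control
#' @return data.frame(te_id, gene_id, distance, distance_bin, orientation)
#' @export
assign_te_to_gene <- function(tes, genes, seed = 1L) {
  te_chr <- as.character(GenomicRanges::seqnames(tes))
  gene_chr <- unique(as.character(GenomicRanges::seqnames(genes)))
  unpaired <- tes$id[!te_chr %in% gene_chr]
  keep <- which(te_chr %in% gene_chr)
  if (length(unpaired))
    warn_nb("%d TE(s) on chromosome(s) without genes left unpaired",
            length(unpaired))
  tk <- tes[keep]
  # candidates per TE: nearest gene on each side plus any overlapped gene
  # (distanceToNearest does not report ties; the tie-break is ours)
  pre <- GenomicRanges::precede(tk, genes, ignore.strand = TRUE)
  fol <- GenomicRanges::follow(tk, genes, ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(tk, genes, ignore.strand = TRUE)
  cand <- rbind(
    data.frame(q = seq_along(tk), s = pre),
    data.frame(q = seq_along(tk), s = fol),
    data.frame(q = S4Vectors::queryHits(ov),
               s = S4Vectors::subjectHits(ov)))
  cand <- cand[!is.na(cand$s), , drop = FALSE]
  cand$d <- GenomicRanges::distance(tk[cand$q], genes[cand$s],
                                    ignore.strand = TRUE)
  cand$gene_id <- genes$id[cand$s]
  # nearest by distance; ties broken toward the smaller gene id
  cand <- cand[order(cand$q, cand$d, cand$gene_id), , drop = FALSE]
  hd <- cand[!duplicated(cand$q), , drop = FALSE]
  overlapping <- GenomicRanges::countOverlaps(tk[hd$q], genes,
                                              ignore.strand = TRUE) > 0L
  te_strand <- as.character(GenomicRanges::strand(tk[hd$q]))
  gene_strand <- as.character(GenomicRanges::strand(genes[hd$s]))
  real <- data.frame(
    te_id = tk$id[hd$q],
    gene_id = hd$gene_id,
    distance = ifelse(overlapping, 0L, hd$d),
    distance_bin = bin_distance(hd$d, overlapping),
    orientation = ifelse(te_strand == gene_strand, "sense", "antisense"),
    stringsAsFactors = FALSE)
  rand <- real
  perm <- withr::with_seed(substream_seed(seed, "random_pairs"),
                           sample.int(nrow(real)))
  rand$gene_id <- real$gene_id[perm]
  gs <- gene_strand[perm]
  rand$orientation <- ifelse(te_strand == gs, "sense", "antisense")
  rand$distance <- NA_integer_
  rand$distance_bin <- "random"
  out <- rbind(real, rand)
  attr(out, "unpaired") <- unpaired
  out
}
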