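#' @import data.table
NULL

nb_states <- c("primed", "naive_5iLA", "naive_4iLA", "naive_t2iL_DOX",
               "reprimed", "embryo")
nb_stages <- c("oocyte", "zygote", "two_cell", "four_cell", "eight_cell",
               "morula", "late_blastocyst_TE", "late_blastocyst_PE",
               "late_blastocyst_EPI")
nb_sexes <- c("female", "male", "unknown")

#' Validate a sample sheet
#'
#' A sample sheet is a data.frame with columns `sample_id`, `state`, `stage`,
#' `sex`, `replicate`. Sample ids must be unique; embryo samples carry a
#' developmental stage, non-embryo samples must not.
#'
#' @param sheet data.frame
#' @return the sheet, invisibly normalized (stage NA for non-embryo)
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "state", "sex", "replicate")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop_nb("sample sheet missing column(s): %s",
                            paste(miss, collapse = ", "))
  if (!"stage" %in% names(sheet)) sheet$stage <- NA_character_
  sheet$stage[!is.na(sheet$stage) & sheet$stage == ""] <- NA_character_
  if (anyDuplicated(sheet$sample_id))
    stop_nb("duplicate sample_id(s): %s",
            paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]),
                  collapse = ", "))
  bad <- setdiff(unique(sheet$state), nb_states)
  if (length(bad)) stop_nb("unknown state(s): %s", paste(bad, collapse = ", "))
  bad <- setdiff(unique(sheet$stage[!is.na(sheet$stage)]), nb_stages)
  if (length(bad)) stop_nb("unknown stage(s): %s", paste(bad, collapse = ", "))
  bad <- setdiff(unique(sheet$sex), nb_sexes)
  if (length(bad)) stop_nb("unknown sex value(s): %s", paste(bad, collapse = ", "))
  emb <- sheet$state == "embryo"
  if (any(emb & is.na(sheet$stage)))
    stop_nb("embryo sample(s) without stage: %s",
            paste(sheet$sample_id[emb & is.na(sheet$stage)], collapse = ", "))
  if (any(!emb & !is.na(sheet$stage)))
    stop_nb("non-embryo sample(s) with a stage: %s",
            paste(sheet$sample_id[!emb & !is.na(sheet$stage)], collapse = ", "))
  if (any(sheet$replicate < 1)) stop_nb("replicate must be >= 1")
  as.data.frame(sheet)
}

#' Read a sample sheet (CSV)
#' @param path CSV file with sample_id,state,stage,sex,replicate
#' @return validated data.frame
#' @export
read_sample_sheet <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  for (nm in intersect(c("sample_id", "state", "stage", "sex"), names(df)))
    df[[nm]] <- as.character(df[[nm]])
  validate_sample_sheet(df)
}

#' Write a sample sheet (CSV)
#' @param sheet data.frame
#' @param path output CSV
#' @export
write_sample_sheet <- function(sheet, path) {
  data.table::fwrite(validate_sample_sheet(sheet), path)
  invisible(path)
}

#' Read a feature x sample count matrix (TSV)
#'
#' TSV with a header row of sample ids and a first column of feature ids.
#' All cells must be non-negative integers. If a sample sheet is supplied the
#' matrix columns must match its samples exactly and are reordered to sheet
#' order.
#'
#' @param path TSV file
#' @param sheet optional sample sheet to check/order against
#' @return integer matrix with feature rownames and sample colnames
#' @export
read_count_matrix <- function(path, sheet = NULL) {
  if (file.size(path) == 0L) stop_nb("no header: %s is empty", path)
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  if (ncol(dt) < 2L) stop_nb("count matrix %s needs a feature column plus >=1 sample", path)
  fid <- as.character(dt[[1L]])
  if (anyDuplicated(fid))
    stop_nb("duplicate feature_id(s): %s",
            paste(unique(fid[duplicated(fid)]), collapse = ", "))
  m <- as.matrix(dt[, -1L])
  storage <- suppressWarnings(as.numeric(m))
  bad <- which(is.na(storage) | storage < 0 | storage != floor(storage))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(m)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(m)) + 1L
    stop_nb("non-integer count '%s' at feature %s, sample %s",
            m[i, j], fid[i], colnames(m)[j])
  }
  counts <- matrix(as.integer(storage), nrow = nrow(m),
                   dimnames = list(fid, colnames(m)))
  if (!is.null(sheet)) {
    sheet <- validate_sample_sheet(sheet)
    extra <- setdiff(colnames(counts), sheet$sample_id)
    missing <- setdiff(sheet$sample_id, colnames(counts))
    if (length(extra) || length(missing))
      stop_nb("sample mismatch vs sheet: missing [%s], extra [%s]",
              paste(missing, collapse = ", "), paste(extra, collapse = ", "))
    counts <- counts[, sheet$sample_id, drop = FALSE]
  }
  counts
}

#' Write a count matrix (TSV)
#' @param counts integer matrix, feature rownames, sample colnames
#' @param path output TSV
#' @export
write_count_matrix <- function(counts, path) {
  dt <- data.table::data.table(feature_id = rownames(counts))
  for (j in colnames(counts)) dt[[j]] <- counts[, j]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a BED file into a GRanges
#'
#' BED is 0-based half-open; the returned GRanges is 1-based closed with
#' mcols `name`, `score` where present.
#'
#' @param path BED3-6 file
#' @return GRanges
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  data.table::setnames(dt, cols[seq_len(ncol(dt))])
  gr <- GenomicRanges::GRanges(
    seqnames = dt$chrom,
    ranges = IRanges::IRanges(start = dt$start + 1L, end = dt$end),
    strand = if ("strand" %in% names(dt)) dt$strand else "*")
  if ("name" %in% names(dt)) gr$name <- dt$name
  if ("score" %in% names(dt)) gr$score <- dt$score
  gr
}

#' Write a GRanges as BED
#' @param gr GRanges (mcols name/score used when present)
#' @param path output BED
#' @export
write_bed <- function(gr, path) {
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else ".",
    score = if (!is.null(gr$score)) gr$score else 0L,
    strand = as.character(GenomicRanges::strand(gr)))
  dt$strand[dt$strand == "*"] <- "."
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read per-cytosine methylation calls (allc-style TSV)
#'
#' Columns: chrom, pos (1-based), strand, context (CpG/CH), meth_reads,
#' total_reads. Strands are kept separate (no CpG dyad merging).
#'
#' @param path TSV file
#' @return data.table of calls
#' @export
read_allc <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  need <- c("chrom", "pos", "strand", "context", "meth_reads", "total_reads")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop_nb("allc table missing column(s): %s",
                            paste(miss, collapse = ", "))
  if (any(dt$meth_reads > dt$total_reads))
    stop_nb("meth_reads > total_reads at %d site(s)",
            sum(dt$meth_reads > dt$total_reads))
  if (anyDuplicated(dt[, c("chrom", "pos", "strand")]))
    stop_nb("duplicate (chrom,pos,strand) records")
  dt
}

#' Write methylation calls (allc-style TSV)
#' @param calls data.table/data.frame of calls
#' @param path output TSV
#' @export
write_allc <- function(calls, path) {
  data.table::fwrite(calls, path, sep = "\t")
  invisible(path)
}

#' Read a binned coverage track (bedGraph-style TSV)
#'
#' Columns chrom, start, end, count over a fixed-width bin grid.
#'
#' @param path TSV file (no header)
#' @return list with `bins` (data.table), `bin_width`, `total_reads`
#' @export
read_bedgraph <- function(path) {
  dt <- data.table::fread(path, header = FALSE,
                          col.names = c("chrom", "start", "end", "count"))
  coverage_track(dt)
}

#' Build a coverage track from a bin table
#' @param bins data.frame with chrom, start (0-based), end, count
#' @return list with `bins`, `bin_width`, `total_reads`
#' @export
coverage_track <- function(bins) {
  bins <- data.table::as.data.table(bins)
  w <- unique(bins$end - bins$start)
  if (length(w) != 1L) stop_nb("coverage track bins are not fixed width")
  if (any(bins$count < 0)) stop_nb("negative bin counts")
  list(bins = bins, bin_width = as.integer(w),
       total_reads = sum(as.numeric(bins$count)))
}

#' Write a coverage track (bedGraph-style TSV)
#' @param track as returned by [coverage_track()]
#' @param path output TSV
#' @export
write_bedgraph <- function(track, path) {
  data.table::fwrite(track$bins, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
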