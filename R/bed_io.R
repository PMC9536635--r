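#' Read a BED6 file of stranded reads or regions
#'
#' Coordinates stay 0-based half-open. Missing name/score columns are filled.
#'
#' @param path BED file path (plain text, tab-separated).
#' @return data.table with columns chrom, start, end, name, score, strand.
#' @export
read_bed6 <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (ncol(dt) < 3L) stop("BED input needs at least 3 columns: ", path)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  data.table::setnames(dt, seq_len(min(ncol(dt), 6L)), cols[seq_len(min(ncol(dt), 6L))])
  if (!"name" %in% names(dt)) dt[, "name" := "."]
  if (!"score" %in% names(dt)) dt[, "score" := 0]
  if (!"strand" %in% names(dt)) dt[, "strand" := "+"]
  dt <- dt[, cols, with = FALSE]
  dt[, `:=`(chrom = as.character(chrom), start = as.integer(start),
            end = as.integer(end), strand = as.character(strand))]
  if (any(dt$start < 0L) || any(dt$end <= dt$start))
    stop("invalid BED intervals (need 0 <= start < end): ", path)
  dt[]
}

#' Write a BED6 file
#'
#' @param dt data.table with chrom/start/end and optionally name/score/strand.
#' @param path Output path.
#' @param header Optional character vector of `#`-prefixed header lines.
#' @export
write_bed6 <- function(dt, path, header = NULL) {
  out <- data.table::data.table(
    chrom = dt$chrom, start = dt$start, end = dt$end,
    name = if ("name" %in% names(dt)) dt$name else ".",
    score = if ("score" %in% names(dt)) dt$score else 0,
    strand = if ("strand" %in% names(dt)) dt$strand else "+")
  if (!is.null(header)) writeLines(header, path)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE,
                     append = !is.null(header))
  invisible(path)
}

#' Read a two-column chromosome-sizes TSV
#' @param path File path.
#' @return Named integer vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  stats::setNames(as.integer(dt[[2L]]), as.character(dt[[1L]]))
}

#' Write a per-bin track as bedGraph
#'
#' @param track data.table with chrom, start, end and a value column.
#' @param path Output path.
#' @param value Name of the value column (default `"value"`).
#' @export
write_bedgraph <- function(track, path, value = "value") {
  dt <- track[is.finite(track[[value]]),
              c("chrom", "start", "end", value), with = FALSE]
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# Internal: reads data.table -> GRanges (1-based closed, for overlap machinery)
.reads_to_granges <- function(reads) {
  GenomicRanges::GRanges(
    seqnames = reads$chrom,
    ranges = IRanges::IRanges(start = reads$start + 1L, end = reads$end),
    strand = reads$strand)
}
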