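#' Localize putative UV damage sites from Damage-seq reads
#'
#' During Damage-seq the polymerase stops immediately before the adduct, so
#' the lesion dinucleotide sits two nucleotides upstream of the read's 5'
#' end (read orientation). Each read is converted to a 10-base window that
#' carries the lesion dinucleotide at read-orientation positions 5-6:
#' for a plus-strand read `[s, e)` the window is `[s-6, s+4)` with the
#' lesion at `[s-2, s)`; for a minus-strand read `[s, e)` the window is
#' `[e-4, e+6)` with the lesion at `[e, e+2)`, and the site dinucleotide is
#' reported reverse-complemented (read orientation). Windows falling outside
#' the chromosome are dropped and tallied.
#'
#' @param reads data.table of aligned Damage-seq reads (chrom, start, end,
#'   strand; 0-based half-open).
#' @param genome A `"genome"` object used to fetch site dinucleotides.
#' @return data.table of damage records: chrom, start, end (the 10-base
#'   window), strand, site (read-orientation lesion dinucleotide), with
#'   attribute `n_dropped` for out-of-bounds windows.
#' @export
locate_damage_sites <- function(reads, genome) {
  dt <- data.table::as.data.table(reads)
  plus <- dt$strand == "+"
  ws <- ifelse(plus, dt$start - 6L, dt$end - 4L)
  we <- ws + 10L
  lens <- genome$lengths[match(dt$chrom, names(genome$lengths))]
  keep <- !is.na(lens) & ws >= 0L & we <= lens
  out <- data.table::data.table(chrom = dt$chrom[keep],
                                start = as.integer(ws[keep]),
                                end = as.integer(we[keep]),
                                strand = dt$strand[keep])
  # positions 5-6 of the 10-mer in read orientation: genomic [start+4, start+6)
  # on plus, [end-6, end-4) on minus (then reverse-complemented)
  if (nrow(out)) {
    p <- out$strand == "+"
    ds <- ifelse(p, out$start + 4L, out$end - 6L)
    site_dt <- data.table::data.table(chrom = out$chrom, start = as.integer(ds),
                                      end = as.integer(ds + 2L),
                                      strand = out$strand)
    out[, "site" := read_sequences(genome, site_dt)]
  } else out[, "site" := character(0)]
  data.table::setattr(out, "n_dropped", sum(!keep))
  out[]
}

#' Keep only damage records with a dipyrimidine at the damage site
#'
#' The UV photoproducts form at adjacent pyrimidines; records whose site
#' dinucleotide is not one of TT, TC, CT, CC cannot carry a lesion and are
#' removed.
#'
#' @param records Output of [locate_damage_sites()].
#' @return Filtered data.table.
#' @export
filter_dipyrimidine <- function(records) {
  records[records$site %in% c("TT", "TC", "CT", "CC")]
}

#' Collapse duplicate reads sharing identical positions
#'
#' Reads with the same (chrom, start, end, strand) are reduced to a single
#' read; output is sorted by chrom, start, end. The strand is part of the
#' key because all downstream analyses are strand-resolved.
#'
#' @param reads data.table with chrom, start, end, strand.
#' @return Deduplicated, sorted data.table.
#' @export
deduplicate_by_position <- function(reads) {
  dt <- unique(data.table::as.data.table(reads),
               by = c("chrom", "start", "end", "strand"))
  data.table::setorder(dt, chrom, start, end)
  dt[]
}

#' Restrict reads to an allow-list of chromosomes
#'
#' Defaults to the common chromosomes (autosomes 1-22 plus X) with and
#' without the `chr` prefix.
#'
#' @param reads data.table with a chrom column.
#' @param allowed Character vector of allowed chromosome names, or a
#'   `"genome"` object (all of its chromosomes allowed).
#' @return Filtered data.table.
#' @export
filter_common_chromosomes <- function(reads,
                                      allowed = common_chromosomes()) {
  if (inherits(allowed, "genome")) allowed <- names(allowed$lengths)
  if (length(allowed) == 0L) stop("empty chromosome allow-list")
  reads[reads$chrom %in% allowed]
}

#' Default common-chromosome allow-list (1-22 + X)
#' @return Character vector (both `chrN` and bare `N` spellings).
#' @export
common_chromosomes <- function() {
  base <- c(as.character(1:22), "X")
  c(paste0("chr", base), base)
}

#' Read-length histogram and median of excision products
#'
#' @param reads data.table with start, end.
#' @return list with `histogram` (data.table length/count) and `median`
#'   (lower of the two middle values for even n).
#' @export
read_length_histogram <- function(reads) {
  len <- reads$end - reads$start
  if (length(len) == 0L) stop("no reads: median length undefined")
  tab <- data.table::as.data.table(table(length = len))
  tab[, "length" := as.integer(length)]
  data.table::setnames(tab, "N", "count")
  sl <- sort(len)
  med <- sl[[ceiling(length(sl) / 2)]]  # lower middle for even n
  list(histogram = tab[], median = med)
}

#' Positional dinucleotide frequency profile of excision reads
#'
#' For reads of exactly `read_length` bases, reports the frequency of each
#' of the 16 dinucleotides starting at every read-orientation position
#' 1..read_length-1. XR-seq excision products carry the lesion dinucleotide
#' 5-6 nucleotides from their 3' end, which shows up as a TT/TC enrichment
#' peak at that position.
#'
#' @param reads data.table with chrom, start, end, strand.
#' @param genome A `"genome"` object.
#' @param read_length Read length to profile (default 26).
#' @return Numeric matrix (read_length-1) x 16; rows sum to 1.
#' @export
positional_dinucleotide_profile <- function(reads, genome, read_length = 26L) {
  sel <- reads[(reads$end - reads$start) == read_length]
  if (nrow(sel) == 0L) stop("no reads of length ", read_length)
  seqs <- read_sequences(genome, sel)
  dinucs <- sort(as.character(Biostrings::mkAllStrings(c("A", "C", "G", "T"), 2L)))
  m <- matrix(0, nrow = read_length - 1L, ncol = 16L,
              dimnames = list(seq_len(read_length - 1L), dinucs))
  chm <- do.call(rbind, strsplit(seqs, ""))
  for (p in seq_len(read_length - 1L)) {
    di <- paste0(chm[, p], chm[, p + 1L])
    tab <- table(factor(di, levels = dinucs))
    m[p, ] <- as.numeric(tab) / length(di)
  }
  m
}
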