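#' Genome container
#'
#' A lightweight genome object holding chromosome sequences and lengths.
#' All package-internal coordinates are 0-based half-open (BED convention);
#' conversion to the 1-based conventions of Bioconductor containers happens
#' inside accessors, never at call sites.
#'
#' @param seqs A named [Biostrings::DNAStringSet], one entry per chromosome.
#' @return An object of class `"genome"` with elements `seqs` (DNAStringSet)
#'   and `lengths` (named integer vector of chromosome lengths).
#' @export
genome <- function(seqs) {
  if (!methods::is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("chromosome sequences must have unique names")
  lens <- Biostrings::width(seqs)
  if (any(lens <= 0L)) stop("chromosome lengths must be positive")
  structure(list(seqs = seqs, lengths = stats::setNames(lens, names(seqs))),
            class = "genome")
}

#' Read a genome from a FASTA file
#'
#' @param path FASTA file path.
#' @return A `"genome"` object.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  # FASTA headers may carry descriptions after the identifier
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  genome(seqs)
}

#' Write a genome to FASTA (plus a chromosome-sizes TSV)
#'
#' @param g A `"genome"` object.
#' @param fasta_path Output FASTA path.
#' @param sizes_path Optional path for a two-column chrom/length TSV.
#' @export
write_genome_fasta <- function(g, fasta_path, sizes_path = NULL) {
  Biostrings::writeXStringSet(g$seqs, fasta_path)
  if (!is.null(sizes_path)) {
    data.table::fwrite(data.table::data.table(chrom = names(g$lengths),
                                              length = unname(g$lengths)),
                       sizes_path, sep = "\t", col.names = FALSE)
  }
  invisible(fasta_path)
}

#' Extract genomic sequence
#'
#' Returns the uppercase nucleotide string for `[start, end)` on `chrom`;
#' minus-strand requests are reverse-complemented (read orientation).
#' Requests outside `[0, chromosome length)` are errors.
#'
#' @param g A `"genome"` object.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open coordinates.
#' @param strand `"+"` or `"-"`.
#' @return A character scalar over `{A,C,G,T,N}`.
#' @export
genome_seq <- function(g, chrom, start, end, strand = "+") {
  stopifnot(inherits(g, "genome"))
  if (!chrom %in% names(g$lengths)) stop("unknown chromosome: ", chrom)
  if (start < 0 || end > g$lengths[[chrom]] || start >= end)
    stop("sequence request outside [0, length): ", chrom, ":", start, "-", end)
  s <- Biostrings::subseq(g$seqs[[chrom]], start + 1L, end)
  if (identical(strand, "-")) s <- Biostrings::reverseComplement(s)
  toupper(as.character(s))
}

#' Vectorised sequence extraction for reads
#'
#' @param g A `"genome"` object.
#' @param reads A data.table with columns chrom, start, end, strand
#'   (0-based half-open).
#' @return Character vector of read-orientation sequences (uppercase).
#' @export
read_sequences <- function(g, reads) {
  stopifnot(inherits(g, "genome"))
  n <- nrow(reads)
  out <- character(n)
  for (chr in unique(reads$chrom)) {
    idx <- which(reads$chrom == chr)
    ir <- IRanges::IRanges(reads$start[idx] + 1L, reads$end[idx])
    ss <- Biostrings::extractAt(g$seqs[[chr]], ir)
    neg <- reads$strand[idx] == "-"
    if (any(neg)) ss[neg] <- Biostrings::reverseComplement(ss[neg])
    out[idx] <- toupper(as.character(ss))
  }
  out
}

#' @export
print.genome <- function(x, ...) {
  cat("genome:", length(x$lengths), "chromosome(s),",
      sum(as.numeric(x$lengths)), "bp total\n")
  invisible(x)
}
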