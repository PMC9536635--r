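#' Read a minimal single-base-substitution catalog
#'
#' Tab-separated columns chrom, position (1-based), ref, alt, sample (as
#' exported from ICGC simple somatic mutation files). Positions are
#' converted to 0-based internally. Non-single-base records are dropped.
#'
#' @param path TSV path (a header line is auto-detected).
#' @return data.table: chrom, pos (0-based), ref, alt, sample.
#' @export
read_mutation_tsv <- function(path) {
  dt <- data.table::fread(path, header = "auto", sep = "\t")
  data.table::setnames(dt, seq_len(5L),
                       c("chrom", "position", "ref", "alt", "sample"))
  dt <- dt[nchar(ref) == 1L & nchar(alt) == 1L & ref != alt]
  dt[, .(chrom = as.character(chrom), pos = as.integer(position) - 1L,
         ref = toupper(ref), alt = toupper(alt),
         sample = as.character(sample))]
}

#' Classify UV-signature mutations and assign strands
#'
#' UV photoproducts convert the 3' C of a TC dinucleotide (TC>TT) or of a
#' CC dinucleotide (CC>CT) to T. Catalogs report mutations on the forward
#' strand, so: a C>T at position p with forward-strand T at p-1 is TC>TT on
#' the plus strand; with C at p-1 it is CC>CT on the plus strand. The
#' reverse-strand events appear as G>A: with forward A at p+1 (reverse
#' reads TC) it is TC>TT on the minus strand; with G at p+1 it is CC>CT on
#' the minus strand. Everything else is class `"other"` with strand
#' `"unassigned"`, as are mutations whose context runs off a chromosome
#' end.
#'
#' @param mutations data.table chrom, pos (0-based), ref, alt.
#' @param genome A `"genome"` object.
#' @return Input with added columns `class` (`"TC>TT"`, `"CC>CT"`,
#'   `"other"`) and `strand` (`"+"`, `"-"`, `"unassigned"`).
#' @export
classify_uv_mutations <- function(mutations, genome) {
  dt <- data.table::as.data.table(mutations)
  dt[, `:=`(class = "other", strand = "unassigned")]
  lens <- genome$lengths[match(dt$chrom, names(genome$lengths))]
  ct <- which(dt$ref == "C" & dt$alt == "T" & !is.na(lens) & dt$pos >= 1L)
  if (length(ct)) {
    prev <- read_sequences(genome, data.table::data.table(
      chrom = dt$chrom[ct], start = dt$pos[ct] - 1L, end = dt$pos[ct],
      strand = "+"))
    dt[ct[prev == "T"], `:=`(class = "TC>TT", strand = "+")]
    dt[ct[prev == "C"], `:=`(class = "CC>CT", strand = "+")]
  }
  ga <- which(dt$ref == "G" & dt$alt == "A" & !is.na(lens) &
                dt$pos + 2L <= lens)
  if (length(ga)) {
    nxt <- read_sequences(genome, data.table::data.table(
      chrom = dt$chrom[ga], start = dt$pos[ga] + 1L, end = dt$pos[ga] + 2L,
      strand = "+"))
    dt[ga[nxt == "A"], `:=`(class = "TC>TT", strand = "-")]
    dt[ga[nxt == "G"], `:=`(class = "CC>CT", strand = "-")]
  }
  dt[]
}

#' Normalized UV-signature mutation counts around initiation zones
#'
#' Per window and strand, `MC = (# TC>TT + CC>CT mutations on the strand) /
#' (# TC + CC dinucleotide contexts on the strand)`. Contexts on the minus
#' strand are forward-strand GA + GG occurrences (overlapping counts). With
#' `genes` supplied, mutations falling inside gene intervals are removed
#' first (intergenic mode). With `collapse_recurrent = TRUE` a site mutated
#' in several samples counts once.
#'
#' @param mutations Classified mutations (from [classify_uv_mutations()]).
#' @param grid A `"window_grid"` centered on initiation zones.
#' @param genome A `"genome"` object.
#' @param genes Optional gene data.table for intergenic filtering.
#' @param collapse_recurrent Count recurrent sites once (default FALSE:
#'   each sample occurrence counts).
#' @return data.table: region_id, window, strand, n_mut, n_context, mc
#'   (NA where a window has no TC+CC context).
#' @export
normalized_mutation_counts <- function(mutations, grid, genome, genes = NULL,
                                       collapse_recurrent = FALSE) {
  mut <- data.table::as.data.table(mutations)[
    class %in% c("TC>TT", "CC>CT") & strand %in% c("+", "-")]
  if (!is.null(genes) && nrow(mut)) {
    mgr <- GenomicRanges::GRanges(mut$chrom,
             IRanges::IRanges(mut$pos + 1L, mut$pos + 1L))
    ggr <- GenomicRanges::GRanges(genes$chrom,
             IRanges::IRanges(genes$start + 1L, genes$end))
    mut <- mut[GenomicRanges::countOverlaps(mgr, ggr, ignore.strand = TRUE) == 0L]
  }
  if (collapse_recurrent)
    mut <- unique(mut, by = c("chrom", "pos", "ref", "alt"))
  reads <- mut[, .(chrom, start = pos, end = pos + 1L, strand)]
  sm <- count_reads_in_windows(reads, grid)
  win <- grid$windows
  seqs <- read_sequences(genome, win[, .(chrom, start, end, strand = "+")])
  of <- Biostrings::oligonucleotideFrequency(Biostrings::DNAStringSet(seqs), 2L)
  ctx_plus <- of[, "TC"] + of[, "CC"]
  ctx_minus <- of[, "GA"] + of[, "GG"]
  ridx <- match(win$region_id, grid$regions$region_id)
  long <- data.table::rbindlist(list(
    data.table::data.table(region_id = win$region_id, window = win$window,
                           strand = "+",
                           n_mut = sm$counts[cbind(ridx, win$window, 1L)],
                           n_context = as.integer(ctx_plus)),
    data.table::data.table(region_id = win$region_id, window = win$window,
                           strand = "-",
                           n_mut = sm$counts[cbind(ridx, win$window, 2L)],
                           n_context = as.integer(ctx_minus))))
  long[, "mc" := ifelse(n_context > 0L, n_mut / n_context, NA_real_)]
  long[]
}

#' Absolute mutation strand difference by zone quartile and domain
#'
#' For initiation zones carrying quartile and domain labels, aggregates
#' UV-signature mutation counts over flanking windows (>= `min_flank` from
#' the center), separately for the left- and right-replicating sides (the
#' lagging strand switches at the center, so a whole-zone difference would
#' cancel), and reports per quartile and domain the summed per-side
#' absolute plus-minus difference alongside the raw counts.
#'
#' @param mc Long table from [normalized_mutation_counts()].
#' @param grid The `"window_grid"` the table was computed on.
#' @param quartiles Integer vector of per-region quartile labels (aligned
#'   with `grid$regions`).
#' @param domains Character vector of per-region domain labels.
#' @param min_flank Minimum distance from zone center (default 2000).
#' @return data.table: domain, quartile, plus_count, minus_count, abs_diff,
#'   n_zones.
#' @export
quartile_strand_difference <- function(mc, grid, quartiles, domains,
                                       min_flank = 2000L) {
  reg <- grid$regions
  dt <- data.table::as.data.table(mc)
  dt[, "center" := reg$center[match(region_id, reg$region_id)]]
  win <- grid$windows
  key <- paste(win$region_id, win$window)
  dt[, `:=`(wstart = win$start[match(paste(region_id, window), key)],
            wend = win$end[match(paste(region_id, window), key)])]
  far <- ifelse(dt$wstart >= dt$center, dt$wstart - dt$center,
                ifelse(dt$wend <= dt$center, dt$center - dt$wend, -1))
  dt <- dt[far >= min_flank]
  dt[, `:=`(quartile = quartiles[match(region_id, reg$region_id)],
            domain = domains[match(region_id, reg$region_id)])]
  dt <- dt[!is.na(quartile) & !is.na(domain)]
  dt[, "side" := ifelse(wstart >= center, "right", "left")]
  per_side <- dt[, .(plus = sum(n_mut[strand == "+"]),
                     minus = sum(n_mut[strand == "-"])),
                 by = .(domain, quartile, side)]
  out <- per_side[, .(plus_count = sum(plus), minus_count = sum(minus),
                      abs_diff = sum(abs(plus - minus))),
                  by = .(domain, quartile)]
  nz <- dt[, .(n_zones = data.table::uniqueN(region_id)),
           by = .(domain, quartile)]
  out <- merge(out, nz, by = c("domain", "quartile"))
  data.table::setorder(out, domain, quartile)
  out[]
}
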