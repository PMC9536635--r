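#' Binned early/late replication-timing track
#'
#' Tiles each chromosome into `bin_size` bins (default 50 kb; last bin
#' truncated), counts early- and late-phase reads per bin by read midpoint,
#' depth-normalizes each library to reads-per-bin-per-million, and reports
#' `log2((early + pseudocount) / (late + pseudocount))`.
#'
#' @param early_reads,late_reads data.tables with chrom, start, end.
#' @param genome A `"genome"` object or named chromosome-length vector.
#' @param bin_size Bin width in bases (default 50000).
#' @param pseudocount Added to both normalized counts (default 1).
#' @return A `"timing_track"` data.table: chrom, start, end, early, late
#'   (normalized), ratio (log2).
#' @export
compute_timing_track <- function(early_reads, late_reads, genome,
                                 bin_size = 50000L, pseudocount = 1) {
  if (nrow(early_reads) == 0L || nrow(late_reads) == 0L)
    stop("both phases need reads")
  lens <- if (inherits(genome, "genome")) genome$lengths else genome
  bins <- .tile_bins(lens, bin_size)
  e <- .count_midpoints(early_reads, bins, bin_size)
  l <- .count_midpoints(late_reads, bins, bin_size)
  en <- e / nrow(early_reads) * 1e6
  ln <- l / nrow(late_reads) * 1e6
  bins[, `:=`(early = en, late = ln,
              ratio = log2((en + pseudocount) / (ln + pseudocount)))]
  data.table::setattr(bins, "class",
                      c("timing_track", class(data.table::data.table())))
  bins[]
}

.tile_bins <- function(lens, bin_size) {
  data.table::rbindlist(lapply(names(lens), function(chr) {
    st <- seq(0L, lens[[chr]] - 1L, by = bin_size)
    data.table::data.table(chrom = chr, start = as.integer(st),
                           end = as.integer(pmin(st + bin_size, lens[[chr]])))
  }))
}

# midpoint-in-bin counting: each read contributes to exactly one bin
.count_midpoints <- function(reads, bins, bin_size) {
  cnt <- numeric(nrow(bins))
  mid <- (reads$start + reads$end) %/% 2L
  for (chr in unique(bins$chrom)) {
    bidx <- which(bins$chrom == chr)
    ridx <- which(reads$chrom == chr)
    if (!length(ridx)) next
    b <- pmin(mid[ridx] %/% bin_size + 1L, length(bidx))
    tab <- tabulate(b, nbins = length(bidx))
    cnt[bidx] <- tab
  }
  cnt
}

#' Call early/late replication domains (ERD/LRD) from a timing track
#'
#' The smoothed log2 early/late ratio is thresholded at 0 (positive = ERD,
#' negative = LRD), same-label runs separated by at most `merge_gap_bins`
#' bins are merged, and runs shorter than `min_bins` are discarded.
#'
#' @param track A `"timing_track"`.
#' @param smooth_bins Moving-average window (default 10).
#' @param min_bins Minimum domain length in bins (default 4, i.e. 200 kb at
#'   50-kb bins).
#' @param merge_gap_bins Maximum gap (bins) bridged between same-label runs
#'   (default 1).
#' @return data.table of domains: chrom, start, end, label (ERD/LRD),
#'   mean_ratio (mean smoothed ratio), n_bins.
#' @export
call_domains <- function(track, smooth_bins = 10L, min_bins = 4L,
                         merge_gap_bins = 1L) {
  out <- list()
  for (chr in unique(track$chrom)) {
    tt <- track[track$chrom == chr]
    sm <- moving_average(tt$ratio, smooth_bins)
    lab <- ifelse(is.na(sm) | sm == 0, NA_character_,
                  ifelse(sm > 0, "ERD", "LRD"))
    runs <- data.table::rleid(lab)
    seg <- data.table::data.table(lab = lab, run = runs, idx = seq_along(lab))[
      , .(label = lab[1L], from = min(idx), to = max(idx)), by = run][
        !is.na(label)]
    # bridge short gaps between same-label neighbours
    if (nrow(seg) > 1L) {
      merged <- seg[1L]
      for (i in 2L:nrow(seg)) {
        last <- nrow(merged)
        if (seg$label[i] == merged$label[last] &&
            seg$from[i] - merged$to[last] - 1L <= merge_gap_bins) {
          merged$to[last] <- seg$to[i]
        } else merged <- rbind(merged, seg[i])
      }
      seg <- merged
    }
    seg <- seg[(seg$to - seg$from + 1L) >= min_bins]
    if (nrow(seg)) {
      out[[chr]] <- data.table::data.table(
        chrom = chr,
        start = tt$start[seg$from], end = tt$end[seg$to],
        label = seg$label,
        mean_ratio = vapply(seq_len(nrow(seg)), function(i)
          mean(sm[seg$from[i]:seg$to[i]], na.rm = TRUE), numeric(1)),
        n_bins = seg$to - seg$from + 1L)
    }
  }
  if (!length(out))
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), label = character(),
                                  mean_ratio = numeric(), n_bins = integer()))
  data.table::rbindlist(out)
}

#' Assign regions to replication domains by overlap fraction
#'
#' A region gets a domain's label iff at least `min_overlap_fraction` of the
#' region's length lies inside that domain; among qualifying domains ties go
#' to the larger overlap, then the leftmost domain.
#'
#' @param regions data.table with chrom, start, end.
#' @param domains data.table with chrom, start, end, label.
#' @param min_overlap_fraction Default 0.5 (bedtools `-F 0.5`).
#' @return `regions` with an added `domain` column (NA when unassigned).
#' @export
assign_to_domains <- function(regions, domains, min_overlap_fraction = 0.5) {
  reg <- data.table::as.data.table(regions)
  reg[, "domain" := NA_character_]
  if (nrow(reg) == 0L || nrow(domains) == 0L) return(reg[])
  rgr <- GenomicRanges::GRanges(reg$chrom,
           IRanges::IRanges(reg$start + 1L, reg$end))
  dgr <- GenomicRanges::GRanges(domains$chrom,
           IRanges::IRanges(domains$start + 1L, domains$end))
  ov <- GenomicRanges::findOverlaps(rgr, dgr, ignore.strand = TRUE)
  if (!length(ov)) return(reg[])
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  inter <- pmin(reg$end[qi], domains$end[si]) -
    pmax(reg$start[qi], domains$start[si])
  frac <- inter / (reg$end[qi] - reg$start[qi])
  dt <- data.table::data.table(qi = qi, si = si, inter = inter, frac = frac,
                               dstart = domains$start[si])[
    frac >= min_overlap_fraction]
  if (nrow(dt)) {
    data.table::setorder(dt, qi, -inter, dstart)
    best <- dt[!duplicated(qi)]
    reg$domain[best$qi] <- domains$label[best$si]
  }
  reg[]
}
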