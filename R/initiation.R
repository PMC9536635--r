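#' Replication fork directionality (RFD) track from Okazaki fragments
#'
#' Okazaki fragments map to the lagging nascent strand, so the per-bin
#' strand ratio `RFD = (C - W) / (C + W)` (Crick = minus-strand reads,
#' Watson = plus-strand reads) measures the proportion of rightward- vs
#' leftward-moving forks; ascending RFD marks replication initiation.
#' Bins with no reads have undefined RFD (NA).
#'
#' @param ok_reads Stranded data.table of Okazaki-fragment reads.
#' @param genome A `"genome"` object or named length vector.
#' @param bin_size Bin width in bases (default 1000).
#' @return data.table: chrom, start, end, watson, crick, rfd.
#' @export
compute_rfd <- function(ok_reads, genome, bin_size = 1000L) {
  lens <- if (inherits(genome, "genome")) genome$lengths else genome
  bins <- .tile_bins(lens, bin_size)
  w <- .count_midpoints(ok_reads[ok_reads$strand == "+"], bins, bin_size)
  c_ <- .count_midpoints(ok_reads[ok_reads$strand == "-"], bins, bin_size)
  tot <- w + c_
  bins[, `:=`(watson = w, crick = c_,
              rfd = ifelse(tot > 0, (c_ - w) / tot, NA_real_))]
  bins[]
}

#' Call replication initiation zones from an RFD track
#'
#' The RFD track is moving-average smoothed, its local extrema are
#' simplified by persistence pruning (adjacent extrema pairs whose
#' amplitude difference is below `prune_delta` - noise wiggles - are
#' removed), and every remaining ascending segment with total rise of at
#' least `min_delta` and genomic extent of at most `max_extent` becomes an
#' initiation zone. The zone center is the midpoint of the ascent and the
#' score is its adjusted slope, rise / extent in kb.
#'
#' @param rfd RFD track from [compute_rfd()].
#' @param min_delta Minimum total RFD rise (default 0.5).
#' @param max_extent Maximum ascent extent in bases (default 150000).
#' @param smooth_bins Moving-average window in bins (default 5).
#' @param prune_delta Amplitude below which an extrema wiggle is treated as
#'   noise (default `min_delta / 2`).
#' @return data.table: chrom, start, end, name, score (rise per kb), strand
#'   (`"."`), center, rise, extent.
#' @export
call_initiation_zones <- function(rfd, min_delta = 0.5, max_extent = 150000L,
                                  smooth_bins = 5L,
                                  prune_delta = min_delta / 2) {
  track <- data.table::as.data.table(rfd)
  out <- list()
  for (chr in unique(track$chrom)) {
    tt <- track[track$chrom == chr]
    if (nrow(tt) < 10L) next
    sm <- moving_average(tt$rfd, smooth_bins)
    keep <- !is.na(sm)
    if (!any(keep)) next
    idx_map <- which(keep)
    v <- sm[keep]
    ext <- .pruned_extrema(v, prune_delta)
    if (length(ext) < 2L) next
    for (j in seq_len(length(ext) - 1L)) {
      e0 <- ext[j]; e1 <- ext[j + 1L]
      if (v[e1] - v[e0] < min_delta) next
      # trim flat shoulders: keep the stretch carrying the middle 80% of rise
      lo <- v[e0] + 0.1 * (v[e1] - v[e0])
      hi <- v[e1] - 0.1 * (v[e1] - v[e0])
      seg <- v[e0:e1]
      t0 <- e0 - 1L + max(which(seg <= lo))
      t1 <- e0 - 1L + min(which(seg >= hi))
      if (t1 <= t0) { t0 <- e0; t1 <- e1 }
      i0 <- idx_map[t0]; i1 <- idx_map[t1]
      rise <- v[e1] - v[e0]
      extent <- tt$end[i1] - tt$start[i0]
      if (extent <= max_extent) {
        # center: mid-rise crossing (averaged from both sides for symmetry)
        midv <- (v[e0] + v[e1]) / 2
        cl <- e0 - 1L + min(which(seg >= midv))
        cr <- e0 - 1L + max(which(seg <= midv))
        ctr <- (tt$start[idx_map[cl]] + tt$end[idx_map[cl]] +
                  tt$start[idx_map[cr]] + tt$end[idx_map[cr]]) / 4
        out[[length(out) + 1L]] <- data.table::data.table(
          chrom = chr, start = tt$start[i0], end = tt$end[i1],
          rise = rise, extent = extent, center_mid = ctr)
      }
    }
  }
  if (!length(out))
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), name = character(),
                                  score = numeric(), strand = character(),
                                  center = numeric(), rise = numeric(),
                                  extent = integer()))
  iz <- data.table::rbindlist(out)
  iz[, `:=`(name = paste0("iz_", seq_len(.N)),
            score = rise / (extent / 1000),
            strand = ".",
            center = center_mid)]
  iz[, "center_mid" := NULL]
  data.table::setcolorder(iz, c("chrom", "start", "end", "name", "score",
                                "strand", "center", "rise", "extent"))
  data.table::setorder(iz, chrom, start)
  iz[]
}

# indices of alternating local extrema (endpoints included) after removing
# adjacent pairs with amplitude difference < prune_delta (persistence)
.pruned_extrema <- function(v, prune_delta) {
  n <- length(v)
  if (n < 2L) return(integer(0))
  d <- diff(v)
  s <- sign(d)
  # carry previous sign through flat stretches
  for (i in seq_along(s)) if (s[i] == 0 && i > 1L) s[i] <- s[i - 1L]
  turns <- which(diff(s) != 0) + 1L
  ext <- unique(c(1L, turns, n))
  repeat {
    if (length(ext) < 3L) break
    amp <- abs(diff(v[ext]))
    j <- which.min(amp)
    if (amp[j] >= prune_delta) break
    if (j == 1L) ext <- ext[-2L]
    else if (j == length(amp)) ext <- ext[-(length(ext) - 1L)]
    else ext <- ext[-c(j, j + 1L)]
  }
  ext
}

#' Split zones (or any scored regions) into score quartiles
#'
#' Quartile 1 holds the lowest scores and 4 the highest; values tied with a
#' quartile boundary go to the lower quartile.
#'
#' @param izs data.table with a `score` column.
#' @return `izs` with an added integer `quartile` column.
#' @export
quartile_by_score <- function(izs) {
  if (nrow(izs) < 4L) stop("need at least 4 zones for quartiles")
  q <- stats::quantile(izs$score, c(0.25, 0.5, 0.75), names = FALSE)
  dt <- data.table::as.data.table(izs)
  dt[, "quartile" := 1L + (score > q[1]) + (score > q[2]) + (score > q[3])]
  dt[]
}

#' Zones shared across samples
#'
#' A zone of the first (reference) set is "common" iff it overlaps (>= 1 bp)
#' at least one zone in every other set. Also reports, per set, the zones
#' overlapping no zone of any other set, and pairwise overlap counts.
#'
#' @param iz_sets Named list (length >= 2) of zone data.tables.
#' @return list with `common` (reference-set zones present everywhere),
#'   `unique` (per-set private zones), `pairwise` (data.table of overlap
#'   counts set_a/set_b/n).
#' @export
common_zones <- function(iz_sets) {
  stopifnot(length(iz_sets) >= 2L)
  if (is.null(names(iz_sets))) names(iz_sets) <- paste0("set", seq_along(iz_sets))
  grs <- lapply(iz_sets, function(z)
    GenomicRanges::GRanges(z$chrom, IRanges::IRanges(z$start + 1L, z$end)))
  nm <- names(iz_sets)
  ref <- grs[[1L]]
  in_all <- rep(TRUE, length(ref))
  for (j in 2L:length(grs))
    in_all <- in_all & GenomicRanges::countOverlaps(ref, grs[[j]]) > 0L
  uniq <- lapply(seq_along(grs), function(i) {
    hit_any <- rep(FALSE, length(grs[[i]]))
    for (j in setdiff(seq_along(grs), i))
      hit_any <- hit_any | GenomicRanges::countOverlaps(grs[[i]], grs[[j]]) > 0L
    iz_sets[[i]][!hit_any]
  })
  names(uniq) <- nm
  pw <- data.table::rbindlist(lapply(seq_along(grs), function(i)
    data.table::rbindlist(lapply(seq_along(grs), function(j)
      if (i < j) data.table::data.table(
        set_a = nm[i], set_b = nm[j],
        n = sum(GenomicRanges::countOverlaps(grs[[i]], grs[[j]]) > 0L))
      else NULL))))
  list(common = iz_sets[[1L]][in_all], unique = uniq, pairwise = pw)
}

#' Leading/lagging template assignment around an initiation-zone center
#'
#' Forks emanate from the zone center: windows to the right are replicated
#' by a rightward-moving fork, for which the plus strand serves as the
#' lagging-strand template and the minus strand as the leading-strand
#' template; windows to the left are mirrored. Windows straddling the
#' center are excluded (NA).
#'
#' @param window_start,window_end Window interval (0-based half-open);
#'   vectorized.
#' @param iz_center Zone center coordinate (vectorized).
#' @return data.table: side (`"left"`/`"right"`/NA), plus_role, minus_role
#'   (`"leading"`/`"lagging"`).
#' @export
assign_fork_polarity <- function(window_start, window_end, iz_center) {
  side <- ifelse(window_end <= iz_center, "left",
                 ifelse(window_start >= iz_center, "right", NA_character_))
  data.table::data.table(
    side = side,
    plus_role = ifelse(is.na(side), NA_character_,
                       ifelse(side == "right", "lagging", "leading")),
    minus_role = ifelse(is.na(side), NA_character_,
                        ifelse(side == "right", "leading", "lagging")))
}
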