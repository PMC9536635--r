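#' Centered window grids around genomic regions
#'
#' Expands each region symmetrically about its integer midpoint to a span of
#' `interval_len * window_num` bases, using truncating integer arithmetic:
#' `span_start = int(mid - a/2 - a*(b-1)/2)` and
#' `span_end = int(mid + a/2 + a*(b-1)/2)` with `mid = (start+end)/2`,
#' `a = interval_len`, `b = window_num`. Spans that cross a chromosome
#' boundary are dropped, and any pair of overlapping expanded spans is
#' dropped mutually (both members), so that opposing signals cannot cancel.
#' Surviving spans are tiled into windows numbered 1..`window_num`
#' left-to-right.
#'
#' @param regions data.table with chrom, start, end (0-based half-open) and
#'   optionally name and strand; row order defines region ids.
#' @param interval_len Window length in bases (>= 1).
#' @param window_num Number of windows per region (>= 1).
#' @param genome A `"genome"` object, or a named integer vector of
#'   chromosome lengths.
#' @return A `"window_grid"` object: `$regions` (one row per surviving
#'   region, with span coordinates and span center), `$windows` (long table
#'   region_id x window), `$window_len`, `$window_num`, `$chrom_lengths`,
#'   and `$n_dropped` (bounds / overlap tallies).
#' @export
make_centered_windows <- function(regions, interval_len, window_num, genome) {
  if (interval_len < 1L || window_num < 1L)
    stop("interval_len and window_num must be >= 1")
  lens <- if (inherits(genome, "genome")) genome$lengths else genome
  reg <- data.table::as.data.table(regions)
  if (!"name" %in% names(reg)) reg[, "name" := paste0("region_", .I)]
  if (!"strand" %in% names(reg)) reg[, "strand" := "."]
  reg[, "region_id" := .I]

  a <- as.numeric(interval_len); b <- as.numeric(window_num)
  mid <- (reg$start + reg$end) / 2
  span_start <- trunc(mid - a / 2 - a * (b - 1) / 2)
  span_end   <- trunc(mid + a / 2 + a * (b - 1) / 2)
  # truncation of the symmetric pair always yields an exact a*b span
  stopifnot(all(span_end - span_start == a * b))
  reg[, `:=`(span_start = as.integer(span_start), span_end = as.integer(span_end))]

  known <- reg$chrom %in% names(lens)
  inb <- known & reg$span_start >= 0L &
    reg$span_end <= unname(lens[match(reg$chrom, names(lens))])
  n_oob <- sum(!inb)
  reg <- reg[inb]

  n_olap <- 0L
  if (nrow(reg) > 1L) {
    gr <- GenomicRanges::GRanges(reg$chrom,
            IRanges::IRanges(reg$span_start + 1L, reg$span_end))
    hits <- GenomicRanges::countOverlaps(gr, gr, ignore.strand = TRUE)
    n_olap <- sum(hits > 1L)
    reg <- reg[hits == 1L]
  }
  if (nrow(reg) == 0L)
    warning("no regions survive windowing filters")

  win <- if (nrow(reg)) reg[, .(window = seq_len(window_num),
            start = span_start + (seq_len(window_num) - 1L) * as.integer(interval_len)),
            by = .(region_id, chrom)] else
    data.table::data.table(region_id = integer(), chrom = character(),
                           window = integer(), start = integer())
  win[, "end" := start + as.integer(interval_len)]

  structure(list(
    regions = reg[, .(region_id, chrom, start, end, name, strand,
                      span_start, span_end,
                      center = (span_start + span_end) / 2)],
    windows = win[, .(region_id, chrom, window, start, end)],
    window_len = as.integer(interval_len),
    window_num = as.integer(window_num),
    chrom_lengths = lens,
    n_dropped = c(out_of_bounds = n_oob, overlapping = n_olap)),
    class = "window_grid")
}

#' @export
print.window_grid <- function(x, ...) {
  cat("window_grid:", nrow(x$regions), "regions x", x$window_num,
      "windows of", x$window_len, "bp (dropped:",
      x$n_dropped[["out_of_bounds"]], "out-of-bounds,",
      x$n_dropped[["overlapping"]], "overlapping)\n")
  invisible(x)
}

#' Strand-aware window counting
#'
#' Counts reads into the grid's windows: a read increments window `w` of
#' region `r` on the read's own strand whenever the read interval overlaps
#' the window interval by at least 1 bp; a read overlapping k windows
#' increments all k (bedtools-intersect semantics).
#'
#' @param reads data.table with chrom, start, end, strand (0-based half-open).
#' @param grid A `"window_grid"`.
#' @param library_size Total mapped reads of the library the reads come from
#'   (defaults to `nrow(reads)`); carried for RPKM normalization.
#' @return A `"signal_matrix"`: `$counts` is a region x window x strand
#'   integer array, `$grid` the grid, `$library_size`, and `$n_skipped`
#'   reads on chromosomes unknown to the grid.
#' @export
count_reads_in_windows <- function(reads, grid, library_size = nrow(reads)) {
  stopifnot(inherits(grid, "window_grid"))
  nr <- nrow(grid$regions); nw <- grid$window_num
  counts <- array(0L, dim = c(nr, nw, 2L),
                  dimnames = list(as.character(grid$regions$region_id),
                                  as.character(seq_len(nw)), c("+", "-")))
  known <- reads$chrom %in% names(grid$chrom_lengths)
  n_skipped <- sum(!known)
  rds <- reads[known & reads$strand %in% c("+", "-")]
  if (nrow(rds) && nr) {
    wgr <- GenomicRanges::GRanges(grid$windows$chrom,
             IRanges::IRanges(grid$windows$start + 1L, grid$windows$end))
    rgr <- GenomicRanges::GRanges(rds$chrom,
             IRanges::IRanges(rds$start + 1L, rds$end))
    ov <- GenomicRanges::findOverlaps(rgr, wgr, ignore.strand = TRUE)
    if (length(ov)) {
      qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
      ridx <- match(grid$windows$region_id[si], grid$regions$region_id)
      widx <- grid$windows$window[si]
      sidx <- ifelse(rds$strand[qi] == "+", 1L, 2L)
      tab <- data.table::data.table(r = ridx, w = widx, s = sidx)[
        , .N, by = .(r, w, s)]
      counts[cbind(tab$r, tab$w, tab$s)] <- tab$N
    }
  }
  structure(list(grid = grid, counts = counts,
                 library_size = as.numeric(library_size),
                 n_skipped = n_skipped),
            class = "signal_matrix")
}

#' RPKM values of a signal matrix
#'
#' `RPKM = count * 1e9 / (window_length * library_size)`.
#'
#' @param sm A `"signal_matrix"`.
#' @return Numeric array, same shape as `sm$counts`.
#' @export
rpkm <- function(sm) {
  stopifnot(inherits(sm, "signal_matrix"))
  if (sm$library_size <= 0) stop("library_size must be positive for RPKM")
  sm$counts * 1e9 / (as.numeric(sm$grid$window_len) * sm$library_size)
}

#' Aggregate a signal matrix into a per-window per-strand meta-profile
#'
#' Windows are aggregated by window number: for each window index and strand
#' the mean over regions is reported. With `normalize = "rpkm"` the RPKM
#' transform is applied per cell before averaging.
#'
#' @param sm A `"signal_matrix"`.
#' @param normalize `"rpkm"` or `"none"`.
#' @return data.table with window, strand, value.
#' @export
aggregate_profile <- function(sm, normalize = c("rpkm", "none")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(sm, "signal_matrix"))
  if (nrow(sm$grid$regions) < 1L) stop("signal matrix has no regions")
  vals <- if (normalize == "rpkm") rpkm(sm) else sm$counts
  m <- apply(vals, c(2L, 3L), mean)
  data.table::data.table(
    window = rep(seq_len(nrow(m)), times = 2L),
    strand = rep(c("+", "-"), each = nrow(m)),
    value = c(m[, "+"], m[, "-"]))
}

#' Centered simple moving average
#'
#' Window of `k` bins centered on each bin (for even `k`, `floor((k-1)/2)`
#' bins to the left and `floor(k/2)` to the right); at track edges the
#' available, shorter window is used. `NA` bins are excluded from each mean.
#'
#' @param x Numeric vector (per-bin track).
#' @param k Window size in bins (default 10).
#' @return Smoothed numeric vector, same length.
#' @export
moving_average <- function(x, k = 10L) {
  if (k < 1L) stop("k must be >= 1")
  n <- length(x)
  if (n == 0L) return(numeric(0))
  if (k == 1L) return(as.numeric(x))
  left <- (k - 1L) %/% 2L; right <- k %/% 2L
  ok <- !is.na(x)
  xs <- ifelse(ok, x, 0)
  cs <- cumsum(xs); cn <- cumsum(as.numeric(ok))
  lo <- pmax(seq_len(n) - left, 1L); hi <- pmin(seq_len(n) + right, n)
  tot <- cs[hi] - c(0, cs)[lo]
  cnt <- cn[hi] - c(0, cn)[lo]
  out <- tot / cnt
  out[cnt == 0] <- NA_real_
  out
}
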