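#' Reverse complement of k-mer strings
#' @param x Character vector over A/C/G/T/N.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Net strand-skew statistics of a k-mer
#'
#' For a sequence over `{A,C,G,T}` of length 1-5: `net_T = #T - #A`,
#' `net_C = #C - #G`, and the dinucleotide versions using overlapping
#' counts: `net_TT = #TT - #AA`, `net_TC = #TC - #GA`, `net_CC = #CC - #GG`.
#' Each statistic is antisymmetric under reverse complementation.
#'
#' @param kmer Character vector of k-mers.
#' @return data.table: kmer, net_T, net_TT, net_TC, net_C, net_CC.
#' @export
net_statistics <- function(kmer) {
  if (any(!grepl("^[ACGT]{1,5}$", kmer)))
    stop("k-mers must be over {A,C,G,T}, length 1-5")
  cnt1 <- function(x, b) vapply(gregexpr(b, x, fixed = TRUE),
                                function(m) sum(m > 0L), integer(1))
  # overlapping dinucleotide count via lookahead-free shift comparison
  cnt2 <- function(x, di) {
    vapply(x, function(s) {
      n <- nchar(s)
      if (n < 2L) return(0L)
      a <- substring(s, 1:(n - 1L), 1:(n - 1L))
      b <- substring(s, 2:n, 2:n)
      sum(a == substr(di, 1, 1) & b == substr(di, 2, 2))
    }, integer(1), USE.NAMES = FALSE)
  }
  data.table::data.table(
    kmer = kmer,
    net_T = cnt1(kmer, "T") - cnt1(kmer, "A"),
    net_TT = cnt2(kmer, "TT") - cnt2(kmer, "AA"),
    net_TC = cnt2(kmer, "TC") - cnt2(kmer, "GA"),
    net_C = cnt1(kmer, "C") - cnt1(kmer, "G"),
    net_CC = cnt2(kmer, "CC") - cnt2(kmer, "GG"))
}

#' Collapsed representative of a reverse-complement k-mer pair
#'
#' The lexicographically smaller of (kmer, revcomp(kmer)); palindromes map
#' to themselves.
#'
#' @param x Character vector of k-mers.
#' @return Character vector of representatives.
#' @export
collapse_pair <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

#' Strand-resolved k-mer percentages around initiation zones
#'
#' Counts overlapping k-mers on the forward (plus) strand of each flanking
#' window (at least `min_flank` bases from the zone center), aggregates by
#' side (left/right of center) and optional domain label, and converts to
#' percentages. The minus-strand percentage of a k-mer equals the
#' plus-strand percentage of its reverse complement, so only forward counts
#' are stored.
#'
#' @param grid A `"window_grid"` centered on initiation zones.
#' @param genome A `"genome"` object.
#' @param k_range Integer vector of k values (default 1:5).
#' @param min_flank Minimum distance from the center in bases (default 2000).
#' @param domains Optional per-region domain labels (character vector
#'   aligned with `grid$regions`).
#' @return A `"kmer_strand_table"` data.table: k, kmer, side, domain,
#'   percent_plus (forward-strand percentage; within each k x side x domain
#'   the percentages sum to 100).
#' @export
kmer_percentages <- function(grid, genome, k_range = 1:5, min_flank = 2000L,
                             domains = NULL) {
  win <- data.table::copy(grid$windows)
  win[, "center" := grid$regions$center[match(region_id, grid$regions$region_id)]]
  win[, "side" := ifelse(end <= center, "left",
                         ifelse(start >= center, "right", NA_character_))]
  far <- ifelse(win$side == "right", win$start - win$center,
                win$center - win$end)
  win <- win[!is.na(side) & far >= min_flank]
  if (is.null(domains)) {
    win[, "domain" := "all"]
  } else {
    win[, "domain" := domains[match(region_id, grid$regions$region_id)]]
    win <- win[!is.na(domain)]
  }
  if (nrow(win) == 0L) stop("no flanking windows beyond min_flank")
  seqs <- read_sequences(genome, win[, .(chrom, start, end, strand = "+")])
  ds <- Biostrings::DNAStringSet(seqs)
  out <- list()
  for (k in k_range) {
    of <- Biostrings::oligonucleotideFrequency(ds, width = k)
    for (grp in split(seq_len(nrow(win)),
                      paste(win$side, win$domain, sep = "\r"))) {
      tot <- colSums(of[grp, , drop = FALSE])
      key <- strsplit(paste(win$side[grp[1]], win$domain[grp[1]], sep = "\r"),
                      "\r")[[1]]
      out[[length(out) + 1L]] <- data.table::data.table(
        k = k, kmer = colnames(of), side = key[1], domain = key[2],
        percent_plus = 100 * tot / sum(tot))
    }
  }
  res <- data.table::rbindlist(out)
  data.table::setattr(res, "class",
                      c("kmer_strand_table", class(data.table::data.table())))
  res[]
}

#' Lagging/leading occurrence ratio versus net skew statistics
#'
#' For every collapsed k-mer (one representative per reverse-complement
#' pair) and each side of the initiation zones, pairs the
#' lagging-over-leading strand occurrence ratio with the k-mer's net
#' statistics. On the right-replicating side the plus strand is the lagging
#' template, so the ratio is `percent_plus(x) / percent_plus(revcomp(x))`;
#' on the left side it is the reciprocal. Per-net-value medians of the
#' ratio are the red-bar summary.
#'
#' @param table A `"kmer_strand_table"` from [kmer_percentages()].
#' @return list: `$points` (kmer, k, side, domain, ratio, net statistics),
#'   `$medians` (per domain x side x net_T the median ratio; analogous
#'   medians for the other net statistics are easily recomputed from
#'   `$points`).
#' @export
skew_vs_ratio <- function(table) {
  dt <- data.table::as.data.table(table)
  dt[, "rep" := collapse_pair(kmer)]
  dt[, "rc" := revcomp(kmer)]
  # forward percentage of the reverse complement within the same group
  dt[, "percent_rc" := percent_plus[match(rc, kmer)], by = .(k, side, domain)]
  pts <- dt[kmer == rep]
  pts <- pts[percent_rc > 0 | percent_plus > 0]
  n_excluded <- 0L
  pts[, "ratio" := ifelse(side == "right",
                          percent_plus / percent_rc,
                          percent_rc / percent_plus)]
  n_excluded <- sum(!is.finite(pts$ratio))
  pts <- pts[is.finite(ratio)]
  ns <- net_statistics(pts$kmer)
  pts <- cbind(pts[, .(k, kmer, side, domain, ratio)],
               ns[, .(net_T, net_TT, net_TC, net_C, net_CC)])
  med <- pts[, .(median_ratio = stats::median(ratio), n = .N),
             by = .(domain, side, net_T)]
  data.table::setorder(med, domain, side, net_T)
  structure(list(points = pts[], medians = med[], n_excluded = n_excluded),
            class = "skew_ratio")
}

#' A+T percentage of regions
#'
#' @param regions data.table with chrom, start, end.
#' @param genome A `"genome"` object.
#' @return Numeric vector of A+T percentages over non-N bases (NA for
#'   all-N regions).
#' @export
at_content <- function(regions, genome) {
  seqs <- read_sequences(genome, data.table::as.data.table(regions)[
    , .(chrom, start, end, strand = "+")])
  af <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(seqs),
                                      baseOnly = TRUE)
  acgt <- rowSums(af[, c("A", "C", "G", "T"), drop = FALSE])
  at <- rowSums(af[, c("A", "T"), drop = FALSE])
  ifelse(acgt > 0, 100 * at / acgt, NA_real_)
}

#' Identify T-rich and A-rich genome slices
#'
#' Slices the genome into `slice_size` windows, computes the forward-strand
#' T% / A% ratio per slice ("relative T": high values mean the forward
#' strand carries the Ts, low values mean the reverse strand does), splits
#' slices into quartiles of relative T, and tags the top quartile T-rich
#' and the bottom quartile A-rich. Slices with zero A (or N-only) are
#' excluded and tallied.
#'
#' @param genome A `"genome"` object.
#' @param slice_size Slice width in bases (default 50000).
#' @return data.table: chrom, start, end, t_pct, a_pct, relative_t,
#'   quartile, class (`"T-rich"`, `"A-rich"` or NA).
#' @export
identify_at_rich <- function(genome, slice_size = 50000L) {
  slices <- .tile_bins(genome$lengths, slice_size)
  seqs <- read_sequences(genome, slices[, .(chrom, start, end, strand = "+")])
  af <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(seqs),
                                      baseOnly = TRUE)
  tot <- rowSums(af[, c("A", "C", "G", "T"), drop = FALSE])
  slices[, `:=`(t_pct = 100 * af[, "T"] / tot, a_pct = 100 * af[, "A"] / tot)]
  n_excluded <- sum(!(slices$a_pct > 0) | !is.finite(slices$a_pct))
  slices <- slices[a_pct > 0]
  slices[, "relative_t" := t_pct / a_pct]
  slices[, "score" := relative_t]
  slices <- quartile_by_score(slices)
  slices[, "score" := NULL]
  slices[, "class" := ifelse(quartile == 4L, "T-rich",
                             ifelse(quartile == 1L, "A-rich", NA_character_))]
  data.table::setattr(slices, "n_excluded", n_excluded)
  slices[]
}
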