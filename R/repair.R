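#' Repair-rate profile: XR-seq over Damage-seq
#'
#' Per window and strand, the ratio of XR-seq RPKM to Damage-seq RPKM.
#' Cells with zero damage counts are undefined (NA), never zero-filled.
#'
#' @param xr,dmg `"signal_matrix"` objects on the same grid.
#' @return A `"repair_profile"`: `$values` (region x window x strand array),
#'   `$grid`, `$kind = "RR"` (ratio scale), `$n_undefined`.
#' @export
repair_rate <- function(xr, dmg) {
  .check_same_grid(xr$grid, dmg$grid)
  vals <- rpkm(xr) / rpkm(dmg)
  vals[dmg$counts == 0L] <- NA_real_
  structure(list(grid = xr$grid, values = vals, kind = "RR",
                 n_undefined = sum(is.na(vals))),
            class = "repair_profile")
}

#' Simulation-normalized repair rate
#'
#' `nRR = log2((XR_real/XR_sim) / (Dmg_real/Dmg_sim))` per cell, on RPKM
#' values. The simulated libraries carry the sequence-context expectation,
#' so nRR removes composition-driven signal from both assays. Cells where
#' any of the four counts is zero are undefined and tallied. nRR is exactly
#' invariant to the sequencing depth of each library because each RPKM
#' normalizes by its own library size.
#'
#' @param xr_real,xr_sim,dmg_real,dmg_sim `"signal_matrix"` objects sharing
#'   one grid.
#' @return A `"repair_profile"` with `$kind = "nRR"` (log2 scale).
#' @export
normalized_repair_rate <- function(xr_real, xr_sim, dmg_real, dmg_sim) {
  .check_same_grid(xr_real$grid, xr_sim$grid)
  .check_same_grid(xr_real$grid, dmg_real$grid)
  .check_same_grid(xr_real$grid, dmg_sim$grid)
  vals <- log2((rpkm(xr_real) / rpkm(xr_sim)) /
                 (rpkm(dmg_real) / rpkm(dmg_sim)))
  undef <- xr_real$counts == 0L | xr_sim$counts == 0L |
    dmg_real$counts == 0L | dmg_sim$counts == 0L
  vals[undef] <- NA_real_
  structure(list(grid = xr_real$grid, values = vals, kind = "nRR",
                 n_undefined = sum(undef)),
            class = "repair_profile")
}

.check_same_grid <- function(g1, g2) {
  if (!identical(g1$windows[, .(region_id, chrom, window, start, end)],
                 g2$windows[, .(region_id, chrom, window, start, end)]))
    stop("signal matrices are not on the same window grid")
}

#' @export
print.repair_profile <- function(x, ...) {
  cat("repair_profile (", x$kind, "): ", nrow(x$grid$regions), " regions x ",
      x$grid$window_num, " windows x 2 strands; ", x$n_undefined,
      " undefined cells\n", sep = "")
  invisible(x)
}

# long-format view of a profile: one row per cell (defined or undefined)
.profile_long <- function(profile) {
  g <- profile$grid
  win <- g$windows
  ridx <- match(win$region_id, g$regions$region_id)
  long <- data.table::rbindlist(list(
    data.table::copy(win)[, `:=`(strand = "+",
      value = profile$values[cbind(ridx, win$window, 1L)])],
    data.table::copy(win)[, `:=`(strand = "-",
      value = profile$values[cbind(ridx, win$window, 2L)])]))
  long[, "center" := g$regions$center[match(region_id, g$regions$region_id)]]
  long[]
}

#' Early-vs-late S phase log2 fold change of repair rates
#'
#' Per region (or aggregated per domain label) the log2 ratio of mean repair
#' rate between phases; for log2-scale profiles (nRR) the difference of
#' means is taken instead.
#'
#' @param rr_early,rr_late `"repair_profile"` objects on matched grids.
#' @param domains Optional character vector of per-region domain labels; if
#'   given, results are aggregated per label.
#' @return data.table with region_id (or domain) and log2fc.
#' @export
early_late_fold_change <- function(rr_early, rr_late, domains = NULL) {
  .check_same_grid(rr_early$grid, rr_late$grid)
  log_scale <- rr_early$kind == "nRR"
  per_region <- function(p) apply(p$values, 1L, mean, na.rm = TRUE)
  if (is.null(domains)) {
    e <- per_region(rr_early); l <- per_region(rr_late)
    fc <- if (log_scale) e - l else log2(e / l)
    data.table::data.table(region_id = rr_early$grid$regions$region_id,
                           log2fc = fc)
  } else {
    stopifnot(length(domains) == nrow(rr_early$grid$regions))
    dt <- data.table::data.table(domain = domains,
                                 e = per_region(rr_early),
                                 l = per_region(rr_late))[!is.na(domain)]
    dt[, .(log2fc = if (log_scale) mean(e, na.rm = TRUE) - mean(l, na.rm = TRUE)
           else log2(mean(e, na.rm = TRUE) / mean(l, na.rm = TRUE))),
       by = domain]
  }
}

#' Accumulated repair between two Damage-seq time points
#'
#' Fraction of initial damage removed by the later time point,
#' `(D_0h - D_2h) / D_0h`, computed on RPKM values per cell. Undefined where
#' the 0 h signal is zero; negative values (apparent gain) are allowed.
#'
#' @param dmg_0h,dmg_2h `"signal_matrix"` objects on one grid.
#' @return A `"repair_profile"` with `$kind = "accumulated"`.
#' @export
accumulated_repair <- function(dmg_0h, dmg_2h) {
  .check_same_grid(dmg_0h$grid, dmg_2h$grid)
  r0 <- rpkm(dmg_0h); r2 <- rpkm(dmg_2h)
  vals <- (r0 - r2) / r0
  vals[dmg_0h$counts == 0L] <- NA_real_
  structure(list(grid = dmg_0h$grid, values = vals, kind = "accumulated",
                 n_undefined = sum(is.na(vals))),
            class = "repair_profile")
}

#' Template/non-template strand repair-rate profiles around TSS and TES
#'
#' Builds centered window grids on transcription start and end sites,
#' computes repair rates, and reports meta-profiles for the template strand
#' (TS; the minus strand of a plus-strand gene) and the non-template strand
#' (NTS), oriented so transcription runs left to right.
#'
#' @param xr_reads,dmg_reads Read data.tables.
#' @param genes Stranded gene data.table (chrom, start, end, strand).
#' @param genome A `"genome"` object.
#' @param interval_len,window_num Grid parameters (defaults 100 x 40 = 4 kb).
#' @return list with `tss` and `tes` data.tables (window, TS, NTS: mean RR
#'   over genes), plus the underlying profiles.
#' @export
tss_tes_profile <- function(xr_reads, dmg_reads, genes, genome,
                            interval_len = 100L, window_num = 40L) {
  stopifnot(all(genes$strand %in% c("+", "-")))
  point <- function(pos, g) data.table::data.table(
    chrom = g$chrom, start = pos, end = pos + 1L, strand = g$strand)
  tss <- point(ifelse(genes$strand == "+", genes$start, genes$end - 1L), genes)
  tes <- point(ifelse(genes$strand == "+", genes$end - 1L, genes$start), genes)
  one <- function(points) {
    grid <- make_centered_windows(points, interval_len, window_num, genome)
    xr <- count_reads_in_windows(xr_reads, grid)
    dmg <- count_reads_in_windows(dmg_reads, grid)
    rr <- repair_rate(xr, dmg)
    src_strand <- grid$regions$strand
    b <- grid$window_num
    # orient: transcription left->right; TS = minus strand for + genes
    ts <- matrix(NA_real_, nrow(grid$regions), b)
    nts <- ts
    pos <- src_strand == "+"
    if (any(pos)) {
      ts[pos, ] <- rr$values[pos, , "-"]
      nts[pos, ] <- rr$values[pos, , "+"]
    }
    if (any(!pos)) {
      ts[!pos, ] <- rr$values[!pos, b:1, "+"]
      nts[!pos, ] <- rr$values[!pos, b:1, "-"]
    }
    list(profile = rr,
         meta = data.table::data.table(
           window = seq_len(b),
           TS = colMeans(ts, na.rm = TRUE),
           NTS = colMeans(nts, na.rm = TRUE)))
  }
  ptss <- one(tss); ptes <- one(tes)
  list(tss = ptss$meta, tes = ptes$meta,
       tss_profile = ptss$profile, tes_profile = ptes$profile)
}

#' Strand asymmetry of a profile around initiation-zone centers
#'
#' Windows at least `min_flank` bases from the zone center are split into
#' left- and right-replicating sides; per side, plus- and minus-strand
#' values of the same window are paired and compared with a paired Wilcoxon
#' signed-rank test. Leading/lagging template roles are attached via
#' [assign_fork_polarity()]. For ratio-scale profiles (RR) values are log2
#' transformed first so that differences are log2 asymmetries.
#'
#' @param profile A `"repair_profile"` on an IZ-centered grid.
#' @param min_flank Minimum distance from the center in bases (default 2000).
#' @return An `"asymmetry_summary"` list: `$per_side` (side, n_pairs, median
#'   plus-minus difference, p value, roles), `$leading_minus_lagging`
#'   (median over all pairs of leading-minus-lagging differences),
#'   `$pairs` (the underlying paired table).
#' @export
strand_asymmetry <- function(profile, min_flank = 2000L) {
  long <- .profile_long(profile)
  if (profile$kind == "RR") long[, "value" := log2(value)]
  long[!is.na(value) & !is.finite(value), "value" := NA_real_]
  pol <- assign_fork_polarity(long$start, long$end, long$center)
  long[, `:=`(side = pol$side, plus_role = pol$plus_role,
              minus_role = pol$minus_role)]
  long <- long[!is.na(side)]
  far <- ifelse(long$side == "right", long$start - long$center,
                long$center - long$end)
  long <- long[far >= min_flank]
  wide <- data.table::dcast(long, region_id + window + side ~ strand,
                            value.var = "value")
  data.table::setnames(wide, c("+", "-"), c("plus", "minus"))
  wide <- wide[is.finite(plus) & is.finite(minus)]
  wide[, "diff" := plus - minus]
  wide[, "leading_minus_lagging" := ifelse(side == "right",
                                           minus - plus, plus - minus)]
  per_side <- wide[, {
    n <- .N
    p <- if (n >= 5L) stats::wilcox.test(plus, minus, paired = TRUE,
                                         exact = FALSE)$p.value else NA_real_
    .(n_pairs = n,
      median_plus_minus = if (n) stats::median(diff) else NA_real_,
      p_value = p,
      plus_role = ifelse(side[1L] == "right", "lagging", "leading"),
      minus_role = ifelse(side[1L] == "right", "leading", "lagging"))
  }, by = side]
  structure(list(
    per_side = per_side[],
    leading_minus_lagging = if (nrow(wide))
      stats::median(wide$leading_minus_lagging) else NA_real_,
    pairs = wide[]),
    class = "asymmetry_summary")
}

#' @export
print.asymmetry_summary <- function(x, ...) {
  cat("asymmetry_summary: median leading - lagging =",
      signif(x$leading_minus_lagging, 4), "\n")
  print(x$per_side)
  invisible(x)
}

#' Repair rates per chromatin state, replication domain and phase
#'
#' State segments are assigned to replication domains (>= 50% overlap), the
#' per-segment mean profile value is computed for each phase, and phases are
#' compared per state x domain with an unpaired Wilcoxon rank-sum test.
#'
#' @param profiles Named list of `"repair_profile"` objects, one per phase
#'   (e.g. `list(early = ..., late = ...)`), on identical grids.
#' @param states data.table chrom, start, end, state.
#' @param domains Domain data.table (chrom, start, end, label).
#' @param min_segments States with fewer segments than this in a domain are
#'   excluded from testing (default 5).
#' @return list: `$segments` (state, domain, segment means per phase),
#'   `$tests` (state, domain, n per phase, p_value).
#' @export
chromatin_state_summary <- function(profiles, states, domains,
                                    min_segments = 5L) {
  stopifnot(length(profiles) >= 1L, !is.null(names(profiles)))
  seg <- assign_to_domains(states, domains)
  seg[, "segment_id" := .I]
  g <- profiles[[1L]]$grid
  wgr <- GenomicRanges::GRanges(g$windows$chrom,
           IRanges::IRanges(g$windows$start + 1L, g$windows$end))
  sgr <- GenomicRanges::GRanges(seg$chrom,
           IRanges::IRanges(seg$start + 1L, seg$end))
  ov <- GenomicRanges::findOverlaps(sgr, wgr, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  ridx <- match(g$windows$region_id[si], g$regions$region_id)
  widx <- g$windows$window[si]
  for (ph in names(profiles)) {
    vals <- profiles[[ph]]$values
    cell_mean <- rowMeans(cbind(vals[cbind(ridx, widx, 1L)],
                                vals[cbind(ridx, widx, 2L)]), na.rm = TRUE)
    agg <- data.table::data.table(segment_id = qi, v = cell_mean)[
      , .(m = mean(v, na.rm = TRUE)), by = segment_id]
    seg[agg$segment_id, (ph) := agg$m]
  }
  phases <- names(profiles)
  tests <- NULL
  if (length(phases) >= 2L) {
    p1 <- phases[1L]; p2 <- phases[2L]
    tests <- seg[!is.na(domain), {
      x <- stats::na.omit(.SD[[p1]]); y <- stats::na.omit(.SD[[p2]])
      if (length(x) >= min_segments && length(y) >= min_segments) {
        .(n_1 = length(x), n_2 = length(y),
          p_value = stats::wilcox.test(x, y, exact = FALSE)$p.value)
      } else .(n_1 = length(x), n_2 = length(y), p_value = NA_real_)
    }, by = .(state, domain)]
  }
  list(segments = seg[], tests = tests)
}

#' Build per-state 2x2 tables of phase-preferential repair by domain
#'
#' For each chromatin state, segments with both phase means defined are
#' dichotomized as better repaired in the first phase (early) or the second
#' (late); the 2x2 table crosses domain (ERD vs LRD rows) with that
#' dichotomy. Ties are excluded. Suitable input for [odds_ratio()] and
#' [breslow_day_tarone()].
#'
#' @param segments `$segments` from [chromatin_state_summary()].
#' @param phases Character vector of the two phase column names
#'   (default `c("early", "late")`).
#' @return Named list (per state) of 2x2 integer matrices with rows
#'   ERD/LRD and columns better_early/better_late.
#' @export
build_phase_tables <- function(segments, phases = c("early", "late")) {
  e <- segments[[phases[1L]]]; l <- segments[[phases[2L]]]
  ok <- !is.na(e) & !is.na(l) & e != l & !is.na(segments$domain)
  dt <- data.table::data.table(state = segments$state[ok],
                               domain = segments$domain[ok],
                               better_early = e[ok] > l[ok])
  out <- lapply(split(dt, dt$state), function(d) {
    m <- matrix(c(sum(d$domain == "ERD" & d$better_early),
                  sum(d$domain == "ERD" & !d$better_early),
                  sum(d$domain == "LRD" & d$better_early),
                  sum(d$domain == "LRD" & !d$better_early)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("ERD", "LRD"),
                                c("better_early", "better_late")))
    m
  })
  out
}
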