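library(data.table)

# tiny shared grid + hand-set signal matrices
mini_sm <- function(counts_plus, counts_minus, lib, grid) {
  sm <- count_reads_in_windows(data.table(chrom = character(),
                                          start = integer(), end = integer(),
                                          strand = character()),
                               grid, library_size = lib)
  sm$counts[, , "+"] <- counts_plus
  sm$counts[, , "-"] <- counts_minus
  sm
}

mini_grid <- function() {
  g <- pattern_genome()
  make_centered_windows(data.table(chrom = "chrT", start = 4000L, end = 6000L),
                        500L, 4L, g)
}

test_that("repair rate is the RPKM ratio with undefined zero-damage cells", {
  grid <- mini_grid()
  xr <- mini_sm(matrix(c(2L, 4L, 0L, 6L), 1), matrix(2L, 1, 4), 100, grid)
  dmg <- mini_sm(matrix(c(1L, 2L, 5L, 0L), 1), matrix(2L, 1, 4), 100, grid)
  rr <- repair_rate(xr, dmg)
  expect_equal(unname(rr$values[1, 1:2, "+"]), c(2, 2))
  expect_equal(unname(rr$values[1, 3, "+"]), 0)
  expect_true(is.na(rr$values[1, 4, "+"]))   # damage 0 -> undefined
  # global XR scaling scales RR linearly
  xr2 <- xr; xr2$counts <- xr$counts * 2L
  rr2 <- repair_rate(xr2, dmg)
  expect_equal(rr2$values, rr$values * 2)
  # grid mismatch is an error
  other <- make_centered_windows(data.table(chrom = "chrT", start = 1000L,
                                            end = 1400L), 500L, 4L,
                                 pattern_genome())
  expect_error(repair_rate(xr, mini_sm(matrix(1L, 1, 4), matrix(1L, 1, 4),
                                       10, other)))
})

test_that("normalized repair rate identities and depth invariance", {
  grid <- mini_grid()
  a <- matrix(c(8L, 2L, 4L, 6L), 1); b <- matrix(c(3L, 5L, 7L, 2L), 1)
  sm <- function(cp, lib) mini_sm(cp, cp, lib, grid)
  # real = simulated for both assays -> 0 everywhere
  n0 <- normalized_repair_rate(sm(a, 50), sm(a, 50), sm(b, 70), sm(b, 70))
  expect_equal(unname(n0$values[1, , "+"]), rep(0, 4))
  # XR_real = 2 x XR_sim (same library sizes), damage equal -> +1
  n1 <- normalized_repair_rate(sm(a * 2L, 50), sm(a, 50), sm(b, 70), sm(b, 70))
  expect_equal(unname(n1$values[1, , "+"]), rep(1, 4))
  # hand-computed 4-value cell
  nh <- normalized_repair_rate(sm(matrix(c(6L, 1L, 1L, 1L), 1), 10),
                               sm(matrix(c(3L, 1L, 1L, 1L), 1), 20),
                               sm(matrix(c(2L, 1L, 1L, 1L), 1), 30),
                               sm(matrix(c(4L, 1L, 1L, 1L), 1), 40))
  expect_equal(nh$values[1, 1, "+"],
               log2(((6 / 10) / (3 / 20)) / ((2 / 30) / (4 / 40))))
  # rescaling any library's depth (counts and library size together) is a no-op
  xr_r <- sm(a, 50); xr_s <- sm(b, 70); d_r <- sm(a + 1L, 90); d_s <- sm(b + 2L, 110)
  base <- normalized_repair_rate(xr_r, xr_s, d_r, d_s)
  xr_r2 <- xr_r; xr_r2$counts <- xr_r$counts * 7L; xr_r2$library_size <- 50 * 7
  expect_equal(normalized_repair_rate(xr_r2, xr_s, d_r, d_s)$values,
               base$values)
  # zero anywhere among the four -> undefined, tallied
  d0 <- sm(matrix(c(0L, 1L, 1L, 1L), 1), 30)
  nz <- normalized_repair_rate(xr_r, xr_s, d0, d_s)
  expect_true(is.na(nz$values[1, 1, "+"]))
  expect_equal(nz$n_undefined, 2L)  # both strands of the zero cell
})

test_that("accumulated repair fraction per cell", {
  grid <- mini_grid()
  d0 <- mini_sm(matrix(c(100L, 50L, 0L, 40L), 1), matrix(10L, 1, 4), 100, grid)
  d2 <- mini_sm(matrix(c(25L, 50L, 5L, 60L), 1), matrix(10L, 1, 4), 100, grid)
  ar <- accumulated_repair(d0, d2)
  expect_equal(ar$values[1, 1, "+"], 0.75)
  expect_equal(ar$values[1, 2, "+"], 0)
  expect_true(is.na(ar$values[1, 3, "+"]))
  expect_lt(ar$values[1, 4, "+"], 0)  # apparent gain allowed, flagged as value
})

test_that("early/late fold change recovers identity and planted boost", {
  grid <- mini_grid()
  a <- matrix(c(8L, 2L, 4L, 6L), 1)
  rr1 <- repair_rate(mini_sm(a, a, 10, grid), mini_sm(a, a, 10, grid))
  fc0 <- early_late_fold_change(rr1, rr1)
  expect_equal(fc0$log2fc, 0)
  rr2 <- repair_rate(mini_sm(a * 2L, a * 2L, 10, grid),
                     mini_sm(a, a, 10, grid))
  expect_equal(early_late_fold_change(rr2, rr1)$log2fc, 1)
  # planted phase boost on synthetic data, aggregated per domain
  w <- cached_world("phase", small_spec(seed = 12L, phase_boost = 0.3))
  dmg <- generate_damage_reads(w, 2e5)
  xre <- generate_xr_reads(w, 2e5, phase = "early")
  xrl <- generate_xr_reads(w, 2e5, phase = "late")
  grid2 <- make_centered_windows(iz_regions(w), 1000L, 30L, w$genome)
  smd <- count_reads_in_windows(dmg, grid2)
  fc <- early_late_fold_change(
    repair_rate(count_reads_in_windows(xre, grid2), smd),
    repair_rate(count_reads_in_windows(xrl, grid2), smd),
    domains = w$truth$izs$domain[match(grid2$regions$name,
                                       w$truth$izs$name)])
  expect_lt(abs(fc[domain == "ERD", log2fc] - 0.3), 0.05)
  expect_lt(abs(fc[domain == "LRD", log2fc] + 0.3), 0.05)
})

test_that("TSS/TES profiles separate template and non-template strands", {
  w <- default_world()
  genes <- w$truth$genes
  # all reads on the template strand (minus strand of + genes and vice versa)
  mk <- function(g, n = 400L) {
    st <- as.integer(seq(g$start, g$end - 30L, length.out = n))
    data.table(chrom = g$chrom, start = st, end = st + 20L,
               strand = ifelse(g$strand == "+", "-", "+"))
  }
  reads <- rbindlist(lapply(seq_len(nrow(genes)), function(i) mk(genes[i])))
  dmg <- rbindlist(lapply(seq_len(nrow(genes)), function(i) {
    r <- mk(genes[i]); rbind(r, copy(r)[, strand := ifelse(strand == "+",
                                                           "-", "+")])
  }))
  tt <- tss_tes_profile(reads, dmg, genes, w$genome, 100L, 20L)
  inside <- 11:20  # windows downstream of the TSS
  expect_true(all(tt$tss$TS[inside] > 0))
  expect_true(all(tt$tss$NTS[inside] == 0 | is.nan(tt$tss$NTS[inside])))
  # strand-balanced reads -> TS ~ NTS
  tt2 <- tss_tes_profile(dmg, dmg, genes, w$genome, 100L, 20L)
  expect_equal(tt2$tss$TS[inside], tt2$tss$NTS[inside], tolerance = 1e-9)
})

test_that("strand asymmetry: negative control, antisymmetry, planted ratio", {
  w_neg <- cached_world("neg", small_spec(seed = 3L, t_skew = c(ERD = 0, LRD = 0)))
  dmg <- generate_damage_reads(w_neg, 2e5)
  xr <- generate_xr_reads(w_neg, 2e5)
  grid <- make_centered_windows(iz_regions(w_neg), 500L, 60L, w_neg$genome)
  rr <- repair_rate(count_reads_in_windows(xr, grid),
                    count_reads_in_windows(dmg, grid))
  asym <- strand_asymmetry(rr, min_flank = 2000L)
  expect_lt(abs(asym$leading_minus_lagging), 0.05)
  # swapping read strands negates the per-side medians
  xr_sw <- copy(xr)[, strand := ifelse(strand == "+", "-", "+")]
  dmg_sw <- copy(dmg)[, strand := ifelse(strand == "+", "-", "+")]
  rr_sw <- repair_rate(count_reads_in_windows(xr_sw, grid),
                       count_reads_in_windows(dmg_sw, grid))
  asym_sw <- strand_asymmetry(rr_sw, min_flank = 2000L)
  expect_equal(asym_sw$per_side$median_plus_minus,
               -asym$per_side$median_plus_minus)
  # planted leading:lagging repair ratio 1.2 -> log2 asymmetry ~ 0.263
  w12 <- cached_world("rho12", small_spec(seed = 3L,
                                          repair_leading_excess = 1.2))
  dmg2 <- generate_damage_reads(w12, 3e5)
  xr2 <- generate_xr_reads(w12, 3e5)
  grid2 <- make_centered_windows(iz_regions(w12), 1000L, 36L, w12$genome)
  rr2 <- repair_rate(count_reads_in_windows(xr2, grid2),
                     count_reads_in_windows(dmg2, grid2))
  a2 <- strand_asymmetry(rr2, min_flank = 2000L)
  expect_lt(abs(a2$leading_minus_lagging - log2(1.2)), 0.08)
})

test_that("chromatin-state summaries detect a planted single-state effect", {
  grid <- mini_grid()
  set.seed(6)
  nreg <- 1L
  # build many segments over the grid span; one state gets a shifted phase
  states <- data.table(chrom = "chrT",
                       start = seq(4000L, 5900L, by = 100L),
                       end = seq(4100L, 6000L, by = 100L))
  states[, state := rep(c("open", "closed"), length.out = .N)]
  doms <- data.table(chrom = "chrT", start = 0L, end = 10000L, label = "ERD")
  base <- matrix(rpois(4, 50) + 10L, 1)
  early_counts <- mini_sm(base * 2L, base * 2L, 100, grid)
  late_counts <- mini_sm(base, base, 100, grid)
  dmgc <- mini_sm(base, base, 100, grid)
  rr_e <- repair_rate(early_counts, dmgc)
  rr_l <- repair_rate(late_counts, dmgc)
  cs <- chromatin_state_summary(list(early = rr_e, late = rr_l), states, doms,
                                min_segments = 3L)
  expect_true(all(cs$segments[!is.na(early), early] >=
                    cs$segments[!is.na(late), late]))
  # segment conservation across the domain partition
  expect_equal(nrow(cs$segments), nrow(states))
  tabs <- build_phase_tables(cs$segments)
  expect_true(all(vapply(tabs, function(t) sum(t[, "better_late"]) == 0,
                         logical(1))))
})
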