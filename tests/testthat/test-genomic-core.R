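library(data.table)

# independent oracle for the centered-window expansion: evaluates the
# truncating integer arithmetic span formula directly per region
awk_span_oracle <- function(start, end, a, b) {
  mid <- (start + end) / 2
  c(trunc(mid - a / 2 - a * (b - 1) / 2), trunc(mid + a / 2 + a * (b - 1) / 2))
}

test_that("centered windowing matches the integer-truncation oracle", {
  g <- pattern_genome()
  grid <- make_centered_windows(data.table(chrom = "chrT", start = 1000L,
                                           end = 3000L), 100L, 4L, g)
  expect_equal(grid$regions$span_start, 1800L)
  expect_equal(grid$regions$span_end, 2200L)
  expect_equal(grid$windows$start, c(1800L, 1900L, 2000L, 2100L))
  expect_equal(grid$windows$end, c(1900L, 2000L, 2100L, 2200L))

  set.seed(41)
  for (rep in 1:20) {
    a <- sample(c(37L, 100L, 251L), 1)
    b <- sample(1:7, 1)
    st <- sort(sample(2000:8000, 3))
    regs <- data.table(chrom = "chrT", start = st, end = st + sample(50:500, 3))
    grid <- suppressWarnings(make_centered_windows(regs, a, b, g))
    if (nrow(grid$regions) == 0) next
    for (i in seq_len(nrow(grid$regions))) {
      r <- grid$regions[i]
      orig <- regs[r$region_id]
      expect_identical(c(r$span_start, r$span_end),
                       as.integer(awk_span_oracle(orig$start, orig$end, a, b)))
    }
    # every surviving span is disjoint from every other original span
    spans <- t(vapply(seq_len(nrow(regs)), function(i)
      awk_span_oracle(regs$start[i], regs$end[i], a, b), numeric(2)))
    for (i in seq_len(nrow(grid$regions)))
      for (j in seq_len(nrow(regs)))
        if (grid$regions$region_id[i] != j)
          expect_true(grid$regions$span_end[i] <= spans[j, 1] ||
                        grid$regions$span_start[i] >= spans[j, 2])
  }
})

test_that("single recentered window reproduces the identity case", {
  g <- pattern_genome()
  grid <- make_centered_windows(data.table(chrom = "chrT", start = 2000L,
                                           end = 2400L), 400L, 1L, g)
  expect_equal(grid$regions$span_end - grid$regions$span_start, 400L)
  expect_equal(grid$regions$center, 2200)
})

test_that("overlapping expanded spans drop both members", {
  g <- pattern_genome()
  # spans: centered 100x4 = 400 bp; centers 350 apart -> 1 bp-scale overlap
  regs <- data.table(chrom = "chrT", start = c(2000L, 2399L),
                     end = c(2400L, 2799L))
  expect_warning(grid <- make_centered_windows(regs, 100L, 4L, g),
                 "no regions survive")
  expect_equal(nrow(grid$regions), 0L)
  expect_equal(unname(grid$n_dropped["overlapping"]), 2L)
  # regions crossing the chromosome boundary are dropped and tallied
  grid2 <- suppressWarnings(
    make_centered_windows(data.table(chrom = "chrT", start = 10L, end = 100L),
                          100L, 4L, g))
  expect_equal(nrow(grid2$regions), 0L)
  expect_equal(unname(grid2$n_dropped["out_of_bounds"]), 1L)
})

# per-base brute-force overlap counter
brute_counts <- function(reads, grid) {
  counts <- array(0L, dim = c(nrow(grid$regions), grid$window_num, 2L))
  for (ri in seq_len(nrow(reads))) {
    rd <- reads[ri]
    s <- if (rd$strand == "+") 1L else 2L
    for (wi in seq_len(nrow(grid$windows))) {
      w <- grid$windows[wi]
      if (w$chrom != rd$chrom) next
      bases <- intersect(seq(rd$start, rd$end - 1L), seq(w$start, w$end - 1L))
      if (length(bases) >= 1L) {
        r <- match(w$region_id, grid$regions$region_id)
        counts[r, w$window, s] <- counts[r, w$window, s] + 1L
      }
    }
  }
  counts
}

test_that("window counting agrees exactly with a per-base oracle", {
  g <- pattern_genome()
  regs <- data.table(chrom = "chrT", start = c(1000L, 6000L),
                     end = c(1400L, 6400L))
  grid <- make_centered_windows(regs, 50L, 8L, g)
  set.seed(7)
  st <- sample(500:7000, 60)
  reads <- data.table(chrom = "chrT", start = st,
                      end = st + sample(c(10L, 60L, 120L), 60, TRUE),
                      strand = sample(c("+", "-"), 60, TRUE))
  sm <- count_reads_in_windows(reads, grid)
  expect_identical(unname(sm$counts[, , ]), unname(brute_counts(reads, grid)))

  # a read spanning a window boundary increments both windows
  one <- data.table(chrom = "chrT", start = grid$windows$end[1] - 5L,
                    end = grid$windows$end[1] + 5L, strand = "+")
  sm1 <- count_reads_in_windows(one, grid)
  expect_equal(sm1$counts[1, 1, "+"], 1L)
  expect_equal(sm1$counts[1, 2, "+"], 1L)
  expect_equal(sum(sm1$counts), 2L)

  # empty read list -> all-zero matrix; unknown chromosomes are tallied
  sm0 <- count_reads_in_windows(reads[0], grid)
  expect_true(all(sm0$counts == 0L))
  smx <- count_reads_in_windows(data.table(chrom = "chrZ", start = 1L,
                                           end = 10L, strand = "+"), grid)
  expect_equal(smx$n_skipped, 1L)
})

test_that("RPKM follows its definition and is depth-scale invariant", {
  g <- pattern_genome()
  grid <- make_centered_windows(data.table(chrom = "chrT", start = 4000L,
                                           end = 6000L), 1000L, 2L, g)
  reads <- data.table(chrom = "chrT", start = rep(4100L, 10),
                      end = rep(4200L, 10), strand = "+")
  sm <- count_reads_in_windows(reads, grid, library_size = 1e6)
  expect_equal(rpkm(sm)[1, 1, "+"], 10)  # 10 reads, 1 kb window, 1e6 reads
  prof <- aggregate_profile(sm, "rpkm")
  sm2 <- sm; sm2$counts <- sm$counts * 2L; sm2$library_size <- 2e6
  expect_equal(aggregate_profile(sm2, "rpkm"), prof)
  expect_error(aggregate_profile(
    count_reads_in_windows(reads, grid, library_size = 0), "rpkm"))
})

test_that("aggregation averages window counts across regions", {
  g <- pattern_genome()
  grid <- make_centered_windows(data.table(chrom = "chrT",
                                           start = c(1000L, 6000L),
                                           end = c(1200L, 6200L)),
                                100L, 2L, g)
  reads <- data.table(chrom = "chrT",
                      start = c(rep(1010L, 2), rep(6010L, 4)),
                      end = c(rep(1020L, 2), rep(6020L, 4)),
                      strand = "+")
  prof <- aggregate_profile(count_reads_in_windows(reads, grid), "none")
  expect_equal(prof[window == 1 & strand == "+", value], 3)  # mean of 2 and 4
})

test_that("moving average handles constants, k=1, pulses and edges", {
  expect_equal(moving_average(rep(4, 20), 10), rep(4, 20))
  x <- rnorm(15)
  expect_equal(moving_average(x, 1), x)
  expect_equal(moving_average(c(0, 0, 10, 0, 0), 5)[3], 2)
  expect_equal(moving_average(numeric(0), 5), numeric(0))
  # edges use the shorter available window
  expect_equal(moving_average(c(1, 2, 3), 3)[1], 1.5)
  # NA bins are excluded from the mean
  expect_equal(moving_average(c(1, NA, 3), 3)[2], 2)
})

test_that("read conservation holds for non-overlapping single-window reads", {
  g <- pattern_genome()
  grid <- make_centered_windows(data.table(chrom = "chrT", start = 4000L,
                                           end = 6000L), 500L, 4L, g)
  # reads fully inside single windows
  st <- as.integer(grid$windows$start + 100L)
  reads <- data.table(chrom = "chrT", start = st, end = st + 50L,
                      strand = rep(c("+", "-"), 2))
  sm <- count_reads_in_windows(reads, grid)
  expect_equal(sum(sm$counts), nrow(reads))
})

test_that("BED6 and genome FASTA round-trip through files", {
  g <- pattern_genome(100L)
  fa <- tempfile(fileext = ".fa"); sz <- tempfile()
  write_genome_fasta(g, fa, sz)
  g2 <- read_genome_fasta(fa)
  expect_identical(as.character(g2$seqs), as.character(g$seqs))
  expect_identical(read_chrom_sizes(sz), g$lengths)
  bed <- tempfile(fileext = ".bed")
  dt <- data.table(chrom = "chrT", start = c(0L, 10L), end = c(5L, 20L),
                   name = c("a", "b"), score = c(0L, 1L),
                   strand = c("+", "-"))
  write_bed6(dt, bed)
  expect_equal(read_bed6(bed), dt)
})

test_that("genome accessor enforces bounds and strand orientation", {
  g <- toy_genome(c(chrS = "ACGTACGTAC"))
  expect_equal(genome_seq(g, "chrS", 0, 4), "ACGT")
  expect_equal(genome_seq(g, "chrS", 0, 4, "-"), "ACGT")  # palindrome
  expect_equal(genome_seq(g, "chrS", 1, 4, "-"), "ACG")   # revcomp of CGT
  expect_error(genome_seq(g, "chrS", -1, 4))
  expect_error(genome_seq(g, "chrS", 0, 11))
  expect_error(genome_seq(g, "nope", 0, 4))
})
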