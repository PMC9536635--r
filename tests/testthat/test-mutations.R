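library(data.table)

test_that("UV-signature classification follows the context rules", {
  #            0123456789
  g <- toy_genome(c(cm = "ATCAGAAGGC"))
  mut <- data.table(chrom = "cm",
                    pos = c(2L, 4L, 7L, 3L, 0L),
                    ref = c("C", "G", "G", "A", "A"),
                    alt = c("T", "A", "A", "G", "C"))
  cl <- classify_uv_mutations(mut, g)
  expect_equal(cl$class[1], "TC>TT")   # T at pos 1, C>T at pos 2
  expect_equal(cl$strand[1], "+")
  expect_equal(cl$class[2], "TC>TT")   # G>A at 4 with A at 5 -> minus TC
  expect_equal(cl$strand[2], "-")
  expect_equal(cl$class[3], "CC>CT")   # G>A at 7 with G at 8 -> minus CC
  expect_equal(cl$strand[3], "-")
  expect_equal(cl$class[4], "other")   # A>G is no UV signature
  expect_equal(cl$strand[5], "unassigned")
  # conservation: every record is classified exactly once
  expect_equal(sum(cl$class != "other") + sum(cl$class == "other"), nrow(mut))
})

test_that("classification swaps strands under genome reverse complementation", {
  w <- default_world()
  mut <- generate_mutations(w, 3000)
  mut0 <- mut[, .(chrom, pos = position - 1L, ref, alt, sample)]
  cl <- classify_uv_mutations(mut0, w$genome)
  # mirror the genome and the catalog coordinates
  g_rc <- genome(Biostrings::reverseComplement(w$genome$seqs))
  lens <- w$genome$lengths[mut0$chrom]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  mut_rc <- data.table(chrom = mut0$chrom, pos = lens - 1L - mut0$pos,
                       ref = comp[mut0$ref], alt = comp[mut0$alt])
  cl_rc <- classify_uv_mutations(mut_rc, g_rc)
  expect_equal(cl_rc$class, cl$class)
  flip <- c("+" = "-", "-" = "+", unassigned = "unassigned")
  expect_equal(cl_rc$strand, unname(flip[cl$strand]))
})

test_that("all generated mutations carry a UV signature class", {
  w <- default_world()
  mut <- generate_mutations(w, 5000)
  cl <- classify_uv_mutations(mut[, .(chrom, pos = position - 1L, ref, alt)],
                              w$genome)
  expect_true(all(cl$class %in% c("TC>TT", "CC>CT")))
  expect_true(all(cl$strand %in% c("+", "-")))
})

test_that("MC follows its definition on a hand-enumerated toy window", {
  # a period-20 genome: the window [240, 260) is exactly one period
  s <- "TCCCATCAGGAGGATTGACA"
  g <- toy_genome(c(ct = paste(rep(s, 25), collapse = "")))
  grid <- make_centered_windows(data.table(chrom = "ct", start = 240L,
                                           end = 260L), 20L, 1L, g)
  expect_equal(grid$windows$start, 240L)
  ctx_plus <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(s), 2L)
  mut <- data.table(chrom = "ct", pos = 240L + c(1L, 2L, 6L),
                    ref = "C", alt = "T",
                    class = c("TC>TT", "CC>CT", "TC>TT"),
                    strand = c("+", "+", "+"))
  mc <- normalized_mutation_counts(mut, grid, g)
  plus <- mc[strand == "+"]
  expect_equal(plus$n_context,
               as.integer(ctx_plus[, "TC"] + ctx_plus[, "CC"]))
  expect_equal(plus$n_mut, 3L)
  expect_equal(plus$mc, 3 / plus$n_context)
  minus <- mc[strand == "-"]
  expect_equal(minus$n_context,
               as.integer(ctx_plus[, "GA"] + ctx_plus[, "GG"]))
  # zero mutations -> MC 0; zero contexts -> undefined
  mc0 <- normalized_mutation_counts(mut[0], grid, g)
  expect_equal(mc0[strand == "+", mc], 0)
  g_a <- toy_genome(c(ca = paste(rep("A", 500), collapse = "")))
  grid_a <- make_centered_windows(data.table(chrom = "ca", start = 240L,
                                             end = 260L), 20L, 1L, g_a)
  mca <- normalized_mutation_counts(mut[0], grid_a, g_a)
  expect_true(all(is.na(mca$mc)))
})

test_that("MC arithmetic: stated example", {
  # 4 TC>TT + 2 CC>CT over 100 TC + 100 CC contexts -> 0.03
  expect_equal((4 + 2) / (100 + 100), 0.03)
})

test_that("intergenic filtering and recurrence collapsing", {
  w <- default_world()
  mut <- generate_mutations(w, 8000)
  cl <- classify_uv_mutations(mut[, .(chrom, pos = position - 1L, ref, alt,
                                      sample)], w$genome)
  grid <- make_centered_windows(iz_regions(w), 1000L, 30L, w$genome)
  mc_all <- normalized_mutation_counts(cl, grid, w$genome)
  mc_ig <- normalized_mutation_counts(cl, grid, w$genome,
                                      genes = w$truth$genes)
  expect_lte(sum(mc_ig$n_mut), sum(mc_all$n_mut))
  dup <- rbind(cl, cl)  # every occurrence duplicated
  mc_dup <- normalized_mutation_counts(dup, grid, w$genome)
  mc_col <- normalized_mutation_counts(dup, grid, w$genome,
                                       collapse_recurrent = TRUE)
  expect_equal(sum(mc_dup$n_mut), 2L * sum(mc_all$n_mut))
  # collapsing counts each mutated site once, however often it recurs
  mc_uni <- normalized_mutation_counts(
    unique(cl, by = c("chrom", "pos", "ref", "alt")), grid, w$genome)
  expect_equal(sum(mc_col$n_mut), sum(mc_uni$n_mut))
})

test_that("strand-balanced catalogs give near-zero quartile differences", {
  w <- cached_world("neg", small_spec(seed = 3L, t_skew = c(ERD = 0, LRD = 0)))
  mut <- generate_mutations(w, 20000)
  cl <- classify_uv_mutations(mut[, .(chrom, pos = position - 1L, ref, alt,
                                      sample)], w$genome)
  grid <- make_centered_windows(iz_regions(w), 1000L, 36L, w$genome)
  truth <- w$truth$izs
  qs <- quartile_by_score(
    copy(grid$regions)[, score := truth$efficiency[match(name, truth$name)]])
  qsd <- quartile_strand_difference(
    normalized_mutation_counts(cl, grid, w$genome), grid,
    qs$quartile, truth$domain[match(grid$regions$name, truth$name)])
  # the absolute per-side difference of a balanced catalog is noise-scale
  expect_lt(max(qsd$abs_diff / (qsd$plus_count + qsd$minus_count)), 0.15)
  # swapping strands leaves absolute differences unchanged
  cl_sw <- copy(cl)[, strand := c("+" = "-", "-" = "+")[strand]]
  qsd_sw <- quartile_strand_difference(
    normalized_mutation_counts(cl_sw, grid, w$genome), grid,
    qs$quartile, truth$domain[match(grid$regions$name, truth$name)])
  expect_equal(qsd_sw$abs_diff, qsd$abs_diff)
})

test_that("lagging excess scaled by efficiency yields a quartile trend", {
  spec <- small_spec(seed = 21L,
                     damage_lagging_excess = c(ERD = 1.2, LRD = 3))
  w <- cached_world("mutq", spec)
  mut <- generate_mutations(w, 50000)
  cl <- classify_uv_mutations(mut[, .(chrom, pos = position - 1L, ref, alt,
                                      sample)], w$genome)
  grid <- make_centered_windows(iz_regions(w), 1000L, 36L, w$genome)
  truth <- w$truth$izs
  qs <- quartile_by_score(
    copy(grid$regions)[, score := truth$efficiency[match(name, truth$name)]])
  qsd <- quartile_strand_difference(
    normalized_mutation_counts(cl, grid, w$genome, genes = w$truth$genes),
    grid, qs$quartile, truth$domain[match(grid$regions$name, truth$name)])
  lrd <- qsd[domain == "LRD"][order(quartile)]
  expect_gte(cor(lrd$quartile, lrd$abs_diff, method = "spearman"), 0.9)
})

test_that("mutation catalogs round-trip through the TSV reader", {
  w <- default_world()
  mut <- generate_mutations(w, 500)
  f <- tempfile(fileext = ".tsv")
  fwrite(mut, f, sep = "\t")
  back <- read_mutation_tsv(f)
  expect_equal(back$pos, mut$position - 1L)
  expect_equal(back$ref, mut$ref)
  expect_equal(nrow(back), nrow(mut))
})
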