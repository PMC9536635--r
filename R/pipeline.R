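#' Log2 signal profile of a single library
#'
#' Wraps one signal matrix as a log2-RPKM profile so that strand-asymmetry
#' machinery built for repair rates can be applied to a single assay
#' (e.g. Damage-seq alone). Zero-count cells are undefined.
#'
#' @param sm A `"signal_matrix"`.
#' @return A `"repair_profile"` with `$kind = "signal"` (log2 scale).
#' @export
signal_profile <- function(sm) {
  vals <- log2(rpkm(sm))
  vals[sm$counts == 0L] <- NA_real_
  structure(list(grid = sm$grid, values = vals, kind = "signal",
                 n_undefined = sum(sm$counts == 0L)),
            class = "repair_profile")
}

#' End-to-end strand-asymmetry analysis around initiation zones
#'
#' Runs the full chain on one synthetic world: generates Damage-seq,
#' XR-seq and mutation data, simulates sequence-context-matched libraries
#' for both assays, builds an initiation-zone-centered window grid
#' (optionally restricted to one replication domain), and summarizes the
#' strand asymmetry of raw damage, of the simulation-normalized repair
#' rate, and of the context-normalized mutation rate (MC).
#'
#' @param world A `"synthetic_world"`.
#' @param n_damage,n_xr Real library sizes (default 2e5).
#' @param n_sim Simulated library size per assay (default 2e4).
#' @param n_mut Mutation catalog size (default 5e4).
#' @param interval_len,window_num Grid geometry (default 1 kb x 100).
#' @param domain Restrict to zones of one domain label (default "LRD";
#'   NULL keeps all zones).
#' @param min_flank Flank exclusion around the zone center (default 2 kb).
#' @param sim_seed Seed for the context-matched simulator (default derived
#'   from the world's spec seed).
#' @return list: `$damage`, `$nrr`, `$mc` (each an `"asymmetry_summary"`),
#'   plus `$grid` and the library sizes used.
#' @export
fork_asymmetry_pipeline <- function(world, n_damage = 2e5, n_xr = 2e5,
                                    n_sim = 2e4, n_mut = 5e4,
                                    interval_len = 1000L, window_num = 100L,
                                    domain = "LRD", min_flank = 2000L,
                                    sim_seed = world$spec$seed + 901L) {
  izs <- world$truth$izs
  if (!is.null(domain)) {
    dom_label <- domain
    izs <- izs[izs$domain %in% dom_label]
  }
  regs <- izs[, .(chrom, start = as.integer(center - interval_len %/% 2L),
                  end = as.integer(center + interval_len %/% 2L),
                  name, strand = ".")]
  grid <- make_centered_windows(regs, interval_len, window_num, world$genome)

  dmg <- generate_damage_reads(world, n_damage)
  xr <- generate_xr_reads(world, n_xr)

  dmg_model <- build_profile(
    locate_damage_sites(dmg, world$genome)[, .(chrom, start, end, strand)],
    world$genome,
    anchor = list(position = 5L, dinucleotides = c("TT", "TC", "CT", "CC")))
  dmg_sim_win <- simulate_reads(dmg_model, world$genome, n_sim,
                                seed = sim_seed)
  # convert simulated 10-mer damage windows back to read-like intervals so
  # both real and simulated damage enter counting identically: the lesion
  # sits at window positions 5-6 (genomic [s+4, s+6) for a plus window),
  # and reads start two bases 3' of the lesion in read orientation
  rl <- world$spec$damage_read_length
  dmg_sim <- dmg_sim_win[, .(chrom,
                             start = as.integer(
                               ifelse(strand == "+", start + 6L, start + 4L - rl)),
                             end = as.integer(
                               ifelse(strand == "+", start + 6L + rl, start + 4L)),
                             strand)]
  xr_model <- build_profile(xr, world$genome,
    anchor = list(position = -5L,
                  dinucleotides = c("TT", "TC", "CT", "CC")))
  xr_sim <- simulate_reads(xr_model, world$genome, n_sim, seed = sim_seed + 1L)

  sm_d <- count_reads_in_windows(dmg, grid)
  sm_x <- count_reads_in_windows(xr, grid)
  sm_ds <- count_reads_in_windows(dmg_sim, grid)
  sm_xs <- count_reads_in_windows(xr_sim, grid)

  nrr <- normalized_repair_rate(sm_x, sm_xs, sm_d, sm_ds)
  mut <- generate_mutations(world, n_mut)
  cl <- classify_uv_mutations(
    mut[, .(chrom, pos = position - 1L, ref, alt, sample)], world$genome)
  mc <- normalized_mutation_counts(cl, grid, world$genome,
                                   genes = world$truth$genes)

  list(damage = strand_asymmetry(signal_profile(sm_d), min_flank),
       nrr = strand_asymmetry(nrr, min_flank),
       mc = strand_asymmetry(.mc_profile(mc, grid), min_flank),
       grid = grid,
       n = c(damage = nrow(dmg), xr = nrow(xr), sim = n_sim,
             mutations = nrow(cl)))
}

# wrap a long MC table as a log2 profile on its grid
.mc_profile <- function(mc, grid) {
  nr <- nrow(grid$regions); nw <- grid$window_num
  vals <- array(NA_real_, dim = c(nr, nw, 2L),
                dimnames = list(as.character(grid$regions$region_id),
                                as.character(seq_len(nw)), c("+", "-")))
  ridx <- match(mc$region_id, grid$regions$region_id)
  sidx <- ifelse(mc$strand == "+", 1L, 2L)
  # log2 with a half-count pseudo-mutation so zero windows stay comparable
  v <- log2((mc$n_mut + 0.5) / mc$n_context)
  v[mc$n_context == 0L] <- NA_real_
  vals[cbind(ridx, mc$window, sidx)] <- v
  structure(list(grid = grid, values = vals, kind = "signal",
                 n_undefined = sum(is.na(vals))),
            class = "repair_profile")
}
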