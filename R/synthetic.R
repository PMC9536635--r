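#' Specification for the synthetic study system
#'
#' Describes a small multi-chromosome genome with planted replication
#' domains (ERD/LRD), initiation zones with efficiencies, lagging-strand
#' T-skew, dipyrimidine damage propensities, a strand- and phase-aware
#' repair field, genes and chromatin-like states. All generators are
#' deterministic given the spec and its seed, and the planted ground truth
#' is returned alongside the genome so recovery tests never read generator
#' internals.
#'
#' Knob conventions: `t_skew` moves base probability mass from A to T on
#' the lagging-strand side of each zone (per domain). AT content per domain
#' defaults to 54% in ERDs and 62% in LRDs. `damage_lagging_excess` and
#' `repair_leading_excess` are lagging:leading (resp. leading:lagging)
#' ratios applied symmetrically (sqrt up / sqrt down) within
#' `skew_halfwidth` of zone centers; either a scalar or a named
#' `c(ERD=, LRD=)` vector. `phase_boost` is the planted early-vs-late
#' log2 fold change of repair in ERDs (mirrored in LRDs).
#'
#' @param seed Integer seed.
#' @param chrom_lengths Named vector (default two 2-Mb chromosomes).
#' @param iz_per_domain Zones planted per domain (default 4; keeps score
#'   quartiles balanced across domain blocks).
#' @param iz_extent Ascent extent of each zone in bases (default 30 kb).
#' @param iz_efficiency Efficiencies in (0, 1]; recycled across zones
#'   (default a spread from 0.4 to 0.95).
#' @param at_content Named per-domain A+T fraction.
#' @param t_skew Named per-domain probability shift from A to T on the
#'   lagging strand near zones.
#' @param skew_halfwidth Half-width of the zone-influence window (bases).
#' @param damage_propensity Relative lesion propensity per dipyrimidine.
#' @param damage_lagging_excess,repair_leading_excess Strand-asymmetry
#'   knobs (1 = none).
#' @param phase_boost Early/late repair log2FC knob (0 = none).
#' @param repair_fraction_2h Fraction of lesions repaired by 2 h (baseline).
#' @param excision_lengths,excision_probs Excision-length distribution
#'   (default 22-30 nt, mode 26).
#' @param damage_read_length,okazaki_length,edu_read_length Read lengths.
#' @param edu_enrichment Phase-matched domain enrichment of EdU reads.
#' @param n_genes_per_chrom,gene_length Gene layout.
#' @param n_states,state_tile State layout (cycling labels).
#' @return A `"synthetic_spec"` list.
#' @export
synthetic_spec <- function(seed = 1L,
                           chrom_lengths = c(chr1 = 2e6, chr2 = 2e6),
                           iz_per_domain = 4L,
                           iz_extent = 30000L,
                           iz_efficiency = NULL,
                           at_content = c(ERD = 0.54, LRD = 0.62),
                           t_skew = c(ERD = 0.04, LRD = 0.08),
                           skew_halfwidth = 50000L,
                           damage_propensity = c(TT = 0.4, TC = 0.25,
                                                 CT = 0.25, CC = 0.1),
                           damage_lagging_excess = 1,
                           repair_leading_excess = 1,
                           phase_boost = 0,
                           repair_fraction_2h = 0.5,
                           excision_lengths = 22:30,
                           excision_probs = c(1, 2, 4, 7, 10, 7, 4, 2, 1) / 38,
                           damage_read_length = 100L,
                           okazaki_length = 150L,
                           edu_read_length = 100L,
                           edu_enrichment = 4,
                           n_genes_per_chrom = 6L,
                           gene_length = 40000L,
                           n_states = 8L,
                           state_tile = 25000L) {
  expand2 <- function(x) if (length(x) == 1L && is.null(names(x)))
    c(ERD = unname(x), LRD = unname(x)) else x
  spec <- list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
               iz_per_domain = iz_per_domain, iz_extent = iz_extent,
               iz_efficiency = iz_efficiency, at_content = at_content,
               t_skew = expand2(t_skew), skew_halfwidth = skew_halfwidth,
               damage_propensity = damage_propensity,
               damage_lagging_excess = expand2(damage_lagging_excess),
               repair_leading_excess = expand2(repair_leading_excess),
               phase_boost = phase_boost,
               repair_fraction_2h = repair_fraction_2h,
               excision_lengths = excision_lengths,
               excision_probs = excision_probs,
               damage_read_length = damage_read_length,
               okazaki_length = okazaki_length,
               edu_read_length = edu_read_length,
               edu_enrichment = edu_enrichment,
               n_genes_per_chrom = n_genes_per_chrom,
               gene_length = gene_length,
               n_states = n_states, state_tile = state_tile)
  class(spec) <- "synthetic_spec"
  spec
}

# planted layout (no RNG): domains, zones, genes, states
.plant_layout <- function(spec) {
  doms <- list(); izs <- list(); genes <- list(); states <- list()
  k <- 0L
  for (chr in names(spec$chrom_lengths)) {
    L <- as.integer(spec$chrom_lengths[[chr]])
    half <- L %/% 2L
    doms[[chr]] <- data.table::data.table(
      chrom = chr, start = c(0L, half), end = c(half, L),
      label = c("ERD", "LRD"))
    for (d in 1:2) {
      ds <- doms[[chr]]$start[d]; de <- doms[[chr]]$end[d]
      centers <- ds + (seq_len(spec$iz_per_domain)) *
        ((de - ds) %/% (spec$iz_per_domain + 1L))
      for (cc in centers) {
        k <- k + 1L
        izs[[k]] <- data.table::data.table(
          chrom = chr, center = as.numeric(cc),
          start = as.integer(cc - spec$iz_extent %/% 2L),
          end = as.integer(cc + spec$iz_extent %/% 2L),
          domain = doms[[chr]]$label[d])
      }
    }
    # genes sit midway between neighbouring zones of a domain, clear of the
    # zone-influence windows, so intergenic filtering is uniform across zones
    zc <- sort(unlist(lapply(izs[(k - 2L * spec$iz_per_domain + 1L):k],
                             function(z) z$center)))
    gaps <- (zc[-1] + zc[-length(zc)]) / 2
    gaps <- gaps[vapply(gaps, function(gp)
      min(abs(gp - zc)) - spec$gene_length / 2 > spec$skew_halfwidth,
      logical(1))]
    gs <- round(rep(gaps, length.out = spec$n_genes_per_chrom) -
                  spec$gene_length / 2)
    genes[[chr]] <- data.table::data.table(
      chrom = chr, start = as.integer(gs),
      end = as.integer(gs + spec$gene_length),
      name = paste0(chr, "_gene", seq_along(gs)), score = 0,
      strand = rep(c("+", "-"), length.out = length(gs)))
    st <- seq(0L, L - 1L, by = spec$state_tile)
    states[[chr]] <- data.table::data.table(
      chrom = chr, start = as.integer(st),
      end = as.integer(pmin(st + spec$state_tile, L)),
      state = paste0("state", rep(seq_len(spec$n_states),
                                  length.out = length(st))))
  }
  iz <- data.table::rbindlist(izs)
  eff <- spec$iz_efficiency
  if (is.null(eff)) {
    # spread efficiencies within every domain block (distinct across blocks)
    # so efficiency is not confounded with domain or chromosome
    n_blocks <- ceiling(nrow(iz) / spec$iz_per_domain)
    eff <- as.vector(vapply(seq_len(n_blocks) - 1L, function(b)
      seq(0.4, 0.9, length.out = spec$iz_per_domain) + b * 0.012,
      numeric(spec$iz_per_domain)))
  }
  iz[, "efficiency" := rep(eff, length.out = .N)]
  iz[, "name" := paste0("iz", seq_len(.N))]
  list(domains = data.table::rbindlist(doms), izs = iz,
       genes = data.table::rbindlist(genes),
       states = data.table::rbindlist(states))
}

#' Generate the synthetic genome and its ground-truth manifest
#'
#' Bases are drawn independently per position from a composition that
#' depends on the local domain (AT content) and, within `skew_halfwidth`
#' of a zone center, on the side of the zone: on the right-replicating
#' side the forward (= lagging-template) strand gains T at the expense of
#' A; the left side is mirrored. Returns the genome plus planted truth
#' (domains, zones, genes, states, the true RFD curve) and a precomputed
#' dipyrimidine site table used by the read generators.
#'
#' @param spec A `"synthetic_spec"`.
#' @return A `"synthetic_world"` list: `$genome`, `$truth`, `$sites`,
#'   `$spec`.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  layout <- .plant_layout(spec)
  g <- .with_seed(spec$seed + 101L, {
    seqs <- lapply(names(spec$chrom_lengths), function(chr) {
      L <- as.integer(spec$chrom_lengths[[chr]])
      segs <- .composition_segments(spec, layout, chr, L)
      paste(vapply(seq_len(nrow(segs)), function(i) {
        n <- segs$end[i] - segs$start[i]
        p <- c(segs$pA[i], segs$pC[i], segs$pG[i], segs$pT[i])
        paste(sample(c("A", "C", "G", "T"), n, TRUE, p), collapse = "")
      }, character(1)), collapse = "")
    })
    names(seqs) <- names(spec$chrom_lengths)
    genome(Biostrings::DNAStringSet(unlist(seqs)))
  })
  truth <- layout
  truth$rfd <- .true_rfd_knots(spec, layout)
  world <- list(genome = g, truth = truth, spec = spec,
                sites = .dipyrimidine_sites(g, spec))
  class(world) <- "synthetic_world"
  world
}

# run expr with a private RNG stream, restoring global state afterwards
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

# constant-composition segments for one chromosome
.composition_segments <- function(spec, layout, chr, L) {
  doms <- layout$domains[layout$domains$chrom == chr]
  izs <- layout$izs[layout$izs$chrom == chr]
  comp_base <- function(domain) {
    at <- spec$at_content[[domain]]
    c(pA = at / 2, pC = (1 - at) / 2, pG = (1 - at) / 2, pT = at / 2)
  }
  cuts <- sort(unique(c(0L, doms$end,
                        pmax(as.integer(izs$center) - spec$skew_halfwidth, 0L),
                        as.integer(izs$center),
                        pmin(as.integer(izs$center) + spec$skew_halfwidth, L),
                        L)))
  segs <- data.table::data.table(start = cuts[-length(cuts)], end = cuts[-1])
  segs <- segs[end > start]
  comp <- t(vapply(seq_len(nrow(segs)), function(i) {
    mid <- (segs$start[i] + segs$end[i]) / 2
    dom <- doms$label[mid >= doms$start & mid < doms$end][1L]
    p <- comp_base(dom)
    near <- which(abs(izs$center - mid) <= spec$skew_halfwidth)
    if (length(near)) {
      s <- spec$t_skew[[izs$domain[near[1L]]]]
      if (mid >= izs$center[near[1L]]) {   # right side: forward strand gains T
        p["pT"] <- p["pT"] + s; p["pA"] <- p["pA"] - s
      } else {
        p["pA"] <- p["pA"] + s; p["pT"] <- p["pT"] - s
      }
    }
    p
  }, numeric(4)))
  cbind(segs, data.table::as.data.table(comp))
}

# piecewise-linear true RFD per chromosome (list of approxfun inputs)
.true_rfd_knots <- function(spec, layout) {
  out <- list()
  for (chr in names(spec$chrom_lengths)) {
    L <- as.numeric(spec$chrom_lengths[[chr]])
    izs <- layout$izs[layout$izs$chrom == chr]
    data.table::setorder(izs, center)
    amp <- 0.9 * izs$efficiency
    x <- c(0); y <- c(-amp[1L])
    for (i in seq_len(nrow(izs))) {
      x <- c(x, izs$center[i] - spec$iz_extent / 2,
             izs$center[i] + spec$iz_extent / 2)
      y <- c(y, -amp[i], amp[i])
    }
    x <- c(x, L); y <- c(y, amp[length(amp)])
    out[[chr]] <- list(x = x, y = y)
  }
  out
}

# table of all dipyrimidine-bearing positions on both strands
# p = forward 0-based start of the dinucleotide; site = read-orientation 2-mer
.dipyrimidine_sites <- function(g, spec) {
  prop <- spec$damage_propensity
  dipy <- names(prop)
  anti <- stats::setNames(revcomp(dipy), dipy)  # minus-strand forward images
  out <- list()
  for (chr in names(g$lengths)) {
    s <- as.character(g$seqs[[chr]])
    L <- nchar(s)
    b <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    code <- 4L * (b[-L] - 1L) + b[-1L]         # NA where either base is N
    bases <- c("A", "C", "G", "T")
    pair_lookup <- paste0(rep(bases, each = 4L), rep(bases, times = 4L))
    pairs <- pair_lookup[code]
    for (strand in c("+", "-")) {
      want <- if (strand == "+") dipy else unname(anti)
      idx <- which(pairs %in% want)
      if (!length(idx)) next
      site <- if (strand == "+") pairs[idx] else revcomp(pairs[idx])
      out[[length(out) + 1L]] <- data.table::data.table(
        chrom = chr, p = idx - 1L, strand = strand, site = site,
        w = unname(prop[site]))
    }
  }
  data.table::rbindlist(out)
}

# side (+1 right, -1 left, 0 outside influence), nearest-zone domain and
# efficiency for positions
.zone_context <- function(world, chrom, pos) {
  spec <- world$spec
  izs <- world$truth$izs
  side <- integer(length(pos)); dom <- rep(NA_character_, length(pos))
  eff <- rep(NA_real_, length(pos))
  for (chr in unique(chrom)) {
    ii <- which(chrom == chr)
    z <- izs[izs$chrom == chr]
    data.table::setorder(z, center)
    if (!nrow(z)) next
    near <- findInterval(pos[ii], z$center) # zones left of position
    cand_lo <- pmax(near, 1L); cand_hi <- pmin(near + 1L, nrow(z))
    d_lo <- abs(pos[ii] - z$center[cand_lo])
    d_hi <- abs(pos[ii] - z$center[cand_hi])
    best <- ifelse(d_hi < d_lo, cand_hi, cand_lo)
    dist <- pmin(d_lo, d_hi)
    within <- dist <= spec$skew_halfwidth
    side[ii[within]] <- ifelse(pos[ii][within] >= z$center[best[within]], 1L, -1L)
    dom[ii] <- z$domain[best]
    eff[ii] <- z$efficiency[best]
  }
  # domain at the position itself (for phase boosts, independent of zones)
  domp <- rep(NA_character_, length(pos))
  dd <- world$truth$domains
  for (chr in unique(chrom)) {
    ii <- which(chrom == chr)
    d <- dd[dd$chrom == chr]
    j <- findInterval(pos[ii], d$start)
    domp[ii] <- d$label[pmax(j, 1L)]
  }
  list(side = side, zone_domain = dom, zone_efficiency = eff,
       pos_domain = domp)
}

# per-site multiplier tables -----------------------------------------------

# lagging flag: +1 lagging, -1 leading, 0 neither
.lagging_sign <- function(side, strand) {
  ifelse(side == 0L, 0L,
         ifelse((side == 1L & strand == "+") | (side == -1L & strand == "-"),
                1L, -1L))
}

.damage_weights <- function(world) {
  spec <- world$spec
  st <- world$sites
  ctx <- .zone_context(world, st$chrom, st$p)
  lag <- .lagging_sign(ctx$side, st$strand)
  delta <- unname(spec$damage_lagging_excess[ctx$zone_domain])
  delta[is.na(delta) | lag == 0L] <- 1
  list(w = st$w * sqrt(delta)^lag,
       survival = 1 - .repair_fraction(world, ctx, lag))
}

.repair_fraction <- function(world, ctx, lag) {
  spec <- world$spec
  rho <- unname(spec$repair_leading_excess[ctx$zone_domain])
  rho[is.na(rho) | lag == 0L] <- 1
  pmin(spec$repair_fraction_2h * sqrt(rho)^(-lag), 0.95)
}

.xr_weights <- function(world, phase = NULL) {
  spec <- world$spec
  st <- world$sites
  ctx <- .zone_context(world, st$chrom, st$p)
  lag <- .lagging_sign(ctx$side, st$strand)
  delta <- unname(spec$damage_lagging_excess[ctx$zone_domain])
  delta[is.na(delta) | lag == 0L] <- 1
  rho <- unname(spec$repair_leading_excess[ctx$zone_domain])
  rho[is.na(rho) | lag == 0L] <- 1
  w <- st$w * sqrt(delta)^lag * sqrt(rho)^(-lag)
  if (!is.null(phase) && spec$phase_boost != 0) {
    sgn <- ifelse(ctx$pos_domain == "ERD", 1, -1) *
      ifelse(phase == "early", 1, -1)
    w <- w * 2^(spec$phase_boost / 2 * sgn)
  }
  w
}

#' Generate Damage-seq reads
#'
#' Lesion sites are drawn proportionally to dipyrimidine propensity (times
#' the planted lagging-strand excess near zones); each read is placed so
#' the lesion dinucleotide sits two bases upstream of the read's 5' end.
#' At the 2 h time point, `n` lesions are drawn as at 0 h and each then
#' survives with probability `1 - repair fraction` at its site and strand,
#' so the returned library is smaller in expectation and directly
#' comparable to the 0 h library on a common scale.
#'
#' @param world A `"synthetic_world"`.
#' @param n Number of lesions drawn (reads returned are fewer at 2 h).
#' @param timepoint `"0h"` or `"2h"`.
#' @return BED6-style data.table of reads.
#' @export
generate_damage_reads <- function(world, n, timepoint = c("0h", "2h")) {
  timepoint <- match.arg(timepoint)
  spec <- world$spec
  dw <- .damage_weights(world)
  rl <- spec$damage_read_length
  .with_seed(spec$seed + 211L + (timepoint == "2h") * 7L, {
    idx <- sample.int(nrow(world$sites), n, replace = TRUE, prob = dw$w)
    if (timepoint == "2h")
      idx <- idx[stats::runif(length(idx)) < dw$survival[idx]]
    st <- world$sites[idx]
    start <- ifelse(st$strand == "+", st$p + 2L, st$p - rl)
    rd <- data.table::data.table(chrom = st$chrom, start = as.integer(start),
                                 end = as.integer(start + rl),
                                 name = paste0("dmg_", seq_along(idx)),
                                 score = 0, strand = st$strand)
    lens <- world$genome$lengths[match(rd$chrom, names(world$genome$lengths))]
    rd[start >= 0L & end <= lens]
  })
}

#' Generate XR-seq excision reads
#'
#' Excision fragments with lengths from the spec's distribution (default
#' 22-30 nt, mode 26) carrying the lesion dinucleotide 5-6 nt from the 3'
#' end; site rates are damage propensity times the planted strand- and
#' phase-specific repair field.
#'
#' @param world A `"synthetic_world"`.
#' @param n Number of reads.
#' @param phase Optional `"early"`/`"late"` (activates the phase boost).
#' @return BED6-style data.table of reads.
#' @export
generate_xr_reads <- function(world, n, phase = NULL) {
  spec <- world$spec
  w <- .xr_weights(world, phase)
  .with_seed(spec$seed + 311L +
               if (is.null(phase)) 0L else (phase == "late") * 13L, {
    idx <- sample.int(nrow(world$sites), n, replace = TRUE, prob = w)
    st <- world$sites[idx]
    L <- sample(spec$excision_lengths, n, TRUE, spec$excision_probs)
    start <- ifelse(st$strand == "+", st$p - L + 6L, st$p - 4L)
    rd <- data.table::data.table(chrom = st$chrom, start = as.integer(start),
                                 end = as.integer(start + L),
                                 name = paste0("xr_", seq_len(n)), score = 0,
                                 strand = st$strand)
    lens <- world$genome$lengths[match(rd$chrom, names(world$genome$lengths))]
    rd[start >= 0L & end <= lens]
  })
}

#' Generate EdU-seq reads for one S-phase fraction
#'
#' Reads are uniform within domains, enriched `edu_enrichment`-fold in the
#' domains replicating in the requested phase (ERDs for early, LRDs for
#' late).
#'
#' @param world A `"synthetic_world"`.
#' @param phase `"early"` or `"late"`.
#' @param n Number of reads.
#' @return BED6-style data.table.
#' @export
generate_edu_reads <- function(world, phase = c("early", "late"), n) {
  phase <- match.arg(phase)
  spec <- world$spec
  dd <- data.table::copy(world$truth$domains)
  dd[, "w" := ifelse((label == "ERD") == (phase == "early"),
                     spec$edu_enrichment, 1) * (end - start)]
  rl <- spec$edu_read_length
  .with_seed(spec$seed + 411L + (phase == "late") * 17L, {
    di <- sample.int(nrow(dd), n, TRUE, prob = dd$w)
    start <- dd$start[di] +
      floor(stats::runif(n) * (dd$end[di] - dd$start[di] - rl))
    data.table::data.table(chrom = dd$chrom[di], start = as.integer(start),
                           end = as.integer(start + rl),
                           name = paste0("edu_", seq_len(n)), score = 0,
                           strand = sample(c("+", "-"), n, TRUE))
  })
}

#' Generate OK-seq Okazaki-fragment reads
#'
#' Positions are uniform; the mapped strand is drawn so the binned
#' replication fork directionality follows the planted piecewise-linear
#' RFD curve, which ascends across each zone with amplitude proportional
#' to its efficiency: `P(minus) = (1 + RFD_true) / 2`.
#'
#' @param world A `"synthetic_world"`.
#' @param n Number of reads.
#' @return BED6-style data.table.
#' @export
generate_okseq_reads <- function(world, n) {
  spec <- world$spec
  lens <- spec$chrom_lengths
  rl <- spec$okazaki_length
  .with_seed(spec$seed + 511L, {
    ci <- sample.int(length(lens), n, TRUE, prob = as.numeric(lens))
    chrom <- names(lens)[ci]
    start <- floor(stats::runif(n) * (as.numeric(lens)[ci] - rl))
    mid <- start + rl / 2
    rfdv <- numeric(n)
    for (chr in unique(chrom)) {
      ii <- which(chrom == chr)
      kn <- world$truth$rfd[[chr]]
      rfdv[ii] <- stats::approx(kn$x, kn$y, xout = mid[ii], rule = 2)$y
    }
    strand <- ifelse(stats::runif(n) < (1 + rfdv) / 2, "-", "+")
    data.table::data.table(chrom = chrom, start = as.integer(start),
                           end = as.integer(start + rl),
                           name = paste0("ok_", seq_len(n)), score = 0,
                           strand = strand)
  })
}

#' Generate a UV-signature mutation catalog
#'
#' C>T mutations (and their strand-mirrored G>A images) are placed on
#' TC/CC dipyrimidine contexts with probability proportional to damage
#' propensity times the planted strand excess times the fraction of damage
#' left unrepaired, `1 - repair fraction` - the damage x (1 - repair)
#' mutagenesis model. The planted strand excess is raised to the nearest
#' zone's efficiency, so more efficient origins carry stronger mutational
#' asymmetry. Output is forward-strand, 1-based, ICGC-style.
#'
#' @param world A `"synthetic_world"`.
#' @param n Number of mutations.
#' @param n_samples Number of synthetic tumor sample ids (default 20).
#' @return data.table: chrom, position (1-based), ref, alt, sample.
#' @export
generate_mutations <- function(world, n, n_samples = 20L) {
  spec <- world$spec
  st <- world$sites[world$sites$site %in% c("TC", "CC")]
  ctx <- .zone_context(world, st$chrom, st$p)
  lag <- .lagging_sign(ctx$side, st$strand)
  delta <- unname(spec$damage_lagging_excess[ctx$zone_domain])
  delta[is.na(delta) | lag == 0L] <- 1
  delta <- delta^ifelse(is.na(ctx$zone_efficiency), 1, ctx$zone_efficiency)
  w <- st$w * sqrt(delta)^lag * (1 - .repair_fraction(world, ctx, lag))
  .with_seed(spec$seed + 611L, {
    idx <- sample.int(nrow(st), n, replace = TRUE, prob = w)
    sel <- st[idx]
    # plus-strand context: mutated C is the 3' base (forward p+1);
    # minus-strand context (forward GA/GG at p): mutated base is forward G at p
    pos0 <- ifelse(sel$strand == "+", sel$p + 1L, sel$p)
    data.table::data.table(
      chrom = sel$chrom, position = pos0 + 1L,
      ref = ifelse(sel$strand == "+", "C", "G"),
      alt = ifelse(sel$strand == "+", "T", "A"),
      sample = paste0("S", sample.int(n_samples, n, TRUE)))
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("synthetic_world:", length(x$genome$lengths), "chromosomes,",
      nrow(x$truth$izs), "planted zones,",
      nrow(x$truth$domains), "planted domains; seed", x$spec$seed, "\n")
  invisible(x)
}
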