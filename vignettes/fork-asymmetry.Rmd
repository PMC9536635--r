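---
title: "Strand asymmetry of UV damage, repair and mutation around replication initiation zones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand asymmetry of UV damage, repair and mutation around replication initiation zones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(forkrepair)
```

# Scope and model

`forkrepair` analyzes how the replication program shapes UV damage
formation, nucleotide excision repair, and C→T mutagenesis, strand by
strand. Its core objects are:

* a **window grid**: regions (initiation zones, domains, TSS/TES points)
  expanded symmetrically about their integer midpoint to `a × b` bases
  (`a` = window length, `b` = window count) with truncating integer
  arithmetic, then tiled into windows numbered left to right. Regions
  whose expanded spans overlap another span, or leave the chromosome,
  are dropped — both members of an overlapping pair, because two
  overlapping meta-profile regions would let opposing strand signals
  cancel;
* a **signal matrix**: region × window × strand read counts of one
  library, counted with the ≥1-bp-overlap rule (a read crossing a window
  boundary increments both windows) plus the library size for RPKM;
* **profiles** derived from signal matrices: the repair rate
  `RR = XR/Damage` on RPKM scale, the simulation-normalized
  `nRR = log2((XR_real/XR_sim) / (Dmg_real/Dmg_sim))`, accumulated
  repair `(D_0h − D_2h)/D_0h`, log2 single-library signals, and
  context-normalized mutation rates.

All coordinates are 0-based half-open (BED convention); Bioconductor's
1-based containers are used internally for interval machinery and
converted at the boundary.

## Damage-site geometry

During Damage-seq library preparation the polymerase stops directly
before the adduct, so the lesion dinucleotide sits two bases upstream of
the read's 5′ end. `locate_damage_sites()` converts a plus-strand read
`[s, e)` into the 10-base window `[s−6, s+4)` whose read-orientation
positions 5–6 are the lesion `[s−2, s)`; a minus-strand read `[s, e)`
maps to `[e−4, e+6)` with the lesion at `[e, e+2)`, reported
reverse-complemented. The minus-strand arithmetic is locked by an
enumeration oracle in the test suite because coordinate mirroring is the
easiest place for an off-by-one to hide. Records whose site is not
TT/TC/CT/CC cannot carry a UV photoproduct and are removed.

XR-seq excision fragments (22–30 nt, median 26) carry their lesion 5–6
nt from the 3′ end; `positional_dinucleotide_profile()` makes that
visible as a TT/TC enrichment peak at read positions `L−5..L−4`.

## Deduplication

Reads sharing (chromosome, start, end, strand) collapse to one. The
strand is part of the key: every downstream analysis is strand-resolved,
and a position-only key would merge independent lesions on opposite
strands. The test suite quantifies the difference against a
position-only variant on a toy set.

## The context-matched simulator

Sequence context drives damage formation, so raw XR/Damage ratios mix
repair with composition. The normalization divides each real library by
a simulated library with the same per-position nucleotide frequencies
and length distribution, placed randomly on the genome. The simulator is
a rejection sampler: a candidate of model-drawn length is placed
uniformly (uniform strand), and accepted with probability proportional
to `prod_p f_p(x_p)/bg(x_p)` over its bases, normalized by the maximum
attainable product. The `bg` correction (strand-symmetrized global base
composition) makes accepted marginals match the profile rather than the
profile tilted by genome composition; it is exact for a compositionally
homogeneous genome. Because real genomes (and the synthetic one) are
heterogeneous, a pilot round measures the residual per-position mismatch
and corrects the weights once (`calibrate = TRUE`); with 50,000 reads
the per-position total-variation distance to the source profile stays
within 0.02.

An anchor constraint rejects candidates without a dipyrimidine at a
fixed read position — position 5 of the 10-base damage windows, or
position `L−5` (counted from the 3′ end, `position = -5`) for excision
fragments. Anchoring is ON for Damage-seq simulation, mirroring the
assay's hard constraint; for XR-seq the empirical profile is already so
sharply peaked at the lesion position that the anchor is effectively
implied, and the pipeline turns it on for symmetry. If the acceptance
rate falls below `min_accept = 1e-4` after a burn-in, the sampler stops
with an error instead of looping — a profile that incompatible with the
sampling space indicates a mismatched genome.

Simulating from sequenced input DNA instead of the whole genome is
supported (`sampling_space = "background_reads"`: every simulated read
is contained in a supplied background fragment, on its strand); both
modes exist because published descriptions of this normalization step
are ambiguous about the sampling space.

## Replication timing and domains

EdU-seq reads from early- and late-S cells are counted into 50-kb bins
by read midpoint, each library depth-normalized to reads per million,
and combined as `log2((early + ψ)/(late + ψ))` with pseudocount ψ = 1.
The pseudocount regularizes empty bins; at realistic coverage its effect
is negligible, and the identity "early = 2 × late gives log2FC = 1"
holds only in that deep-coverage limit (the formula, not the identity,
is the contract). Depth normalization is applied even though a ratio of
raw counts would often be close, because without it the track conflates
sequencing depth with timing.

Domains are called by smoothing the track (centered moving average, 10
bins), thresholding at 0 (positive = ERD, negative = LRD; exact zeros
are left unlabeled), bridging same-label runs separated by at most 1
bin, and discarding runs shorter than 4 bins (200 kb). These defaults
are exposed because the segmentation granularity is a genuine analysis
choice; the threshold–merge–filter scheme is the simplest two-state
segmentation of a signed log-ratio and recovers planted boundaries
within one bin at noise σ = 0.3 on a ±1 step.

## Initiation zones from OK-seq

Okazaki fragments map to the lagging nascent strand, so the binned
replication fork directionality `RFD = (C − W)/(C + W)` ascends across
an initiation zone. The caller smooths the RFD track (5 bins of 1 kb by
default), simplifies its local extrema by persistence pruning — adjacent
extrema pairs with amplitude difference below `min_delta/2` are noise
wiggles and are removed — and reports every remaining ascent with total
rise ≥ `min_delta` (0.5) and extent ≤ `max_extent` (150 kb). Flat
shoulders are trimmed to the stretch carrying the middle 80 % of the
rise before the extent test, the center is the mid-rise crossing
(averaged from both directions), and the score is the adjusted slope,
rise per kb. Persistence pruning rather than strict monotonicity is what
makes the caller robust to counting noise: a strictly ascending-run
definition fragments real ascents at realistic OK-seq depth.

Fork polarity around a zone center follows the standard convention:
right of the center the fork moves rightward, the plus strand serves as
the lagging-strand template and the minus strand as the leading-strand
template; the left side mirrors this. Asymmetry statistics exclude
windows within 2 kb of the center, where the polarity assignment is
ambiguous.

Quartiles of the slope score put ties in the lower quartile; common
zones across samples are those overlapping (≥1 bp) at least one zone in
every other sample.

## Repair-rate statistics

Undefined cells (zero damage; any zero among the four nRR inputs)
propagate as missing and every aggregation runs over defined cells with
counts reported — zero-filling would bias log ratios. nRR is exactly
invariant to each library's sequencing depth because every RPKM
normalizes by its own library size.

Strand asymmetry pairs the plus- and minus-strand values of the same
window, splits pairs by replicating side, applies a paired Wilcoxon
signed-rank test per side (suppressed below 5 pairs), and summarizes the
median leading-minus-lagging difference over all pairs. Ratio-scale
profiles are log2-transformed first so that medians are log2
asymmetries.

Accumulated repair compares damage maps at 0 h and 2 h on a common
scale: the 2 h generator draws lesions at the 0 h rate and thins each by
its survival probability, and both signal matrices are given the same
`library_size`, so `(D0 − D2)/D0` estimates the repaired fraction
directly. Normalizing each library to its own depth would cancel a
spatially uniform repair signal — only relative inputs are meaningful
there.

For the chromatin-state analysis, state segments are assigned to the
domain holding ≥50 % of their length (ties to the larger overlap, then
leftmost), per-segment mean profile values are compared between phases
with an unpaired Wilcoxon test (≥5 segments per side), and the 2×2
tables for the odds-ratio/Breslow–Day analysis dichotomize each segment
as better repaired in early or late phase (ties excluded), crossed with
ERD/LRD. No multiple-testing correction is applied; tests are reported
per comparison.

## k-mer skew and net T

All mono- to pentanucleotides are counted on the forward strand of each
flanking window with overlapping counts (consistent with how adjacent
lesion sites are counted); the minus-strand percentage of a k-mer equals
the forward percentage of its reverse complement, so one representative
per complement pair is kept — the lexicographically smaller, palindromes
once. Net statistics (`net_T = #T − #A`, `net_TT = #TT − #AA`,
`net_TC`, `net_C`, `net_CC`, dinucleotides overlapping) are exactly
antisymmetric under reverse complementation, which the suite checks over
all 4^5 pentamers. The lagging/leading occurrence ratio of a k-mer on
the right-replicating side is `pct(x)/pct(revcomp(x))`, reciprocal on
the left; k-mers absent from the leading strand are excluded and
tallied.

T-rich/A-rich genome slices divide the forward-strand T% by A% per 50-kb
slice and take the top/bottom quartile of that "relative T" — high
values mean the forward strand carries the Ts, low values the reverse
strand does.

## Mutations

The catalog format is a minimal TSV (chrom, 1-based position, ref, alt,
sample), converted to 0-based internally — full VCF machinery is not
needed for single-base substitutions. A C>T at `p` with forward T (C) at
`p−1` is a plus-strand TC>TT (CC>CT); G>A at `p` with forward A (G) at
`p+1` is the reverse-strand image. MC divides signature-mutation counts
by TC+CC context counts per window and strand (minus-strand contexts are
forward GA+GG). Recurrent sites count once per sample occurrence by
default — aggregation across tumors without collapsing is the
conservative reading of how catalogs are pooled — with
`collapse_recurrent = TRUE` provided. Quartile strand differences are
aggregated per replicating side before taking absolute values, because
the lagging strand switches identity at the zone center and a whole-zone
difference would cancel by construction.

## Breslow–Day with Tarone correction

The expected a-cell under the Mantel–Haenszel common OR is the
margin-respecting root of the conditional quadratic; the statistic sums
`(a_k − E_k)²/V_k` and the Tarone term subtracts
`(Σ(a_k − E_k))²/ΣV_k`, referred to χ²(K−1). Strata with an empty row or
column are excluded (df reduced, warning). Monte-Carlo calibration in
the suite (K = 8, n = 200 per stratum, 2,000 replicates) keeps the
empirical type-I error within [0.03, 0.07] at α = 0.05.

# The synthetic study system

`synthetic_spec()` defines a deterministic world; `generate_genome()`
returns the genome plus a ground-truth manifest (domains, zones with
efficiencies, genes, states, the true RFD curve) that recovery tests
consume — no test reads generator internals.

Defaults and why:

* **two 2-Mb chromosomes**, each half ERD / half LRD, four zones per
  domain (so zone-score quartiles hold equally many zones from every
  domain block); full suites run in minutes on one CPU at this scale.
* **AT content** 54 % (ERD) / 62 % (LRD) — the domain-level composition
  contrast reported for real initiation zones.
* **T-skew**: within 50 kb of a zone center the lagging-strand side
  gains T at the expense of A (+4 % ERD, +8 % LRD of probability mass) —
  the qualitative T-track asymmetry, stronger in LRDs.
* **zone efficiencies** spread over 0.4–0.9 within every domain block
  (tiny per-block offsets keep them distinct), driving both the planted
  RFD amplitude and, raised to the efficiency, the per-zone mutational
  strand excess — so higher-scoring zones carry stronger asymmetry.
* **damage propensities** TT 0.4, TC = CT 0.25, CC 0.1 — the
  CPD-like dipyrimidine preference; a TC-dominant vector emulates
  (6–4)PP libraries. These are configuration, not claims.
* **excision lengths** 22–30 nt with mode (and median) 26.
* **repair field**: baseline 2-h repaired fraction 0.5; a
  leading:lagging ratio knob and an early/late phase-boost knob (log2FC
  in ERDs, mirrored in LRDs) act as symmetric square-root factors within
  the zone-influence window.
* **mutations** are placed on TC/CC contexts proportional to damage
  propensity × strand excess × (1 − repair fraction) — the
  damage × (1 − repair) mutagenesis model, forward-strand recorded.
* **genes** sit midway between neighbouring zones, outside every
  zone-influence window, so intergenic filtering removes mutations
  uniformly across zones rather than sculpting spurious quartile trends;
  **states** tile the genome in 25-kb cycles of 8 labels.

What the generator does *not* emulate: real coverage heterogeneity
(mappability, GC bias, copy number), fragment-size distributions,
transcription-coupled repair, replication-timing gradients within
domains, mutation burden differences between tumors, and linkage between
neighbouring lesions. Passing recovery tests therefore demonstrates that
the pipeline measures what was planted at realistic counting noise — not
that real libraries are free of the biases the generator omits.

# Recovery experiments and problem sizes

The acceptance suite runs, at fixed seeds:

* exact brute-force equivalence and reverse-complement/normalization
  identities on ≤10-kb toys;
* the simulator contract at 50,000 reads (per-position TV ≤ 0.02;
  anchored mode 100 % dipyrimidine);
* segmentation recovery — domain boundaries within 1 bin at σ = 0.3,
  zone centers within 2 bins and Spearman(score, efficiency) ≥ 0.9 from
  500,000 Okazaki fragments on the 4-Mb system;
* parameter recovery — a planted leading:lagging repair ratio of 1.2
  recovered as log2 asymmetry 0.263 ± 0.05 (5 × 10⁵-read libraries,
  1-kb × 100 window grids), a planted phase boost of 0.3 recovered
  ± 0.05 per domain, and an all-knobs-zero negative control with
  |median asymmetry| < 0.02 over ~2,300 window pairs;
* end-to-end sign consistency over 20 seeds on 2-Mb worlds with a
  lagging damage excess (1.3) and leading repair excess (1.2) planted in
  LRD zones: lagging-biased damage, leading-biased nRR, lagging-biased
  MC in ≥95 % of seeds. The effect knobs are the planted conditions;
  T-skew is held at zero there so the experiment isolates the two
  planted asymmetries from composition effects that the simulator
  normalization can only partially cancel at these library sizes.

The recovery-effect sizes (e.g. the lagging excess of 3 in the
mutation-quartile experiment) are chosen so the planted trend dominates
per-zone context sampling noise at simulation scale; they are experiment
designs, not estimates of real effect magnitudes.

# Known limitations

* The initiation-zone caller is a re-specification (ascent segmentation
  with persistence pruning), not a reimplementation of any published
  OK-seq caller; its parameters are exposed and its contract is defined
  by planted recovery.
* "Adjusted slope" is implemented as rise/extent-in-kb; other
  definitions (regression slope over the ascent) would order zones
  nearly identically but are not provided.
* The simulator matches per-position marginals, not joint k-mer
  statistics; dinucleotide-level context beyond the anchored lesion is
  matched only to the extent the marginals imply it.
* Domain-level fold changes on real data depend on coverage and
  composition structure the generator does not model; on synthetic data
  they recover planted values, which is the strongest claim made here.
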