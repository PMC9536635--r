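#!/usr/bin/env Rscript
# Step 1: build the synthetic study system -- a 4-Mb two-chromosome genome
# with planted ERD/LRD replication domains, replication initiation zones,
# lagging-strand T-skew, genes and chromatin-like states -- and write every
# input the downstream steps consume (FASTA, BED6 read sets, mutation TSV,
# ground-truth BEDs).

suppressPackageStartupMessages({library(forkrepair); library(data.table)})

seed <- 42L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- synthetic_spec(seed = seed,
                       damage_lagging_excess = c(ERD = 1, LRD = 1.3),
                       repair_leading_excess = c(ERD = 1, LRD = 1.2),
                       phase_boost = 0.3)
world <- generate_genome(spec)

write_genome_fasta(world$genome, file.path(out, "genome.fa"),
                   file.path(out, "genome.chrom.sizes"))
write_bed6(world$truth$izs[, .(chrom, start, end, name,
                               score = efficiency, strand = ".")],
           file.path(out, "truth_initiation_zones.bed"))
write_bed6(world$truth$domains[, .(chrom, start, end, name = label,
                                   score = 0, strand = ".")],
           file.path(out, "truth_domains.bed"))
write_bed6(world$truth$genes, file.path(out, "genes.bed"))
fwrite(world$truth$states, file.path(out, "states.tsv"), sep = "\t")

libs <- list(
  damage_0h = generate_damage_reads(world, 5e5, "0h"),
  damage_2h = generate_damage_reads(world, 5e5, "2h"),
  xr = generate_xr_reads(world, 5e5),
  xr_early = generate_xr_reads(world, 4e5, phase = "early"),
  xr_late = generate_xr_reads(world, 4e5, phase = "late"),
  edu_early = generate_edu_reads(world, "early", 1e5),
  edu_late = generate_edu_reads(world, "late", 1e5),
  okseq = generate_okseq_reads(world, 5e5))
for (nm in names(libs))
  write_bed6(libs[[nm]], file.path(out, paste0(nm, ".bed")))
fwrite(generate_mutations(world, 1e5),
       file.path(out, "mutations.tsv"), sep = "\t")

message("Simulated study system written to ", out, ": ",
        paste(sprintf("%s=%d reads", names(libs),
                      vapply(libs, nrow, integer(1))), collapse = ", "),
        "; planted ", nrow(world$truth$izs), " zones in ",
        nrow(world$truth$domains), " domains (seed ", seed, ").")
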