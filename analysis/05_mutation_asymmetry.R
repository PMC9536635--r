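#!/usr/bin/env Rscript
# Step 5: melanoma-style mutation analysis -- UV-signature (TC>TT, CC>CT)
# classification with strand assignment, intergenic context-normalized
# mutation counts (MC) around initiation zones, and the absolute strand
# difference by zone-score quartile and replication domain.

suppressPackageStartupMessages({library(forkrepair); library(data.table)})

dat <- "results/data"; out <- "results"
genome <- read_genome_fasta(file.path(dat, "genome.fa"))
genes <- read_bed6(file.path(dat, "genes.bed"))
izs <- fread(file.path(out, "initiation_zones.tsv"))

mut <- read_mutation_tsv(file.path(dat, "mutations.tsv"))
mut <- filter_common_chromosomes(mut, genome)
cl <- classify_uv_mutations(mut, genome)
fwrite(cl[, .N, by = .(class, strand)],
       file.path(out, "mutation_classes.tsv"), sep = "\t")

regs <- izs[!is.na(domain),
            .(chrom, start = as.integer(center - 500),
              end = as.integer(center + 500), name, strand = ".")]
grid <- make_centered_windows(regs, 1000L, 40L, genome)
mc <- normalized_mutation_counts(cl, grid, genome, genes = genes)
fwrite(mc, file.path(out, "mutation_mc_long.tsv"), sep = "\t")

quart <- izs$quartile[match(grid$regions$name, izs$name)]
doms <- izs$domain[match(grid$regions$name, izs$name)]
qsd <- quartile_strand_difference(mc, grid, quart, doms, min_flank = 2000L)
fwrite(qsd, file.path(out, "mutation_quartile_differences.tsv"), sep = "\t")

lrd <- qsd[domain == "LRD"][order(quartile)]
message("Classified ", sum(cl$class != "other"), "/", nrow(cl),
        " mutations as UV signature. LRD absolute strand differences by ",
        "score quartile: ", paste(lrd$abs_diff, collapse = ", "),
        " (Spearman ",
        round(cor(lrd$quartile, lrd$abs_diff, method = "spearman"), 2),
        "); ERD: ",
        paste(qsd[domain == "ERD"][order(quartile)]$abs_diff, collapse = ", "),
        ".")
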