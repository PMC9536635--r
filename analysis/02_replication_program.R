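#!/usr/bin/env Rscript
# Step 2: reconstruct the replication program from reads alone -- the
# early/late timing track and ERD/LRD domains from EdU-seq, and the RFD
# track, initiation zones, slope scores and quartiles from OK-seq -- then
# compare with the planted truth.

suppressPackageStartupMessages({library(forkrepair); library(data.table)})

dat <- "results/data"; out <- "results"
genome <- read_genome_fasta(file.path(dat, "genome.fa"))
truth_iz <- read_bed6(file.path(dat, "truth_initiation_zones.bed"))
truth_dom <- read_bed6(file.path(dat, "truth_domains.bed"))

track <- compute_timing_track(read_bed6(file.path(dat, "edu_early.bed")),
                              read_bed6(file.path(dat, "edu_late.bed")),
                              genome, bin_size = 50000L)
write_bedgraph(track, file.path(out, "timing_track.bedgraph"), "ratio")
domains <- call_domains(track)
write_bed6(domains[, .(chrom, start, end, name = label,
                       score = round(mean_ratio, 3), strand = ".")],
           file.path(out, "replication_domains.bed"))

rfd <- compute_rfd(read_bed6(file.path(dat, "okseq.bed")), genome, 1000L)
write_bedgraph(rfd, file.path(out, "rfd_track.bedgraph"), "rfd")
izs <- call_initiation_zones(rfd)
izs <- assign_to_domains(izs, domains[, .(chrom, start, end, label)])
izs <- quartile_by_score(izs)
fwrite(izs, file.path(out, "initiation_zones.tsv"), sep = "\t")

m <- merge(izs, truth_iz[, .(chrom, tcenter = (start + end) / 2,
                             efficiency = score)],
           by = "chrom", allow.cartesian = TRUE)
best <- m[, .SD[which.min(abs(center - tcenter))], by = .(chrom, tcenter)]
message("Called ", nrow(domains), " replication domains (truth ",
        nrow(truth_dom), ") and ", nrow(izs), " initiation zones (truth ",
        nrow(truth_iz), "); mean center error ",
        round(mean(abs(best$center - best$tcenter)) / 1000, 2),
        " kb; Spearman(score, planted efficiency) = ",
        round(cor(best$score, best$efficiency, method = "spearman"), 3), ".")
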