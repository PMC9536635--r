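Package: forkrepair
Title: Strand-Resolved UV Damage, Excision Repair and Mutation Asymmetry
    Around Replication Initiation Zones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A strand-aware analysis pipeline for UV damage formation and
    nucleotide excision repair in the context of DNA replication. Processes
    aligned Damage-seq, XR-seq, EdU-seq and OK-seq reads (BED6) into
    damage-site maps, repair-rate and simulation-normalized repair-rate
    profiles, replication-timing domains (ERD/LRD), OK-seq
    replication-fork-directionality initiation zones, k-mer strand-skew
    (net T) statistics, and strand-resolved UV-signature mutation rates
    around initiation zones. Includes a sequence-context-matched read
    simulator, odds-ratio and Breslow-Day/Tarone homogeneity tests, and a
    fully deterministic synthetic-data generator with ground-truth
    manifests so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
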