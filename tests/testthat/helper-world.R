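# shared fixtures: built in code, cached per test run

.world_cache <- new.env(parent = emptyenv())

# a compact two-chromosome study system for unit tests
small_spec <- function(seed = 1L, ...) {
  synthetic_spec(seed = seed,
                 chrom_lengths = c(chrA = 4e5, chrB = 4e5),
                 iz_per_domain = 2L,
                 skew_halfwidth = 20000L,
                 n_genes_per_chrom = 3L,
                 gene_length = 20000L,
                 ...)
}

cached_world <- function(key, spec) {
  if (!exists(key, envir = .world_cache))
    assign(key, generate_genome(spec), envir = .world_cache)
  get(key, envir = .world_cache)
}

default_world <- function() cached_world("default", small_spec(seed = 1L))

# deterministic toy genome from explicit sequences
toy_genome <- function(...) {
  genome(Biostrings::DNAStringSet(c(...)))
}

# a repeating-pattern 10-kb chromosome (alphabet-rich, N-free)
pattern_genome <- function(n = 2500L, pattern = "ACGT", name = "chrT") {
  toy_genome(stats::setNames(paste(rep(pattern, n), collapse = ""), name))
}

iz_regions <- function(world, width = 1000L) {
  izs <- world$truth$izs
  data.table::data.table(chrom = izs$chrom,
                         start = as.integer(izs$center - width %/% 2L),
                         end = as.integer(izs$center + width %/% 2L),
                         name = izs$name, strand = ".")
}

dipyrimidines <- c("TT", "TC", "CT", "CC")
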