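suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

# explicit bindings so the constructors resolve regardless of how the test
# environment's lookup chain is rooted (installed package vs load_all)
GRanges <- GenomicRanges::GRanges
IRanges <- IRanges::IRanges
DNAString <- Biostrings::DNAString
DNAStringSet <- Biostrings::DNAStringSet
reverseComplement <- Biostrings::reverseComplement

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# one shared small simulated dataset per test run (cached)
.sim_cache <- new.env(parent = emptyenv())
shared_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    cfg <- sim_config(seed = 7, chrom_lengths = c(chrS1 = 200000L),
                      n_genes = 20)
    .sim_cache$sim <- simulate_dataset(cfg)
  }
  .sim_cache$sim
}

# a flat coverage track over the given sizes
flat_track <- function(sizes, value = 1, stranded = FALSE) {
  vecs <- lapply(sizes, function(n) rep(value, n))
  if (!stranded) return(coverage_track(vecs))
  coverage_track(list("+" = vecs, "-" = vecs), stranded = TRUE)
}

gr1 <- function(chrom, start, end, strand = "*", ...) {
  GRanges(chrom, IRanges(start, end), strand = strand, ...)
}
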