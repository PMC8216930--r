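# Shared fixtures: synthetic replicas of the three packaged skipper
# architectures (cached per test file) and small hand-built toys.

.replica_cache <- new.env(parent = emptyenv())

replica <- function(species, seed = 1) {
  key <- paste0(species, "_", seed)
  if (is.null(.replica_cache[[key]]))
    .replica_cache[[key]] <- replicate_architecture(species, seed = seed)
  .replica_cache[[key]]
}

all_species <- c("ampittia_virgata", "halpe_nephele", "onryza_maga")

# a minimal consistent annotation: two PCGs flanking a tRNA, plus NCR
toy_features <- function() {
  data.frame(
    gene  = c("nad2", "trnW", "atp6", "NCR"),
    class = c("PCG", "tRNA", "PCG", "NCR"),
    from  = c(1L, 31L, 41L, 71L),
    to    = c(30L, 40L, 64L, 100L),
    strand = c("J", "J", "N", "J"),
    start_codon = c("ATG", NA, "ATG", NA),
    stop_codon  = c("TAA", NA, "TAA", NA),
    stringsAsFactors = FALSE)
}

random_dna <- function(n, at = 0.8) {
  paste0(sample(c("A", "T", "G", "C"), n, replace = TRUE,
                prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
         collapse = "")
}
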