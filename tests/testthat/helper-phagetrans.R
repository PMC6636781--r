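# shared fixture builders: everything is generated in code at test time

# a temperate transducing phage with small, fast parameters
tiny_phage <- function(...) {
  args <- modifyList(list(lifestyle = "temperate", p_GT = 0.3, burst_size = 10L,
                          headful = 3L, prophage_span = 4L, id = 1L), list(...))
  do.call(phage_genotype, args)
}

# a genome of L slots with a single resistance gene at `marker_at`
marker_genome <- function(L = 20L, drug = "CAM", active = TRUE,
                          marker_at = 11L, provenance = "donor") {
  bacterial_genome(L, genes("resistance", drug = drug, active = active,
                            provenance = provenance), at = marker_at)
}

# brute-force oracle: probability that a headful window of `h` consecutive
# non-prophage slots (uniform circular start) contains the marker, by
# exhaustive enumeration of every start position
capture_prob_oracle <- function(genome, h) {
  np <- genome$loci[genome$loci >= 0L]
  n <- length(np)
  hits <- vapply(seq_len(n), function(s) {
    idx <- ((s - 1L + seq_len(h) - 1L) %% n) + 1L
    any(np[idx] > 0L)
  }, logical(1))
  mean(hits)
}

# small single-strain, single-phase configuration for engine tests
tiny_config <- function(width = 12L, height = 12L, n = 20L, moi = 0,
                        lysogen = FALSE, alpha = 1e5, ...) {
  phage <- phage_genotype("temperate", p_GT = 0.3, burst_size = 10L,
                          headful = 5L, alpha = alpha, prophage_span = 5L,
                          id = 1L)
  st <- strain_spec("A", L = 50L, n_essential = 10L, n_accessory = 5L,
                    markers = data.frame(drug = "CAM", active = TRUE),
                    lysogen_of = if (lysogen) phage else NULL)
  sim_config(strains = list(st), genotypes = list(phage),
             populations = list(list(strain = "A", n = n)),
             inoculum = if (moi > 0) list(genotype = 1L, n = as.integer(moi * n)),
             width = width, height = height, ...)
}
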