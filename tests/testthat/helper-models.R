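# shared fixtures, built in code

# diagnostic panel: pools fixed for alternative alleles at every locus
fixed_freq_model <- function(L = 11) {
  allele_freq_model(lapply(seq_len(L), function(l) c("100" = 1)),
                    lapply(seq_len(L), function(l) c("200" = 1)),
                    loci = paste0("Loc", seq_len(L)))
}

# fast MCMC settings for unit-level checks (acceptance tests use the desk
# preset proper)
fast_settings <- function(seed = 1, replicates = 1)
  mcmc_settings("desk", burnin = 500, sweeps = 5000,
                replicates = replicates, seed = seed)

# tiny deterministic dataset: 2 samples x 2 loci
tiny_dataset <- function() {
  microsat_dataset(a1 = rbind(c("120", "100"), c("140", NA)),
                   a2 = rbind(c("140", "100"), c("140", NA)),
                   loci = c("LocA", "LocB"),
                   meta = data.frame(sample_id = c("s1", "s2"),
                                     location = c("SY1", "SY1"),
                                     species = c("fabalis", "obtusata")))
}

# truth labels as pure/hybrid vocabulary
truth_genetic <- function(truth)
  stats::setNames(ifelse(truth$true_class == "F", "pure_fab",
                         ifelse(truth$true_class == "O", "pure_obt",
                                "hybrid")),
                  truth$sample_id)
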