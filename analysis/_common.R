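# Shared settings for the analysis workflow. Every script sources this
# file, so the herd is identical (and bit-reproducible) across stages.
library(gesskit)

RESULTS <- file.path("results")
dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)

MASTER_SEED <- 20210903L

# The demonstration herd: ~2,000 recorded cows over two cohorts bred from
# a founder population, 60 contemporary service sires with skewed usage,
# gestation length as the worked trait (its reference components have the
# largest signal), and a 3,000-SNP panel for the association stage.
herd_config <- function(trait = "GL", seed = MASTER_SEED) {
  sim_config(trait = trait,
             n_founders = 200L, n_generations = 3L,
             cows_per_generation = c(500L, 900L, 900L),
             male_frac = c(0.3, 0, 0),
             n_service_sires = 120L, sire_skew = 0.5, n_parities = 3L,
             n_herds = 8L, n_years = 4L,
             n_snps = 3000L, seed = seed)
}

the_herd <- function(trait = "GL", genotypes = FALSE) {
  simulate_herd(herd_config(trait), genotypes = genotypes)
}
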