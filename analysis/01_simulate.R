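#!/usr/bin/env Rscript
# Stage 1 - simulate the demonstration herd.
#
# Generates the pedigree, correlated sire/dam breeding values, gestation-
# length records and the SNP panel, and writes them as plain-text files.
# The herd mimics the recording structure of a commercial dairy
# population: repeated parities per cow, a small heavily-used service
# sire battery, and herd-year-month contemporary groups.

source(file.path("analysis", "_common.R"))

herd <- the_herd(genotypes = TRUE)
out <- file.path(RESULTS, "sim")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

write_pedigree(herd$pedigree, file.path(out, "pedigree.csv"))
utils::write.csv(herd$records, file.path(out, "records.csv"),
                 row.names = FALSE)
write_plink(herd$geno, file.path(out, "genotypes"))
write_vcf(herd$geno, file.path(out, "genotypes.vcf"))
write_truth_json(herd$truth, file.path(out, "truth.json"))

load <- table(herd$records$sire)
cat(sprintf(paste0(
  "Simulated %d gestation-length records on %d cows.\n",
  "Pedigree: %d animals; service sires: %d (services per sire: mean %.0f,",
  " max %.0f - usage is heavily skewed, as in real insemination logs).\n",
  "Genotypes: %d animals x %d SNPs written as PLINK text and VCF.\n"),
  nrow(herd$records), length(unique(herd$records$cow)),
  nrow(herd$pedigree), length(load), mean(load), max(load),
  nrow(herd$geno$genotypes), ncol(herd$geno$genotypes)))
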