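#!/usr/bin/env Rscript
# Stage 4 - breeding values, reliabilities, de-regressed proofs.
#
# Solves the mixed-model equations at the converged components, computes
# exact reliabilities from the inverse coefficient matrix, de-regresses
# the service-sire and dam EBVs, and illustrates the reliability-weighted
# (Calo-type) approximate correlation between two EBV sets.

source(file.path("analysis", "_common.R"))

herd <- the_herd()
records <- utils::read.csv(file.path(RESULTS, "records_edited.csv"))
fit <- reml_estimate(records, trait_model_spec("GL"), herd$pedigree)
sol <- solve_blup(fit)

sires <- colnames(fit$design$W1)
cows <- colnames(fit$design$W2)
rel_ss <- reliability(fit, sires, "GESS")
rel_d <- reliability(fit, cows, "GED")
h2 <- heritability(fit$vc)
drp_ss <- deregress(sol$u_ss[sires], rel_ss, herd$pedigree,
                    h2 = h2[["h2_ss"]])
drp_d <- deregress(sol$u_d[cows], rel_d, herd$pedigree, h2 = h2[["h2_d"]])
utils::write.csv(rbind(cbind(effect = "GESS", drp_ss),
                       cbind(effect = "GED", drp_d)),
                 file.path(RESULTS, "ebv_drp.csv"), row.names = FALSE)

cat(sprintf(paste0(
  "Service-sire EBVs: %d bulls, reliability %.2f-%.2f (median %.2f); %d",
  " pass the 10%% accuracy filter for the association stage.\n"),
  length(sires), min(rel_ss), max(rel_ss), stats::median(rel_ss),
  sum(drp_ss$included)))
cat(sprintf("EBV vs true breeding value correlation: %.3f (GESS), %.3f (GED).\n",
            cor(sol$u_ss[sires], herd$bv[sires, "u_ss"]),
            cor(sol$u_d[cows], herd$bv[cows, "u_d"])))

## Calo-type correlation between the sire EBV sets of the two effects
cal <- approx_genetic_correlation(sol$u_ss[sires], rel_ss,
                                  sol$u_d[sires],
                                  reliability(fit, sires, "GED"))
cat(sprintf(paste0(
  "Approximate genetic correlation between GESS and GED sire EBVs: %.3f",
  " +/- %.3f (raw Pearson %.3f x reliability factor %.3f).\n"),
  cal$r, cal$se, cal$r_raw, cal$factor))
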