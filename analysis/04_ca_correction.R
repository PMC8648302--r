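#!/usr/bin/env Rscript
# Effect of relaxing the full-equilibrium assumption: apply the CA-limited
# correction (k_CA = 6.5 mol m-2 s-1 bar-1, the measured hydration rate) to
# the four genotype-level conductances and report the inflation factor; also
# demonstrate the direction property on simulated finite-kCA data.

library(mesoflux)
dir.create("results", showWarnings = FALSE)

gm_eq <- c(control = 0.42, line52 = 0.46, line44 = 0.55, line27 = 0.59)
gm_ca <- gm_ca_corrected(gm_eq, kCA = 6.5)
tab <- data.frame(genotype = names(gm_eq), gm_equilibrium = unname(gm_eq),
                  gm_ca_limited = unname(gm_ca),
                  fold = unname(gm_ca / gm_eq))
print(tab, row.names = FALSE)
cat(sprintf("\nMean fold-change %.3f; genotype ranking unchanged: %s\n",
            mean(tab$fold), identical(order(gm_ca), order(gm_eq))))

# direction property on synthetic data generated with finite CA
rec <- gen_isotope_records(0.42, theta_mode = "finite_kCA", kCA = 6.5,
                           cfg = sim_config(seed = 1, sigma_delta = 0))
eq <- estimate_gm(rec, mode = "equilibrium")$gm_mean
ca <- estimate_gm(rec, mode = "ca_limited", kCA = 6.5)$gm_mean
cat(sprintf("\nData generated at g_m = 0.42 with k_CA = 6.5:\n"))
cat(sprintf("  equilibrium-mode estimate %.4f (underestimates truth)\n", eq))
cat(sprintf("  ca_limited-mode estimate  %.4f (bias removed)\n", ca))
utils::write.csv(tab, "results/ca_correction.csv", row.names = FALSE)
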