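#!/usr/bin/env Rscript
# Consistency of the curve-fitting route with the closed-form slope relation:
# simulate stepwise CO2-response curves (0-1600 ppm) at known gm, fit the
# initial slope by OLS over Ci <= 60 ubar, and compare with the model.

library(mesoflux)
dir.create("results", showWarnings = FALSE)

p <- c4_params(Rd = 0, Rm = 0)
rows <- list()
for (gm in c(0.42, 0.59)) {
  noiseless <- fit_initial_slope(gen_aci(gm, p, cfg = sim_config(seed = 1,
                                                                 sigma_A = 0)),
                                 ci_max = 60)
  noisy <- vapply(1:100, function(s)
    fit_initial_slope(gen_aci(gm, p, cfg = sim_config(seed = s,
                                                      sigma_A = 0.3)))$slope,
    numeric(1))
  rows[[length(rows) + 1]] <- data.frame(
    gm = gm, slope_model = initial_slope_from_gm(gm),
    slope_noiseless = noiseless$slope,
    slope_noisy_mean = mean(noisy), slope_noisy_se = sd(noisy) / 10)
}
tab <- do.call(rbind, rows)
print(tab, row.names = FALSE)
cat(sprintf("\nNoiseless fit deviates from the closed form by %.2f%% (gm=0.42) and %.2f%% (gm=0.59)\n",
            100 * abs(tab$slope_noiseless[1] / tab$slope_model[1] - 1),
            100 * abs(tab$slope_noiseless[2] / tab$slope_model[2] - 1)))
cat("(small curvature bias of the finite fitting window).\n")
utils::write.csv(tab, "results/aci_slope_recovery.csv", row.names = FALSE)
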