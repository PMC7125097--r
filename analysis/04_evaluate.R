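#!/usr/bin/env Rscript
# Step 4 — cohort evaluation statistics and figures.
#
# Paired ROC of below- vs above-LLA per-animal index means (with DeLong
# comparisons of each wavelet/correlation pair), paired t-tests on the
# above-LLA index SDs, Pearson + Bland-Altman agreement of wavelet vs
# correlation ABPopt, and the discrimination table. Writes the table, a
# JSON results bundle, and the U-curve / Bland-Altman figures.

library(autoregwave)

seed <- 1L
out <- "results"
dir.create(file.path(out, "figures"), recursive = TRUE, showWarnings = FALSE)

co <- run_cohort(n_animals = 30L, seed = seed)
st <- co$stats

tab <- discrimination_table(st)
write.csv(tab, file.path(out, "discrimination_table.csv"), row.names = FALSE)
write_cohort_json(co, file.path(out, "cohort_results.json"))

cat("Discrimination of ABP below vs above the LLA (per-animal means):\n")
print(cbind(tab[, c("index", "auc", "cutoff")],
            p = signif(tab$p, 2)), row.names = FALSE)

cat("\nAbove-LLA index variability (SD), correlation vs wavelet:\n")
for (pr in names(st$sd_tests)) {
  t <- st$sd_tests[[pr]]
  cat(sprintf("  %-12s mean SD difference %+.3f (paired t p = %.3g)\n",
              pr, t$mean_diff, t$p))
}

cat("\nABPopt agreement (wavelet vs correlation):\n")
for (pr in names(st$abpopt_agreement)) {
  ag <- st$abpopt_agreement[[pr]]
  cat(sprintf("  %-12s r = %.2f, bias %+.1f mmHg, LOA [%.1f, %.1f]\n",
              pr, ag$r, ag$bias, ag$loa_lower, ag$loa_upper))
}

# figures: example U-curve per index, Bland-Altman per pair
an <- co$animals[[1]]
for (nm in INDEX_NAMES) {
  above <- an$sw[is.finite(an$sw$abp) & an$sw$abp > an$lla$lla, ]
  attr(above, "epoch_s") <- 10
  samples <- median_abp_epochs(above, an$indices[[nm]])
  curve <- bin_index_curve(samples)
  png(file.path(out, "figures", paste0("ucurve_", nm, ".png")), 600, 450)
  plot_u_curve(curve, main = paste(nm, "vs ABP (example animal)"))
  dev.off()
}
for (pr in INDEX_PAIRS) {
  png(file.path(out, "figures",
                paste0("bland_altman_", pr[1], "_", pr[2], ".png")), 600, 450)
  plot_bland_altman(st$abpopt_table[, pr[2]], st$abpopt_table[, pr[1]],
                    main = paste("ABPopt:", pr[2], "vs", pr[1]))
  dev.off()
}
cat("\nTable, JSON bundle and figures written under", out, "\n")
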