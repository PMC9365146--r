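#!/usr/bin/env Rscript
# Pooled and per-unit fits across governance levels, plus the ordered
# cross-level prediction checks.
#
# The original small-group / U.S.-state / country observation tables are
# not redistributable, so this driver runs the identical pipeline on
# synthetic stand-ins generated at the published operating points (see
# scenario_presets()). It writes, under results/pipeline/:
#   mean_best_parameters.csv  - mean best parameters per level (pooled)
#   per_unit_variance.csv     - cross-unit variance of per-unit fits
#   predictions.csv           - strict cross-level inequality checks
#   manifest.json             - seeds and config echo

suppressPackageStartupMessages(library(gpsafit))

res <- run_pipeline(
  "results/pipeline",
  presets = scenario_presets(noise_sd = 0.05, seed = 2026),
  cfg = fit_config(n_realizations = 30, seed = 2027),
  per_unit_cfg = fit_config(n_realizations = 5, seed = 2028))

cat("Mean best parameters (pooled fits, 30 restarts):\n")
print(as.data.frame(readr::read_csv("results/pipeline/mean_best_parameters.csv",
                                    show_col_types = FALSE)))
cat("\nCross-unit variance of per-unit best parameters:\n")
print(as.data.frame(readr::read_csv("results/pipeline/per_unit_variance.csv",
                                    show_col_types = FALSE)))
cat("\nOrdered predictions (small group vs country):\n")
print(as.data.frame(res$predictions))
cat(sprintf("\n%d of %d strict inequalities hold on this synthetic run.\n",
            sum(res$predictions$holds), nrow(res$predictions)))
cat("Restart means are reported, so weakly identified directions (the\n",
    "small-group E-alpha ridge) wander even though every restart reaches\n",
    "the same fit value; the per-unit variances mix real heterogeneity\n",
    "with one-observation non-identifiability.\n")
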