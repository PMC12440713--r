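#!/usr/bin/env Rscript
# Parameter-recovery study: fit the autoinduction NLME model to a
# synthetic cohort with the identifiability-oriented rich design
# (samples at 48, 168 and 672 h) and compare the estimates with the
# generating (published) values. Writes an estimates table with SE/RSE
# from the Fisher information matrix.

library(phenopk)

seed <- 20250903
out <- "results"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

truth <- pb_params()
data <- generate_tdm_dataset(demographics_config(n_subjects = 100),
                             sampling_design("rich"), truth, seed = seed)

cat("Fitting", length(unique(data$ID)), "dogs,",
    sum(data$EVID == 0), "observations ...\n")
fit <- fit_model(data)
print(fit)

rse <- compute_rse(fit, data)
gen <- unlist(truth[rse$parameter])
rse$generating_value <- as.numeric(gen)
write.csv(rse, file.path(out, "estimates.csv"), row.names = FALSE)

cat("\nEstimates written to results/estimates.csv\n")
print(rse, digits = 3, row.names = FALSE)
cat("\nOFV:", fit$ofv, "  BICc:", bicc(fit), "\n")
cat("\nNote: with every dog dosed at exactly 5 mg/kg and volume scaling",
    "\nlinearly with weight, all dogs share one dose schedule per litre,",
    "\nso CL/F and IC50 are informed only by covariate spread and the",
    "\nearly samples; their sampling uncertainty is accordingly wide",
    "\n(see the RSE column and the methods vignette).\n")
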