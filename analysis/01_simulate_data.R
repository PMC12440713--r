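#!/usr/bin/env Rscript
# Simulate the study cohorts: a training set of 100 dogs with sparse
# steady-state trough sampling (the clinical TDM pattern) and an
# independent validation set of 50 dogs, both from the published final
# model. Writes the event tables and a demographics summary.

library(phenopk)

seed <- 20250903
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

truth <- pb_params()

train <- generate_tdm_dataset(demographics_config(n_subjects = 100),
                              sampling_design("sparse"), truth,
                              seed = seed)
valid <- generate_tdm_dataset(demographics_config(n_subjects = 50),
                              sampling_design("sparse"), truth,
                              seed = seed + 1L)

write_event_table(train, file.path(out, "training.csv"),
                  header_comments = paste0("seed=", seed))
write_event_table(valid, file.path(out, "validation.csv"),
                  header_comments = paste0("seed=", seed + 1L))

summarise_cohort <- function(d, label) {
  cov <- unique(d[, c("ID", "WT", "AGE", "SEX")])
  obs <- d[d$EVID == 0L & d$MDV == 0L, ]
  data.frame(cohort = label, n_subjects = nrow(cov),
             n_observations = nrow(obs),
             male_fraction = mean(cov$SEX),
             age_mean = mean(cov$AGE), age_sd = sd(cov$AGE),
             weight_mean = mean(cov$WT), weight_sd = sd(cov$WT),
             trough_median = median(obs$DV),
             trough_p05 = quantile(obs$DV, 0.05),
             trough_p95 = quantile(obs$DV, 0.95))
}
summ <- rbind(summarise_cohort(train, "training"),
              summarise_cohort(valid, "validation"))
write.csv(summ, file.path(out, "cohort_summary.csv"), row.names = FALSE)

cat("Cohorts written to", out, "\n")
print(summ, digits = 3, row.names = FALSE)
cat("\nThe training cohort mirrors the study structure: ~1.2 troughs per",
    "dog,\nsampled 20-40 days into 5 mg/kg q12h therapy; demographics",
    "match the\npublished 57% male, 5.4 +/- 3.5 y, 21.3 +/- 14.0 kg",
    "targets.\n")
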