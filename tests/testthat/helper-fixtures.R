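# Shared fixtures. Small datasets are generated in code; anything
# expensive is built once per test run and memoised here.

ref_params <- function(...) pb_params(...)

ref_individual <- function(params = pb_params(), eta = 0) {
  individual_params(params, weight = 20, age = 5, sex = 0, eta = eta)
}

# compact rich-design dataset for fitting tests: 14-day regimen,
# samples on the absorption/induction/steady-state timescales
small_rich_design <- function() {
  sampling_design("rich", sample_times = c(24, 96, 312))
}

small_dataset <- function(n = 15, seed = 1, truth = pb_params(),
                          design = small_rich_design()) {
  generate_tdm_dataset(demographics_config(n_subjects = n), design,
                       truth = truth, seed = seed)
}

# Bateman closed form for first-order absorption/elimination
bateman <- function(t, dose, V, ka, ke) {
  (dose / V) * ka / (ka - ke) * (exp(-ke * t) - exp(-ka * t))
}

# superpose a q-tau regimen of the Bateman solution (linear model only)
bateman_regimen <- function(t, dose_times, dose, V, ka, ke) {
  sapply(t, function(tt) {
    el <- tt - dose_times[dose_times <= tt]
    sum(bateman(el, dose, V, ka, ke))
  })
}
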