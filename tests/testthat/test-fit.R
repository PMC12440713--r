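test_that("noise-free typical-subject data identify CL/F exactly", {
  truth <- pb_params(omega_CL = 0, sigma_add = 0)
  d <- small_dataset(n = 5, seed = 31, truth = truth)
  spec <- model_spec(age_cov = "power",
                     estimate = c("CL_pop", "sigma_add"),
                     fixed = list(beta_age = -0.15, Kenz = 0.15,
                                  IC50 = 1.77, omega_CL = 0))
  fit <- suppressWarnings(fit_model(d, spec))
  # self-consistency: the OFV-minimizing CL_pop is the generating value
  expect_equal(fit$estimates$CL_pop, 0.015, tolerance = 5e-4)
})

test_that("structural parameters are recovered from a small synthetic study", {
  d <- small_dataset(n = 25, seed = 41)
  fit <- fit_model(d)
  expect_true(fit$convergence$converged)
  # loose envelopes: a 25-dog study only localizes the parameters
  expect_gt(fit$estimates$CL_pop, 0.015 / 3)
  expect_lt(fit$estimates$CL_pop, 0.015 * 3)
  expect_gt(fit$estimates$omega_CL, 0.1)
  expect_lt(fit$estimates$omega_CL, 0.6)
  expect_gt(fit$estimates$sigma_add, 1)
  expect_lt(fit$estimates$sigma_add, 4)
  expect_lt(abs(fit$estimates$beta_age - (-0.15)), 0.5)
  expect_equal(length(fit$eta_map), fit$n_subjects)
  # fixed parameters untouched
  expect_equal(fit$estimates$ka, 0.6)
  expect_equal(fit$estimates$V_ref, 20)
  expect_equal(fit$estimates$beta_wt, 0.75)
})

test_that("model_spec validates its constraints", {
  expect_error(model_spec(estimate = c("Kenz", "IC50")), "CL_pop")
  expect_error(model_spec(weight_cov = "allometric",
                          estimate = c("CL_pop", "beta_wt")),
               "beta_wt")
  expect_error(model_spec(age_cov = "none",
                          estimate = c("CL_pop", "beta_age")),
               "beta_age")
  s <- model_spec(weight_cov = "power")
  expect_true("beta_wt" %in% s$estimate)
})

test_that("likelihood ratio test reproduces the chi-square gates", {
  f1 <- structure(list(ofv = 103.84, estimated = c("CL_pop")),
                  class = "pb_fit")
  f2 <- structure(list(ofv = 100.00, estimated = c("CL_pop", "beta_age")),
                  class = "pb_fit")
  out <- lrt(f1, f2)
  expect_equal(out$delta_ofv, 3.84)
  expect_equal(out$df, 1)
  expect_equal(out$p_value, 0.050, tolerance = 2e-3)
  expect_equal(lrt(106.63, 100, df = 1)$p_value, 0.010, tolerance = 5e-3)
  same <- lrt(100, 100, df = 1)
  expect_equal(same$delta_ofv, 0)
  expect_equal(same$p_value, 1)
  expect_warning(lrt(90, 100, df = 1), "negative delta")
})

test_that("BICc applies the hybrid subject/observation penalty", {
  base <- list(ofv = 500, n_subjects = 40, n_obs = 120,
               estimated = c("CL_pop", "omega_CL", "sigma_add"))
  f1 <- structure(base, class = "pb_fit")
  f2 <- structure(modifyList(base, list(
    estimated = c("CL_pop", "omega_CL", "sigma_add", "Kenz"))),
    class = "pb_fit")
  # one extra fixed-effect (non-CL/F) parameter costs exactly log(n_obs)
  expect_equal(bicc(f2) - bicc(f1), log(120))
  # an extra CL/F-related parameter costs log(N_subjects)
  f3 <- structure(modifyList(base, list(
    estimated = c("CL_pop", "beta_age", "omega_CL", "sigma_add"))),
    class = "pb_fit")
  expect_equal(bicc(f3) - bicc(f1), log(40))
  # N_subjects == N_obs reduces to the classical BIC
  f4 <- structure(modifyList(base, list(n_obs = 40)), class = "pb_fit")
  expect_equal(bicc(f4), 500 + 3 * log(40))
})

test_that("MAP estimation recovers a known individual deviation", {
  pop <- pb_params(sigma_add = 1e-3)
  eta_true <- 0.4
  ind <- individual_params(pop, 18, 4, 1, eta_true)
  reg <- build_regimen(18, 5, 12, 15)
  tt <- c(24, 48, 96, 168, 264, 336)
  dv <- simulate_profile(ind, reg, tt)$conc
  sub <- rbind(
    data.frame(ID = 1L, TIME = tt, AMT = NA, DV = dv, EVID = 0L, MDV = 0L,
               WT = 18, AGE = 4, SEX = 1L),
    data.frame(ID = 1L, TIME = reg$time, AMT = reg$amount, DV = NA,
               EVID = 1L, MDV = 1L, WT = 18, AGE = 4, SEX = 1L))
  sub <- sub[order(sub$TIME, sub$EVID), ]
  m <- map_individual(sub, pop)
  expect_equal(m$eta, eta_true, tolerance = 1e-3)
  expect_equal(m$CL_i, individual_clearance(pop, 18, 4, 1, eta_true),
               tolerance = 1e-3)
})

test_that("MAP degenerates to the prior mode without data or variability", {
  pop <- pb_params()
  sub <- list(id = 1, weight = 20, age = 5, sex = 0,
              obs_time = numeric(0), dv = numeric(0),
              dose_time = c(0, 12), dose_amt = c(100, 100))
  m <- map_individual(sub, pop)
  expect_equal(m$eta, 0)
  expect_equal(m$CL_i, typical_clearance(pop, 20, 5))
  # omega -> 0: prior pins eta at 0 regardless of observations
  pop0 <- pb_params(omega_CL = 0)
  sub$obs_time <- 240; sub$dv <- 50
  sub$dose_time <- seq(0, 240, by = 12)
  sub$dose_amt <- rep(100, length(sub$dose_time))
  expect_equal(map_individual(sub, pop0)$eta, 0)
})

test_that("MAP estimates are shrunk relative to unpenalized estimates", {
  pop <- pb_params()
  d <- small_dataset(n = 8, seed = 51)
  for (id in unique(d$ID)[1:5]) {
    sub <- d[d$ID == id, ]
    class(sub) <- class(d)
    m_map <- map_individual(sub, pop, prior = TRUE)
    m_mle <- map_individual(sub, pop, prior = FALSE)
    expect_lte(abs(m_map$eta), abs(m_mle$eta) + 1e-6)
  }
})

test_that("standard errors behave like Fisher information", {
  truth <- pb_params()
  spec <- model_spec(age_cov = "power",
                     estimate = c("CL_pop", "omega_CL", "sigma_add"),
                     fixed = list(beta_age = -0.15, Kenz = 0.15,
                                  IC50 = 1.77))
  d_small <- small_dataset(n = 16, seed = 61)
  d_large <- small_dataset(n = 64, seed = 61)
  f_small <- fit_model(d_small, spec)
  f_large <- fit_model(d_large, spec)
  r_small <- compute_rse(f_small, d_small)
  r_large <- compute_rse(f_large, d_large)
  expect_true(attr(r_small, "ok"))
  se_s <- r_small$se[r_small$parameter == "CL_pop"]
  se_l <- r_large$se[r_large$parameter == "CL_pop"]
  expect_true(is.finite(se_s) && se_s > 0)
  # quadrupling n roughly halves the SE (1/sqrt(n) scaling, +/-35%)
  expect_gt(se_s / se_l, 2 * 0.65)
  expect_lt(se_s / se_l, 2 * 1.5)
  # fixed parameters carry no SE
  expect_true(all(is.na(r_small$se[r_small$parameter %in%
                                     c("ka", "V_ref", "Kenz", "IC50")])))
  w <- wald_test(r_small, "CL_pop")
  expect_lt(w$p_value, 0.05)
  expect_error(wald_test(r_small, "ka"), "no SE")
})
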