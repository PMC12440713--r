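test_that("covariate model on CL/F evaluates the power terms", {
  p <- pb_params()
  # at the covariate medians both factors are exactly 1
  expect_equal(typical_clearance(p, 20, 5), 0.015)
  expect_equal(typical_clearance(p, 10, 5), 0.015 * 0.5^0.75,
               tolerance = 1e-10)
  expect_equal(typical_clearance(p, 20, 10), 0.015 * 2^(-0.15),
               tolerance = 1e-10)
  # sex has no effect in the final model
  expect_equal(typical_clearance(p, 20, 5, sex = 1),
               typical_clearance(p, 20, 5, sex = 0))
  expect_error(typical_clearance(p, -1, 5), "weight")
  expect_error(typical_clearance(p, 20, 0), "age")
})

test_that("log-normal random effect scales clearance multiplicatively", {
  p <- pb_params()
  expect_equal(individual_clearance(p, 20, 5, eta = 0),
               typical_clearance(p, 20, 5))
  expect_equal(individual_clearance(p, 20, 5, eta = log(2)), 0.030)
  expect_equal(individual_clearance(p, 20, 5, eta = -log(2)), 0.0075)
  expect_error(individual_clearance(p, 20, 5, eta = Inf), "finite")
})

test_that("volume scales linearly with weight", {
  p <- pb_params()
  expect_equal(individual_volume(p, 20), 20)
  expect_equal(individual_volume(p, 10), 10)
  expect_equal(individual_volume(p, 40), 40)
  expect_error(individual_volume(p, 0), "positive")
})

test_that("enzyme inhibition is hyperbolic with half-max at IC50", {
  expect_equal(enzyme_inhibition(0, 1.77), 0)
  expect_equal(enzyme_inhibition(1.77, 1.77), 0.5)
  expect_equal(enzyme_inhibition(c(0.5, 5) * 1.77, 1.77), c(1/3, 5/6))
  expect_error(enzyme_inhibition(-1, 1.77), "non-negative")
})

test_that("enzyme steady state is 1 + Css/IC50", {
  expect_equal(enzyme_steady_state(0, 1.77), 1)
  expect_equal(enzyme_steady_state(1.77, 1.77), 2)
  expect_equal(enzyme_steady_state(30.486, 1.77), 18.2237, tolerance = 1e-4)
})

test_that("steady-state average solves the induction mass balance", {
  ind <- ref_individual()
  # frozen from the quadratic: a = CL/IC50, disc = CL^2 + 4 a dose/tau
  css <- steady_state_average(ind, 100, 12)
  expect_equal(css, 30.48563, tolerance = 1e-6)
  disc <- ind$CL_i^2 + 4 * (ind$CL_i / ind$IC50) * (100 / 12)
  expect_equal(disc, 0.282711, tolerance = 1e-5)
  # root satisfies the balance dose/tau = CL (1 + Css/IC50) Css
  expect_equal(ind$CL_i * (1 + css / ind$IC50) * css, 100 / 12)
  expect_equal(steady_state_average(ind, 0, 12), 0)
  # linear limit: IC50 -> Inf recovers rate/CL
  ind_lin <- ref_individual(pb_params(IC50 = 1e12))
  expect_equal(steady_state_average(ind_lin, 100, 12),
               (100 / 12) / ind_lin$CL_i, tolerance = 1e-6)
})

test_that("Css_avg increases strictly with dose rate", {
  ind <- ref_individual()
  doses <- seq(20, 200, by = 20)
  css <- vapply(doses, function(d) steady_state_average(ind, d, 12),
                numeric(1))
  expect_true(all(diff(css) > 0))
})

test_that("clearance is monotone in weight and age", {
  p <- pb_params()
  wts <- seq(5, 60, by = 5)
  expect_true(all(diff(typical_clearance(p, wts, 5)) > 0))
  ages <- seq(1, 14, by = 1)
  expect_true(all(diff(typical_clearance(p, 20, ages)) < 0))
})

test_that("profile simulation matches the Bateman closed form without induction", {
  # inhibition disabled via a huge IC50; single dose
  ind <- ref_individual(pb_params(IC50 = 1e9))
  tt <- c(1, 4, 8, 24, 72)
  pr <- simulate_profile(ind, data.frame(time = 0, amount = 100), tt)
  expect_equal(pr$conc, bateman(tt, 100, 20, 0.6, 7.5e-4),
               tolerance = 1e-3)
  expect_equal(pr$conc[3], 4.935, tolerance = 1e-3)
  # multiple doses: superposition holds in the linear limit
  dt <- seq(0, 108, by = 12)
  reg <- data.frame(time = dt, amount = 100)
  tt2 <- c(6, 30, 54, 102, 120)
  pr2 <- simulate_profile(ind, reg, tt2)
  expect_equal(pr2$conc, bateman_regimen(tt2, dt, 100, 20, 0.6, 7.5e-4),
               tolerance = 1e-3)
})

test_that("drug-free system stays at the enzyme fixed point", {
  ind <- ref_individual()
  pr <- simulate_profile(ind, doses = NULL, times = c(0, 10, 100))
  expect_equal(pr$conc, c(0, 0, 0))
  expect_equal(pr$Enz, c(1, 1, 1))
  pr2 <- simulate_profile(ind, data.frame(time = numeric(0),
                                          amount = numeric(0)),
                          times = c(5, 50))
  expect_equal(pr2$conc, c(0, 0))
})

test_that("mass is conserved when clearance is zero", {
  ind <- ref_individual()
  ind$CL_i <- 1e-14
  reg <- data.frame(time = c(0, 12, 24), amount = c(100, 50, 100))
  pr <- simulate_profile(ind, reg, times = c(6, 18, 23.9, 30, 200))
  given <- vapply(pr$time, function(t) sum(reg$amount[reg$time <= t]),
                  numeric(1))
  expect_equal(pr$Ad + pr$Ac, given, tolerance = 1e-6)
})

test_that("enzyme pool never falls below drug-free baseline under dosing", {
  ind <- ref_individual()
  reg <- build_regimen(20, 5, 12, 30)
  pr <- simulate_profile(ind, reg, times = seq(0, 720, by = 4))
  expect_true(all(pr$Enz >= 1 - 1e-8))
  expect_true(all(pr$conc >= 0))
  # enzyme pool grows toward its steady state under sustained exposure
  expect_gt(tail(pr$Enz, 1), 10)
})

test_that("unsorted inputs are rejected", {
  ind <- ref_individual()
  expect_error(simulate_profile(ind, data.frame(time = 0, amount = 100),
                                times = c(10, 5)), "sorted")
  expect_error(simulate_profile(ind,
                                data.frame(time = c(12, 0),
                                           amount = c(100, 100)),
                                times = c(5, 10)), "sorted")
})

test_that("ODE steady state agrees with the closed-form quadratic", {
  # across the clinical per-kg dose range, interval averages at 60 days
  # match the mass-balance root within 0.5%
  ind <- ref_individual()
  for (dpk in c(1, 5, 10)) {
    ex <- steady_state_extremes(ind, dpk * 20, 12, horizon_days = 60)
    expect_equal(ex$css_avg, steady_state_average(ind, dpk * 20, 12),
                 tolerance = 5e-3)
    expect_true(ex$converged)
    expect_lt(ex$trough, ex$css_avg)
    expect_gt(ex$peak, ex$css_avg)
  }
})

test_that("typical dog on 5 mg/kg q12h sits inside the therapeutic window", {
  ex <- steady_state_extremes(ref_individual(), 100, 12, horizon_days = 60)
  expect_gte(ex$trough, 15)
  expect_lte(ex$peak, 45)
  expect_equal(ex$trough, 28.7, tolerance = 0.01)
})

test_that("steady-state extremes flag non-attainment on short horizons", {
  expect_warning(steady_state_extremes(ref_individual(), 100, 12,
                                       horizon_days = 4),
                 "steady state")
  ex0 <- steady_state_extremes(ref_individual(), 0, 12)
  expect_equal(c(ex0$trough, ex0$peak), c(0, 0))
})
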