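# Virtual canine populations and synthetic therapeutic-drug-monitoring
# datasets. The generator emulates the structure of a steady-state TDM
# study: ~100 dogs, mostly single predose samples taken at least 20 days
# into therapy, oral tablet dosing, additive assay error with an LLOQ of
# 1.1 mg/L.

#' Demographics configuration for a virtual canine population
#'
#' Covariates are drawn from truncated normal distributions whose
#' parameters are moment-matched so that the realized mean and SD equal
#' the targets despite truncation. Defaults reproduce the study cohort:
#' 57% male, age 5.4 +/- 3.5 years, weight 21.3 +/- 14.0 kg.
#'
#' @param n_subjects number of dogs.
#' @param male_fraction probability of `sex == 1`.
#' @param age_mean,age_sd target age moments, years.
#' @param weight_mean,weight_sd target weight moments, kg.
#' @param age_bounds,weight_bounds truncation limits (positive,
#'   lower < upper).
#' @return A list of class `pb_demographics`.
#' @export
demographics_config <- function(n_subjects = 100, male_fraction = 0.57,
                                age_mean = 5.4, age_sd = 3.5,
                                weight_mean = 21.3, weight_sd = 14.0,
                                age_bounds = c(0.3, 16),
                                weight_bounds = c(2, 70)) {
  stopifnot(n_subjects >= 1, male_fraction >= 0, male_fraction <= 1,
            age_sd >= 0, weight_sd >= 0,
            length(age_bounds) == 2L, length(weight_bounds) == 2L,
            all(age_bounds > 0), all(weight_bounds > 0),
            age_bounds[1] < age_bounds[2],
            weight_bounds[1] < weight_bounds[2])
  cfg <- list(n_subjects = as.integer(n_subjects),
              male_fraction = male_fraction,
              age_mean = age_mean, age_sd = age_sd,
              weight_mean = weight_mean, weight_sd = weight_sd,
              age_bounds = age_bounds, weight_bounds = weight_bounds)
  cfg$age_parent <- truncnorm_match(age_mean, age_sd, age_bounds)
  cfg$weight_parent <- truncnorm_match(weight_mean, weight_sd, weight_bounds)
  structure(cfg, class = "pb_demographics")
}

# moments of N(mu, sigma^2) truncated to [lo, hi]
truncnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  Z <- pnorm(b) - pnorm(a)
  if (Z < 1e-12) return(c(NaN, NaN))
  d <- (dnorm(a) - dnorm(b)) / Z
  m <- mu + sigma * d
  v <- sigma^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z - d^2)
  c(m, sqrt(pmax(v, 0)))
}

# find parent (mu, sigma) whose truncation to bounds has the target moments
truncnorm_match <- function(target_mean, target_sd, bounds) {
  lo <- bounds[1]; hi <- bounds[2]
  if (target_mean <= lo || target_mean >= hi)
    stop("target mean outside truncation bounds")
  obj <- function(par) {
    mo <- truncnorm_moments(par[1], exp(par[2]), lo, hi)
    if (any(!is.finite(mo))) return(1e6)
    ((mo[1] - target_mean) / target_sd)^2 + ((mo[2] - target_sd) / target_sd)^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj,
               method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  if (fit$value > 1e-6)
    stop("infeasible truncation bounds: cannot match the requested moments")
  list(mu = fit$par[1], sigma = exp(fit$par[2]), lo = lo, hi = hi)
}

rtruncnorm_inv <- function(n, parent) {
  pa <- pnorm((parent$lo - parent$mu) / parent$sigma)
  pb <- pnorm((parent$hi - parent$mu) / parent$sigma)
  u <- runif(n, pa, pb)
  parent$mu + parent$sigma * qnorm(u)
}

#' Draw covariates for a virtual canine population
#'
#' @param config a [demographics_config()].
#' @param seed integer seed (draws are reproducible; the caller's RNG
#'   state is preserved).
#' @return Data frame with columns `id`, `weight` (kg), `age` (years),
#'   `sex` (1 = male, 0 = female).
#' @export
sample_covariates <- function(config = demographics_config(), seed = NULL) {
  stopifnot(inherits(config, "pb_demographics"))
  with_seed(seed, {
    n <- config$n_subjects
    data.frame(id = seq_len(n),
               weight = rtruncnorm_inv(n, config$weight_parent),
               age = rtruncnorm_inv(n, config$age_parent),
               sex = rbinom(n, 1L, config$male_fraction))
  })
}

# dose amounts realizable from 100/40/15 mg tablets and their halves
tablet_achievable <- function(max_mg) {
  coins <- c(100, 50, 40, 20, 15, 7.5) / 2.5
  limit <- ceiling(max_mg / 2.5) + 40L
  ok <- logical(limit + 1L)   # ok[k+1] <=> k * 2.5 mg achievable
  ok[1] <- TRUE
  for (k in seq_len(limit)) {
    reach <- coins[coins <= k]
    ok[k + 1L] <- length(reach) > 0L && any(ok[k + 1L - reach])
  }
  which(ok) - 1L
}

#' Round a dose to the nearest achievable tablet combination
#'
#' Commercial phenobarbital tablets come in 100, 40 and 15 mg strengths
#' and may be halved; achievable doses are sums of
#' \{100, 50, 40, 20, 15, 7.5\} mg. The nearest achievable amount is
#' returned (ties resolved downward).
#'
#' @param dose_mg desired dose, mg (vectorized, positive).
#' @export
round_to_tablets <- function(dose_mg) {
  stopifnot(all(dose_mg > 0))
  ach <- tablet_achievable(max(dose_mg)) * 2.5
  ach <- ach[ach > 0]
  vapply(dose_mg, function(d) {
    err <- abs(ach - d)
    cand <- ach[err == min(err)]
    min(cand)
  }, numeric(1))
}

#' Build a repeated oral dosing schedule
#'
#' @param weight body weight, kg.
#' @param dose_per_kg dose, mg/kg.
#' @param interval dosing interval, h.
#' @param duration_days length of the regimen, days.
#' @param round_tablets round each administration to an achievable tablet
#'   combination ([round_to_tablets()]).
#' @param start time of the first dose, h.
#' @return Data frame of dose events with columns `time` (h) and `amount`
#'   (mg).
#' @export
build_regimen <- function(weight, dose_per_kg, interval = 12,
                          duration_days = 30, round_tablets = FALSE,
                          start = 0) {
  stopifnot(weight > 0, dose_per_kg > 0, interval > 0, duration_days > 0)
  times <- seq(start, start + duration_days * 24 - interval, by = interval)
  amt <- dose_per_kg * weight
  if (round_tablets) amt <- round_to_tablets(amt)
  data.frame(time = times, amount = rep(amt, length(times)))
}

#' Sampling design for a synthetic TDM study
#'
#' The `"sparse"` design mirrors clinical practice: one predose (trough)
#' sample on a random day between `predose_window_days`, with
#' `repeat_fraction` of subjects contributing a second trough on a later
#' day. The `"rich"` design samples every subject at fixed times chosen to
#' inform the induction dynamics (defaults 48, 168 and 672 h).
#'
#' @param type `"sparse"` or `"rich"`.
#' @param sample_times fixed sampling times for the rich design, h.
#' @param predose_window_days day window for sparse trough sampling.
#' @param repeat_fraction fraction of subjects with a second sample
#'   (sparse design).
#' @param lloq assay lower limit of quantification, mg/L.
#' @param lloq_policy `"exclude"` marks below-LLOQ observations as missing
#'   for estimation (`MDV = 1`); `"flag"` keeps them with `BLQ = 1`.
#' @return A list of class `pb_design`.
#' @export
sampling_design <- function(type = c("sparse", "rich"),
                            sample_times = c(48, 168, 672),
                            predose_window_days = c(20, 40),
                            repeat_fraction = 0.2,
                            lloq = 1.1,
                            lloq_policy = c("exclude", "flag")) {
  type <- match.arg(type)
  lloq_policy <- match.arg(lloq_policy)
  stopifnot(all(sample_times >= 0), repeat_fraction >= 0,
            repeat_fraction <= 1, lloq >= 0,
            length(predose_window_days) == 2L,
            predose_window_days[1] <= predose_window_days[2])
  structure(list(type = type, sample_times = sort(sample_times),
                 predose_window_days = predose_window_days,
                 repeat_fraction = repeat_fraction, lloq = lloq,
                 lloq_policy = lloq_policy),
            class = "pb_design")
}

#' Generate a synthetic TDM dataset
#'
#' Simulates a steady-state therapeutic-drug-monitoring study: for each
#' virtual dog a clearance random effect `eta ~ N(0, omega_CL^2)` is
#' drawn, the autoinduction profile under its regimen is integrated,
#' concentrations are sampled per the design, additive
#' `N(0, sigma_add^2)` noise is applied, and the LLOQ policy is enforced.
#' Negative noisy observations are truncated at 0 (they then fall below
#' the LLOQ and are handled by its policy). With `omega_CL = 0` and
#' `sigma_add = 0` every observation equals the typical-subject model
#' prediction.
#'
#' @param demog a [demographics_config()].
#' @param design a [sampling_design()].
#' @param truth a [pb_params()] object used as simulation truth.
#' @param regimen list with `dose_per_kg`, `interval` (h) and optional
#'   `round_tablets` flag; every subject receives it from time 0.
#' @param seed integer seed.
#' @return An event table (see [read_event_table()] for the dialect): one
#'   row per dose (`EVID = 1`) or observation (`EVID = 0`), with columns
#'   `ID, TIME, AMT, DV, EVID, MDV, WT, AGE, SEX, BLQ`. Observation rows
#'   at a dose time are predose samples and sort before the dose row.
#' @export
generate_tdm_dataset <- function(demog = demographics_config(),
                                 design = sampling_design(),
                                 truth = pb_params(),
                                 regimen = list(dose_per_kg = 5,
                                                interval = 12,
                                                round_tablets = FALSE),
                                 seed = NULL) {
  stopifnot(inherits(demog, "pb_demographics"),
            inherits(design, "pb_design"), inherits(truth, "pb_params"))
  with_seed(seed, {
    cov <- sample_covariates(demog, seed = NULL)
    n <- nrow(cov)
    etas <- rnorm(n, 0, truth$omega_CL)
    # observation times per subject
    obs_times <- vector("list", n)
    if (design$type == "rich") {
      for (i in seq_len(n)) obs_times[[i]] <- design$sample_times
    } else {
      w <- design$predose_window_days
      d1 <- sample(seq(w[1], w[2]), n, replace = TRUE)
      second <- runif(n) < design$repeat_fraction
      for (i in seq_len(n)) {
        tt <- d1[i] * 24
        if (second[i]) {
          d2 <- sample(setdiff(seq(w[1], w[2]), d1[i]), 1L)
          tt <- c(tt, d2 * 24)
        }
        obs_times[[i]] <- sort(tt)
      }
    }
    dur_days <- ceiling(max(unlist(obs_times)) / 24) + 1
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      reg <- build_regimen(cov$weight[i], regimen$dose_per_kg,
                           regimen$interval, dur_days,
                           round_tablets = isTRUE(regimen$round_tablets))
      ind <- individual_params(truth, cov$weight[i], cov$age[i],
                               cov$sex[i], etas[i])
      tt <- obs_times[[i]]
      pred <- simulate_profile(ind, reg, tt)$conc
      dv <- pred + rnorm(length(tt), 0, truth$sigma_add)
      dv <- pmax(dv, 0)
      blq <- as.integer(dv < design$lloq)
      mdv <- if (design$lloq_policy == "exclude") blq else rep(0L, length(tt))
      obs <- data.frame(ID = cov$id[i], TIME = tt, AMT = NA_real_, DV = dv,
                        EVID = 0L, MDV = mdv, WT = cov$weight[i],
                        AGE = cov$age[i], SEX = cov$sex[i], BLQ = blq)
      dos <- data.frame(ID = cov$id[i], TIME = reg$time, AMT = reg$amount,
                        DV = NA_real_, EVID = 1L, MDV = 1L,
                        WT = cov$weight[i], AGE = cov$age[i],
                        SEX = cov$sex[i], BLQ = 0L)
      rows[[i]] <- rbind(obs, dos)
    }
    tab <- do.call(rbind, rows)
    # predose convention: at equal times observations precede doses
    tab <- tab[order(tab$ID, tab$TIME, tab$EVID), ]
    rownames(tab) <- NULL
    class(tab) <- c("pb_event_table", "data.frame")
    tab
  })
}
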