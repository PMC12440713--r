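# Dosing regimens and Monte Carlo evaluation: loading/progression/
# maintenance plans stratified by weight and age, probability of target
# attainment against the 15-45 mg/L therapeutic window, time to target
# and maintenance-dose search.

#' Loading/progression/maintenance regimen plan
#'
#' All doses are in mg/kg; absolute amounts are formed per subject as
#' dose * weight. Phase hand-offs follow a documented convention:
#' loading doses at their stated times (single dose at 0 h, or repeated
#' q24h); the progression phase starts 24 h after the last loading dose
#' and runs q12h for its stated duration; maintenance starts when the
#' progression ends (or 24 h after the last loading dose when there is
#' no progression phase) and continues q12h to the simulation horizon.
#'
#' @param loading data frame with columns `time` (h) and `dose_per_kg`,
#'   or `NULL`.
#' @param progression list with `dose_per_kg`, `interval`, `start`,
#'   `duration_days`, or `NULL`.
#' @param maintenance list with `dose_per_kg`, `interval`, `start`.
#' @return A list of class `pb_regimen_plan`.
#' @export
regimen_plan <- function(loading = NULL, progression = NULL, maintenance) {
  if (!is.null(loading)) {
    stopifnot(is.data.frame(loading),
              all(c("time", "dose_per_kg") %in% names(loading)),
              all(loading$dose_per_kg > 0), all(loading$time >= 0))
  }
  if (!is.null(progression)) {
    stopifnot(progression$dose_per_kg > 0, progression$interval > 0,
              progression$duration_days > 0)
    if (!is.null(loading) && progression$start <= max(loading$time))
      stop("progression phase overlaps the loading phase")
  }
  stopifnot(maintenance$dose_per_kg > 0, maintenance$interval > 0)
  if (!is.null(progression) &&
      maintenance$start < progression$start +
        progression$duration_days * 24)
    stop("maintenance phase overlaps the progression phase")
  if (is.null(progression) && !is.null(loading) &&
      maintenance$start <= max(loading$time))
    stop("maintenance phase overlaps the loading phase")
  structure(list(loading = loading, progression = progression,
                 maintenance = maintenance), class = "pb_regimen_plan")
}

#' @export
print.pb_regimen_plan <- function(x, ...) {
  cat("Phenobarbital regimen plan (doses in mg/kg)\n")
  if (!is.null(x$loading))
    cat("  loading:    ", paste(sprintf("%g mg/kg at %g h",
        x$loading$dose_per_kg, x$loading$time), collapse = "; "), "\n")
  if (!is.null(x$progression))
    cat(sprintf("  progression: %g mg/kg q%gh from %g h for %g days\n",
                x$progression$dose_per_kg, x$progression$interval,
                x$progression$start, x$progression$duration_days))
  cat(sprintf("  maintenance: %g mg/kg q%gh from %g h\n",
              x$maintenance$dose_per_kg, x$maintenance$interval,
              x$maintenance$start))
  invisible(x)
}

# per-kg dose schedule implied by a plan up to `horizon` hours
plan_schedule <- function(plan, horizon) {
  tt <- numeric(0); dd <- numeric(0)
  if (!is.null(plan$loading)) {
    tt <- plan$loading$time
    dd <- plan$loading$dose_per_kg
  }
  if (!is.null(plan$progression)) {
    p <- plan$progression
    pt <- seq(p$start, p$start + p$duration_days * 24 - p$interval,
              by = p$interval)
    tt <- c(tt, pt); dd <- c(dd, rep(p$dose_per_kg, length(pt)))
  }
  m <- plan$maintenance
  mt <- seq(m$start, horizon - m$interval, by = m$interval)
  tt <- c(tt, mt); dd <- c(dd, rep(m$dose_per_kg, length(mt)))
  ord <- order(tt)
  list(time = tt[ord], dose_per_kg = dd[ord])
}

#' Recommended regimen by weight and age stratum
#'
#' Look-up of the simulation-derived dosing recommendations on the 3 x 3
#' grid of weight (< 10, 10-25, > 25 kg) by age (<= 1, 1-7, >= 7 years)
#' strata. Boundary values resolve as: weight bins `[0, 10)`, `[10, 25]`,
#' `(25, Inf)`; age bins `(0, 1]`, `(1, 7)`, `[7, Inf)`.
#'
#' @param weight body weight, kg.
#' @param age age, years.
#' @return A [regimen_plan()] with attributes `weight_stratum` and
#'   `age_stratum`.
#' @examples
#' recommend_regimen(20, 5)   # maintenance 5 mg/kg q12h
#' @export
recommend_regimen <- function(weight, age) {
  stopifnot(weight > 0, age > 0)
  wi <- if (weight < 10) 1L else if (weight <= 25) 2L else 3L
  ai <- if (age <= 1) 1L else if (age < 7) 2L else 3L
  load1 <- function(dose) data.frame(time = 0, dose_per_kg = dose)
  # cells: list(loading df, progression dose or NA, maintenance dose)
  grid <- list(
    list(load1(25), 5, 8), list(load1(25), 5, 6),
    list(data.frame(time = c(0, 24), dose_per_kg = 20), 3, 5),
    list(load1(25), 4, 6), list(load1(25), 3, 5), list(load1(20), NA, 4),
    list(load1(25), 3, 5), list(load1(20), NA, 3), list(load1(20), NA, 3))
  cell <- grid[[(wi - 1L) * 3L + ai]]
  loading <- cell[[1]]
  prog_start <- max(loading$time) + 24
  progression <- if (!is.na(cell[[2]]))
    list(dose_per_kg = cell[[2]], interval = 12, start = prog_start,
         duration_days = 5) else NULL
  maint_start <- if (is.null(progression)) prog_start
                 else prog_start + 5 * 24
  plan <- regimen_plan(loading, progression,
                       list(dose_per_kg = cell[[3]], interval = 12,
                            start = maint_start))
  attr(plan, "weight_stratum") <- c("<10", "10-25", ">25")[wi]
  attr(plan, "age_stratum") <- c("<=1", "1-7", ">=7")[ai]
  plan
}

#' Stratum definition for population simulation
#'
#' @param weight_range,age_range numeric length-2 vectors (kg, years).
#' @export
stratum <- function(weight_range, age_range) {
  stopifnot(length(weight_range) == 2L, length(age_range) == 2L,
            all(weight_range > 0), all(age_range > 0),
            weight_range[1] <= weight_range[2],
            age_range[1] <= age_range[2])
  structure(list(weight_range = weight_range, age_range = age_range),
            class = "pb_stratum")
}

#' Monte Carlo simulation of a dosing plan in a covariate stratum
#'
#' Draws `n` virtual dogs with weight and age uniform within the stratum
#' and a clearance random effect `eta ~ N(0, omega_CL^2)`, builds each
#' dog's dose events from the per-kg plan, and integrates the
#' autoinduction model over the horizon. Because volume scales linearly
#' with weight, per-kg dosing gives all subjects the same dose schedule
#' in concentration units, so the population is simulated by solving the
#' system on a log-ke grid and interpolating each subject's trajectory.
#'
#' Trough concentrations are recorded immediately before each dose (the
#' central concentration is continuous at dose times) and the final
#' dosing interval is sampled densely for the peak. Steady-state
#' attainment is flagged by comparing the last two troughs per subject.
#'
#' @param plan a [regimen_plan()].
#' @param strat a [stratum()].
#' @param n number of simulated subjects.
#' @param pop a [pb_params()] object (residual error is not added;
#'   exposure targets concern true concentrations).
#' @param seed integer seed.
#' @param horizon_days simulation horizon, days.
#' @return List of class `pb_popsim`: `trough_time` (h), `troughs`
#'   (matrix subjects x trough times), `final_trough`, `final_peak`,
#'   `css_converged` (per-subject logical), `covariates`, `plan`,
#'   `percentiles` (5/50/95 of the trough trajectory across subjects).
#' @export
simulate_population <- function(plan, strat, n = 1000, pop = pb_params(),
                                seed = NULL, horizon_days = 60) {
  stopifnot(inherits(plan, "pb_regimen_plan"), inherits(strat, "pb_stratum"),
            n >= 1)
  horizon <- horizon_days * 24
  sched <- plan_schedule(plan, horizon)
  with_seed(seed, {
    wt <- runif(n, strat$weight_range[1], strat$weight_range[2])
    age <- runif(n, strat$age_range[1], strat$age_range[2])
    sex <- rbinom(n, 1L, 0.5)
    eta <- rnorm(n, 0, pop$omega_CL)
    cl <- individual_clearance(pop, wt, age, sex, eta)
    V <- individual_volume(pop, wt)
    lke <- log(cl / V)
    # doses in concentration units: dose_per_kg * wt / V = per_kg * 20/V_ref
    dose_conc <- sched$dose_per_kg * pop$wt_ref / pop$V_ref
    trough_time <- c(sched$time[-1], horizon)
    last_int <- c(tail(sched$time, 1), horizon)
    dense <- seq(last_int[1], last_int[2], length.out = 25L)
    times <- sort(unique(c(trough_time, dense)))
    pad <- 0.05
    lgrid <- seq(min(lke) - pad, max(lke) + pad,
                 length.out = max(31L, min(121L,
                   ceiling((diff(range(lke)) + 2 * pad) / 0.05) + 1L)))
    sol <- pb_solve(ke = exp(lgrid), dose_time = sched$time,
                    dose_conc = dose_conc, times = times,
                    ka = pop$ka, Kenz = pop$Kenz, IC50 = pop$IC50)
    conc <- matrix(0, length(times), n)                      # times x n
    for (row in seq_along(times))
      conc[row, ] <- splinefun(lgrid, sol$Cc[row, ], method = "fmm")(lke)
    ti <- match(trough_time, times)
    troughs <- t(conc[ti, , drop = FALSE])                   # n x troughs
    fi <- times >= last_int[1]
    final_peak <- apply(conc[fi, , drop = FALSE], 2, max)
    final_trough <- apply(conc[fi, , drop = FALSE], 2, min)
    ntr <- ncol(troughs)
    css_converged <- abs(troughs[, ntr] - troughs[, ntr - 1L]) <=
      1e-3 * pmax(troughs[, ntr], 1e-12)
    pct <- apply(troughs, 2, quantile, probs = c(0.05, 0.5, 0.95))
    structure(list(
      trough_time = trough_time, troughs = troughs,
      final_trough = final_trough, final_peak = final_peak,
      css_converged = css_converged,
      covariates = data.frame(weight = wt, age = age, sex = sex,
                              eta = eta),
      percentiles = data.frame(time = trough_time, p5 = pct[1, ],
                               p50 = pct[2, ], p95 = pct[3, ]),
      plan = plan, horizon_days = horizon_days), class = "pb_popsim")
  })
}

#' Probability of target attainment
#'
#' Fraction of simulated subjects whose steady-state exposure lies in the
#' therapeutic window. By default the steady-state trough (the clinical
#' TDM quantity) must fall within `[target_low, target_high]`; with
#' `evaluation = "window"` the entire final-interval concentration range
#' must.
#'
#' @param result a [simulate_population()] result.
#' @param target_low,target_high window bounds, mg/L (default 15-45).
#' @param evaluation `"trough"` or `"window"`.
#' @return Fraction in `[0, 1]`.
#' @export
pta <- function(result, target_low = 15, target_high = 45,
                evaluation = c("trough", "window")) {
  stopifnot(inherits(result, "pb_popsim"))
  evaluation <- match.arg(evaluation)
  if (!all(result$css_converged))
    warning(sum(!result$css_converged),
            " subject(s) had not reached steady state")
  hit <- if (evaluation == "trough")
    result$final_trough >= target_low & result$final_trough <= target_high
  else
    result$final_trough >= target_low & result$final_peak <= target_high
  mean(hit)
}

#' Time to stable attainment of the therapeutic window
#'
#' First time the trough trajectory enters the window and remains inside
#' through the end of the simulation; `Inf` when that never happens.
#'
#' @param trough_time trough times, h.
#' @param troughs numeric vector (one subject) or matrix
#'   (subjects x times) of trough concentrations.
#' @param target_low,target_high window bounds, mg/L.
#' @return Time(s) in hours (vector for a matrix input).
#' @export
time_to_target <- function(trough_time, troughs, target_low = 15,
                           target_high = 45) {
  one <- function(v) {
    inside <- v >= target_low & v <= target_high
    if (!any(inside)) return(Inf)
    stays <- rev(cumprod(rev(inside))) == 1
    if (!stays[length(stays)]) return(Inf)
    trough_time[which(stays)[1]]
  }
  if (is.matrix(troughs)) apply(troughs, 1, one) else one(troughs)
}

#' Search for the minimal maintenance dose meeting a PTA threshold
#'
#' Simulates a maintenance-only q`interval` regimen for each candidate
#' dose (common random numbers across candidates) and returns the
#' smallest one whose steady-state-trough PTA reaches the threshold.
#'
#' @param strat a [stratum()].
#' @param candidates candidate doses, mg/kg, sorted ascending.
#' @param pop a [pb_params()] object.
#' @param n subjects per candidate.
#' @param seed integer seed (reused across candidates).
#' @param pta_threshold required PTA.
#' @param interval dosing interval, h.
#' @param horizon_days simulation horizon.
#' @return List with `dose` (`NA` when no candidate qualifies) and
#'   `curve` (data frame dose vs PTA).
#' @export
search_maintenance_dose <- function(strat, candidates, pop = pb_params(),
                                    n = 500, seed = NULL,
                                    pta_threshold = 0.90, interval = 12,
                                    horizon_days = 60) {
  stopifnot(!is.unsorted(candidates), all(candidates > 0))
  curve <- data.frame(dose_per_kg = candidates, pta = NA_real_)
  for (i in seq_along(candidates)) {
    plan <- regimen_plan(maintenance = list(dose_per_kg = candidates[i],
                                            interval = interval,
                                            start = 0))
    sim <- simulate_population(plan, strat, n = n, pop = pop, seed = seed,
                               horizon_days = horizon_days)
    curve$pta[i] <- pta(sim)
  }
  hit <- which(curve$pta >= pta_threshold)
  list(dose = if (length(hit)) candidates[hit[1]] else NA_real_,
       curve = curve)
}

#' Days until trough concentrations stabilize
#'
#' First day at which the trough is within `tol` (relative) of the
#' terminal trough. Under pure first-order elimination this is the
#' classical 4-5 half-life accumulation time; autoinduction stretches it
#' because clearance keeps rising while enzymes accumulate.
#'
#' @param trough_time trough times, h.
#' @param troughs trough concentrations of a single trajectory, mg/L.
#' @param tol relative tolerance (default 0.10).
#' @return Time in days (`NA` with a warning for an all-zero trajectory).
#' @export
stabilization_time <- function(trough_time, troughs, tol = 0.10) {
  terminal <- tail(troughs, 1)
  if (terminal <= 0) {
    warning("undefined stabilization time: no exposure")
    return(NA_real_)
  }
  within <- abs(troughs - terminal) <= tol * terminal
  stays <- rev(cumprod(rev(within))) == 1
  trough_time[which(stays)[1]] / 24
}
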