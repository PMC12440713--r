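#' Population pharmacokinetic parameters
#'
#' Container for the fixed effects, random-effect variability and residual
#' error of the autoinduction phenobarbital model. Defaults are the final
#' published estimates for dogs on chronic oral monotherapy: absorption and
#' volume fixed to literature values, apparent clearance scaled
#' allometrically with weight (exponent 3/4) and by a power of age, and an
#' enzyme-turnover pool whose degradation is inhibited by drug concentration
#' (half-maximal at `IC50`), so that clearance rises with exposure.
#'
#' All disposition parameters are apparent (confounded with the unobserved
#' oral bioavailability F); doses are treated as entering the depot in full.
#'
#' @param ka absorption rate constant, 1/h.
#' @param V_ref apparent central volume at the 20 kg reference weight, L.
#' @param CL_pop typical apparent clearance at the covariate medians
#'   (20 kg, 5 years), L/h.
#' @param beta_wt allometric weight exponent on CL/F (3/4 in the final
#'   model).
#' @param beta_age age power exponent on CL/F (negative: clearance falls
#'   with age).
#' @param beta_sex sex effect on log CL/F (0: no effect in the final
#'   model); sex coded 1 = male, 0 = female.
#' @param Kenz enzyme turnover rate constant (production = degradation at
#'   baseline), 1/h.
#' @param IC50 drug concentration halving the enzyme degradation rate,
#'   mg/L.
#' @param omega_CL standard deviation of the log-normal between-subject
#'   random effect on CL/F.
#' @param sigma_add additive residual error SD, mg/L.
#' @param wt_ref,age_ref covariate centering values (population medians),
#'   kg and years.
#' @return An object of class `pb_params` (a validated named list).
#' @examples
#' p <- pb_params()
#' typical_clearance(p, weight = 20, age = 5)
#' @export
pb_params <- function(ka = 0.6, V_ref = 20, CL_pop = 0.015,
                      beta_wt = 0.75, beta_age = -0.15, beta_sex = 0,
                      Kenz = 0.15, IC50 = 1.77,
                      omega_CL = 0.3, sigma_add = 2,
                      wt_ref = 20, age_ref = 5) {
  p <- list(ka = ka, V_ref = V_ref, CL_pop = CL_pop, beta_wt = beta_wt,
            beta_age = beta_age, beta_sex = beta_sex, Kenz = Kenz,
            IC50 = IC50, omega_CL = omega_CL, sigma_add = sigma_add,
            wt_ref = wt_ref, age_ref = age_ref)
  for (nm in c("ka", "V_ref", "CL_pop", "Kenz", "IC50", "wt_ref", "age_ref"))
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0)
      stop(sprintf("'%s' must be a single positive number", nm))
  for (nm in c("omega_CL", "sigma_add"))
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] < 0)
      stop(sprintf("'%s' must be a single non-negative number", nm))
  for (nm in c("beta_wt", "beta_age", "beta_sex"))
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop(sprintf("'%s' must be a single finite number", nm))
  structure(p, class = "pb_params")
}

#' @export
print.pb_params <- function(x, ...) {
  cat("Population PK parameters (autoinduction model)\n")
  cat(sprintf("  ka       %8.4g 1/h      V_ref  %8.4g L (at %g kg)\n",
              x$ka, x$V_ref, x$wt_ref))
  cat(sprintf("  CL_pop   %8.4g L/h      beta_wt %7.3g  beta_age %7.3g  beta_sex %7.3g\n",
              x$CL_pop, x$beta_wt, x$beta_age, x$beta_sex))
  cat(sprintf("  Kenz     %8.4g 1/h      IC50   %8.4g mg/L\n", x$Kenz, x$IC50))
  cat(sprintf("  omega_CL %8.4g          sigma_add %6.4g mg/L\n",
              x$omega_CL, x$sigma_add))
  invisible(x)
}

check_covariates <- function(weight, age) {
  if (any(!is.finite(weight)) || any(weight <= 0))
    stop("weight must be positive")
  if (any(!is.finite(age)) || any(age <= 0))
    stop("age must be positive")
  invisible(TRUE)
}

#' Typical (population) apparent clearance for given covariates
#'
#' Evaluates the covariate model on CL/F:
#' `CL_pop * (weight/20)^beta_wt * (age/5)^beta_age * exp(beta_sex * sex)`.
#' With the final-model defaults the sex term is absent (`beta_sex = 0`).
#'
#' @param params a [pb_params()] object.
#' @param weight body weight, kg (vectorized).
#' @param age age, years (vectorized).
#' @param sex 1 = male, 0 = female (vectorized; no effect by default).
#' @return Clearance in L/h.
#' @export
typical_clearance <- function(params, weight, age, sex = 0) {
  stopifnot(inherits(params, "pb_params"))
  check_covariates(weight, age)
  params$CL_pop * (weight / params$wt_ref)^params$beta_wt *
    (age / params$age_ref)^params$beta_age * exp(params$beta_sex * sex)
}

#' Individual apparent clearance
#'
#' Applies the log-normal between-subject random effect:
#' `CL_i = CL_typical * exp(eta)`.
#'
#' @inheritParams typical_clearance
#' @param eta individual random effect (finite).
#' @export
individual_clearance <- function(params, weight, age, sex = 0, eta = 0) {
  if (any(!is.finite(eta))) stop("eta must be finite")
  typical_clearance(params, weight, age, sex) * exp(eta)
}

#' Individual apparent volume of distribution
#'
#' Volume scales linearly with weight: `V_i = V_ref * weight / 20`.
#'
#' @inheritParams typical_clearance
#' @export
individual_volume <- function(params, weight) {
  stopifnot(inherits(params, "pb_params"))
  if (any(!is.finite(weight)) || any(weight <= 0))
    stop("weight must be positive")
  params$V_ref * weight / params$wt_ref
}

#' Fractional inhibition of enzyme degradation
#'
#' The autoinduction mechanism: drug inhibits degradation of its own
#' metabolizing enzymes with a hyperbolic concentration-effect,
#' `conc / (conc + IC50)`, so the degradation rate is halved at
#' `conc == IC50`.
#'
#' @param conc drug concentration, mg/L (vectorized, non-negative).
#' @param IC50 half-maximal inhibitory concentration, mg/L.
#' @return Fraction in `[0, 1)`.
#' @export
enzyme_inhibition <- function(conc, IC50) {
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("conc must be non-negative")
  if (!is.numeric(IC50) || IC50 <= 0) stop("IC50 must be positive")
  conc / (conc + IC50)
}

#' Enzyme pool at steady state for a constant concentration
#'
#' At equilibrium of the turnover equation the relative enzyme pool is
#' `1 + Css / IC50`; unity in the absence of drug.
#'
#' @param Css steady-state concentration, mg/L (non-negative).
#' @param IC50 half-maximal inhibitory concentration, mg/L.
#' @export
enzyme_steady_state <- function(Css, IC50) {
  if (any(!is.finite(Css)) || any(Css < 0)) stop("Css must be non-negative")
  if (!is.numeric(IC50) || IC50 <= 0) stop("IC50 must be positive")
  1 + Css / IC50
}

#' Individual parameter set
#'
#' Bundles the individual clearance and volume implied by the covariates
#' and a random effect with the shared structural constants, for use with
#' [simulate_profile()] and the steady-state helpers.
#'
#' @inheritParams typical_clearance
#' @param eta random effect on CL/F.
#' @return A list of class `pb_individual` with elements `CL_i`, `V_i`,
#'   `ka`, `Kenz`, `IC50`.
#' @export
individual_params <- function(params, weight, age, sex = 0, eta = 0) {
  structure(list(
    CL_i = individual_clearance(params, weight, age, sex, eta),
    V_i  = individual_volume(params, weight),
    ka   = params$ka, Kenz = params$Kenz, IC50 = params$IC50
  ), class = "pb_individual")
}

#' Average steady-state concentration under repeated dosing
#'
#' Under the autoinduction model the mass balance at steady state is
#' `dose/tau = CL_i * (1 + Css/IC50) * Css`: the input rate is cleared by
#' the induced clearance `CL_i * Enz_ss`. `Css` is the positive root of
#' the quadratic `(CL_i/IC50) Css^2 + CL_i Css - dose/tau = 0`. As
#' `IC50 -> Inf` this reduces to the linear result `(dose/tau)/CL_i`.
#'
#' @param ind a [individual_params()] object (or any list with `CL_i`,
#'   `IC50`).
#' @param dose maintenance dose per administration, mg.
#' @param tau dosing interval, h.
#' @return Average steady-state concentration, mg/L.
#' @export
steady_state_average <- function(ind, dose, tau) {
  stopifnot(dose >= 0, tau > 0)
  if (dose == 0) return(0)
  cl <- ind$CL_i; ic50 <- ind$IC50
  rate <- dose / tau
  a <- cl / ic50
  disc <- cl^2 + 4 * a * rate
  (-cl + sqrt(disc)) / (2 * a)
}
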