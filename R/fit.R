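# Model specification, maximum marginal likelihood fitting, uncertainty
# (Fisher information by finite differences), information criteria and
# individual MAP (Bayesian forecasting) estimation.

PB_TRANSFORMS <- c(CL_pop = "log", beta_wt = "id", beta_age = "id",
                   beta_sex = "id", Kenz = "log", IC50 = "log",
                   omega_CL = "log", sigma_add = "log")
PB_INITS <- c(CL_pop = 0.01, beta_wt = 0.75, beta_age = 0, beta_sex = 0,
              Kenz = 0.1, IC50 = 1, omega_CL = 0.2, sigma_add = 1)
# plausibility boxes on the transformed scale: canine phenobarbital
# CL/F below 1 L/h, enzyme turnover slower than ~30 min, IC50 within
# the assay's dynamic range. They keep the optimizer off degenerate
# branches (e.g. Kenz -> Inf mimics instantaneous induction).
PB_LOWER <- c(CL_pop = log(1e-4), beta_wt = -5, beta_age = -5,
              beta_sex = -5, Kenz = log(1e-3), IC50 = log(1e-2),
              omega_CL = log(1e-3), sigma_add = log(1e-3))
PB_UPPER <- c(CL_pop = log(1), beta_wt = 5, beta_age = 5, beta_sex = 5,
              Kenz = log(2), IC50 = log(200), omega_CL = log(2),
              sigma_add = log(50))
# parameters tied to CL/F (the parameter carrying the random effect) get
# the per-subject BIC penalty; the rest the per-observation penalty
PB_RANDOM_RELATED <- c("CL_pop", "beta_wt", "beta_age", "beta_sex",
                       "omega_CL")

#' Model specification for estimation
#'
#' Declares the covariate structure on CL/F and which parameters are
#' estimated. Absorption (`ka`) and the reference volume (`V_ref`) are
#' always fixed (sparse trough data cannot identify them). The weight
#' covariate is either allometric with the exponent fixed at 3/4 (the
#' final model), a power model with estimated exponent, or absent; age
#' enters as a power of age/5; sex as an exponential factor on CL/F.
#'
#' @param weight_cov `"allometric"` (fixed exponent 0.75), `"power"`
#'   (estimated exponent) or `"none"`.
#' @param age_cov `"power"` or `"none"`.
#' @param sex_cov `"none"` or `"exponential"`.
#' @param estimate character vector of estimated parameters; defaults to
#'   `CL_pop`, `Kenz`, `IC50`, `omega_CL`, `sigma_add` plus the exponents
#'   implied by the covariate choices.
#' @param fixed named list overriding default fixed values (e.g.
#'   `list(ka = 0.61)`).
#' @return A list of class `pb_model_spec`.
#' @export
model_spec <- function(weight_cov = c("allometric", "power", "none"),
                       age_cov = c("power", "none"),
                       sex_cov = c("none", "exponential"),
                       estimate = NULL, fixed = list()) {
  weight_cov <- match.arg(weight_cov)
  age_cov <- match.arg(age_cov)
  sex_cov <- match.arg(sex_cov)
  if (is.null(estimate)) {
    estimate <- c("CL_pop",
                  if (weight_cov == "power") "beta_wt",
                  if (age_cov == "power") "beta_age",
                  if (sex_cov == "exponential") "beta_sex",
                  "Kenz", "IC50", "omega_CL", "sigma_add")
  }
  if (!"CL_pop" %in% estimate) stop("CL_pop must be estimated")
  bad <- setdiff(estimate, names(PB_TRANSFORMS))
  if (length(bad)) stop("cannot estimate: ", paste(bad, collapse = ", "))
  if (("beta_wt" %in% estimate) != (weight_cov == "power"))
    stop("beta_wt is estimated exactly when weight_cov == \"power\"")
  if (("beta_age" %in% estimate) && age_cov != "power")
    stop("beta_age requires age_cov == \"power\"")
  if (("beta_sex" %in% estimate) && sex_cov != "exponential")
    stop("beta_sex requires sex_cov == \"exponential\"")
  structure(list(weight_cov = weight_cov, age_cov = age_cov,
                 sex_cov = sex_cov, estimate = estimate, fixed = fixed),
            class = "pb_model_spec")
}

spec_base_values <- function(spec) {
  vals <- PB_INITS
  vals["beta_wt"] <- switch(spec$weight_cov, allometric = 0.75,
                            power = PB_INITS["beta_wt"], none = 0)
  if (spec$age_cov == "none") vals["beta_age"] <- 0
  if (spec$sex_cov == "none") vals["beta_sex"] <- 0
  vals
}

# assemble a pb_params from transformed estimated values + spec
spec_params <- function(spec, theta, base = NULL) {
  vals <- if (is.null(base)) spec_base_values(spec) else base
  for (nm in names(theta)) {
    vals[nm] <- if (PB_TRANSFORMS[nm] == "log") exp(theta[[nm]])
                else theta[[nm]]
  }
  args <- as.list(vals)
  args$ka <- spec$fixed$ka %||% 0.6
  args$V_ref <- spec$fixed$V_ref %||% 20
  for (nm in setdiff(names(spec$fixed), c("ka", "V_ref")))
    args[[nm]] <- spec$fixed[[nm]]
  do.call(pb_params, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

to_trans <- function(x) {
  out <- x
  isl <- PB_TRANSFORMS[names(x)] == "log"
  out[isl] <- log(x[isl])
  out
}

#' Fit the autoinduction NLME model by maximum marginal likelihood
#'
#' Maximizes the Gauss-Hermite marginal likelihood
#' ([marginal_neg2loglik()]) over the estimated parameters, with positive
#' parameters log-transformed (covariate exponents unconstrained), using
#' the PORT quasi-Newton optimizer (`nlminb`). The fit is deterministic
#' given the data and initial values.
#'
#' @param data an event table.
#' @param spec a [model_spec()].
#' @param init named numeric vector of natural-scale initial values for
#'   (a subset of) the estimated parameters.
#' @param n_nodes quadrature nodes for the marginal likelihood.
#' @param control passed to [stats::nlminb()] (defaults
#'   `eval.max = 2000`, `iter.max = 500`).
#' @return An object of class `pb_fit`: estimates (a [pb_params()]),
#'   OFV, convergence metadata, per-subject MAP `eta` and shrinkage.
#' @export
fit_model <- function(data, spec = model_spec(), init = NULL,
                      n_nodes = 32, control = list()) {
  stopifnot(inherits(spec, "pb_model_spec"))
  validate_event_table(data)
  n_obs <- sum(data$EVID == 0L & data$MDV == 0L)
  n_sub <- length(unique(data$ID[data$EVID == 0L & data$MDV == 0L]))
  if (n_obs < length(spec$estimate))
    warning("fewer usable observations (", n_obs,
            ") than estimated parameters (", length(spec$estimate), ")")
  start_nat <- spec_base_values(spec)[spec$estimate]
  if (!is.null(init)) {
    ok <- intersect(names(init), spec$estimate)
    start_nat[ok] <- init[ok]
  }
  theta0 <- to_trans(start_nat)
  objective <- function(theta) {
    names(theta) <- spec$estimate
    p <- tryCatch(spec_params(spec, theta), error = function(e) NULL)
    if (is.null(p)) return(1e10)
    ofv <- tryCatch(
      marginal_neg2loglik(data, p, n_nodes = n_nodes),
      error = function(e) NA_real_)
    if (!is.finite(ofv)) 1e10 else ofv
  }
  ctl <- modifyList(list(eval.max = 2000, iter.max = 500), control)
  opt <- nlminb(theta0, objective, lower = PB_LOWER[spec$estimate],
                upper = PB_UPPER[spec$estimate], control = ctl)
  theta_hat <- setNames(opt$par, spec$estimate)
  params_hat <- spec_params(spec, theta_hat)
  det <- marginal_neg2loglik(data, params_hat, n_nodes = n_nodes,
                             details = TRUE)
  eta_map <- det$eta_mode
  shrink <- if (params_hat$omega_CL > 0 && length(eta_map) > 1)
    1 - sd(eta_map) / params_hat$omega_CL else NA_real_
  converged <- opt$convergence == 0
  if (!converged)
    warning("optimizer did not report convergence: ", opt$message,
            " (best iterate returned)")
  at_bound <- names(theta_hat)[
    theta_hat <= PB_LOWER[spec$estimate] + 1e-8 |
      theta_hat >= PB_UPPER[spec$estimate] - 1e-8]
  if (length(at_bound))
    warning("estimate(s) at plausibility bound: ",
            paste(at_bound, collapse = ", "))
  structure(list(
    estimates = params_hat, theta = theta_hat, estimated = spec$estimate,
    spec = spec, ofv = det$ofv, n_nodes = n_nodes,
    convergence = list(converged = converged, code = opt$convergence,
                       message = opt$message,
                       iterations = opt$iterations,
                       evaluations = opt$evaluations),
    eta_map = eta_map, shrinkage = shrink,
    n_subjects = n_sub, n_obs = n_obs
  ), class = "pb_fit")
}

#' @export
print.pb_fit <- function(x, ...) {
  cat("Autoinduction popPK fit:", x$n_subjects, "subjects,",
      x$n_obs, "observations\n")
  cat(sprintf("OFV (-2LL): %.3f   converged: %s\n", x$ofv,
              x$convergence$converged))
  est <- unlist(x$estimates[names(PB_TRANSFORMS)])
  tag <- ifelse(names(est) %in% x$estimated, "estimated", "fixed")
  for (i in seq_along(est))
    cat(sprintf("  %-9s %10.4g  (%s)\n", names(est)[i], est[i], tag[i]))
  cat(sprintf("  eta shrinkage: %.1f%%\n", 100 * x$shrinkage))
  invisible(x)
}

#' Standard errors from the Fisher information matrix
#'
#' Computes the numerical Hessian of OFV/2 at the optimum by central
#' finite differences on the transformed scale (relative step `1e-4`),
#' inverts it, and back-transforms the standard errors to the natural
#' scale by the delta method. Fixed parameters carry no SE.
#'
#' @param fit a [fit_model()] result.
#' @param data the event table the model was fitted to.
#' @param rel_step relative finite-difference step.
#' @return Data frame with columns `parameter`, `estimate`, `se`,
#'   `rse_pct` and attribute `ok` (`FALSE` when the Hessian is not
#'   positive definite, in which case SEs are `NA`).
#' @export
compute_rse <- function(fit, data, rel_step = 1e-4) {
  stopifnot(inherits(fit, "pb_fit"))
  spec <- fit$spec
  theta <- fit$theta
  p <- length(theta)
  f <- function(th) {
    names(th) <- spec$estimate
    marginal_neg2loglik(data, spec_params(spec, th),
                        n_nodes = fit$n_nodes) / 2
  }
  h <- rel_step * pmax(abs(theta), 1)
  H <- matrix(NA_real_, p, p)
  f0 <- f(theta)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h[i])
    H[i, i] <- (f(theta + ei) - 2 * f0 + f(theta - ei)) / h[i]^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- replace(numeric(p), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(theta + ei + ej) - f(theta + ei - ej) -
           f(theta - ei + ej) + f(theta - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  cov_t <- tryCatch(solve(H), error = function(e) NULL)
  ok <- !is.null(cov_t) && all(diag(cov_t) > 0)
  if (!ok)
    warning("Fisher information matrix not positive definite; no SEs")
  est_nat <- unlist(fit$estimates[spec$estimate])
  se_nat <- rep(NA_real_, p)
  if (ok) {
    se_t <- sqrt(diag(cov_t))
    isl <- PB_TRANSFORMS[spec$estimate] == "log"
    se_nat <- ifelse(isl, abs(est_nat) * se_t, se_t)
  }
  fixed_par <- c("ka", "V_ref", setdiff(names(PB_TRANSFORMS), spec$estimate))
  out <- rbind(
    data.frame(parameter = spec$estimate, estimate = est_nat,
               se = se_nat, rse_pct = 100 * se_nat / abs(est_nat)),
    data.frame(parameter = fixed_par,
               estimate = unlist(fit$estimates[fixed_par]),
               se = NA_real_, rse_pct = NA_real_))
  rownames(out) <- NULL
  attr(out, "ok") <- ok
  out
}

#' Corrected Bayesian information criterion
#'
#' Hybrid-penalty BIC for mixed-effects models: parameters tied to the
#' subject-level random effect (here everything on CL/F, including its
#' covariate exponents and `omega_CL`) are penalized by `log(N_subjects)`,
#' purely fixed-effect and residual-error parameters by
#' `log(N_observations)`. When every subject contributes one observation
#' the two penalties coincide and the classical BIC is recovered.
#'
#' @param fit a [fit_model()] result.
#' @return The BICc value.
#' @export
bicc <- function(fit) {
  stopifnot(inherits(fit, "pb_fit"))
  nR <- sum(fit$estimated %in% PB_RANDOM_RELATED)
  nF <- sum(!fit$estimated %in% PB_RANDOM_RELATED)
  fit$ofv + nR * log(fit$n_subjects) + nF * log(fit$n_obs)
}

#' Likelihood ratio test between nested fits
#'
#' `delta_OFV = OFV_reduced - OFV_full`, referred to a chi-square with
#' `df` degrees of freedom. A small negative delta (within numerical
#' tolerance) is clamped to zero; a larger one signals an optimizer
#' failure and triggers a warning.
#'
#' @param fit_reduced,fit_full nested [fit_model()] results fitted to the
#'   same data (or raw OFV numbers, in which case `df` is required).
#' @param df degrees of freedom; defaults to the difference in the number
#'   of estimated parameters.
#' @return List with `delta_ofv`, `df`, `p_value`.
#' @export
lrt <- function(fit_reduced, fit_full, df = NULL) {
  ofv_r <- if (inherits(fit_reduced, "pb_fit")) fit_reduced$ofv
           else as.numeric(fit_reduced)
  ofv_f <- if (inherits(fit_full, "pb_fit")) fit_full$ofv
           else as.numeric(fit_full)
  if (is.null(df)) {
    if (!inherits(fit_reduced, "pb_fit") || !inherits(fit_full, "pb_fit"))
      stop("df must be given when raw OFVs are supplied")
    df <- length(fit_full$estimated) - length(fit_reduced$estimated)
  }
  if (df < 0) stop("models are not nested as given (df < 0)")
  delta <- ofv_r - ofv_f
  if (delta < 0) {
    if (delta > -1e-6) delta <- 0
    else warning("negative delta OFV (", format(delta),
                 "): likely optimizer failure in the full model")
  }
  p <- if (df == 0) NA_real_ else
    pchisq(max(delta, 0), df, lower.tail = FALSE)
  list(delta_ofv = delta, df = df, p_value = p)
}

#' Wald test for an estimated parameter
#'
#' Two-sided normal-approximation test of `estimate / SE` against zero,
#' on the natural scale for covariate exponents.
#'
#' @param rse_table a [compute_rse()] result.
#' @param parameter parameter name.
#' @return List with `z` and `p_value`.
#' @export
wald_test <- function(rse_table, parameter) {
  row <- rse_table[rse_table$parameter == parameter, ]
  if (nrow(row) != 1L || is.na(row$se))
    stop("no SE available for parameter ", parameter)
  z <- row$estimate / row$se
  list(z = z, p_value = 2 * pnorm(-abs(z)))
}

#' Individual MAP estimation (Bayesian forecasting)
#'
#' Maximizes the posterior of a subject's clearance random effect,
#' `log p(obs | eta) + log phi(eta; 0, omega^2)`, given the population
#' model: the basis of model-informed precision dosing. With no
#' observations (or `omega_CL = 0`) the prior mode `eta = 0` is returned.
#'
#' @param subject a single-subject event table, or a record as produced
#'   internally (list with `weight`, `age`, `sex`, `obs_time`, `dv`,
#'   `dose_time`, `dose_amt`).
#' @param pop a [pb_params()] object.
#' @param prior include the population prior (setting `FALSE` gives the
#'   unpenalized individual maximum-likelihood `eta`, useful to quantify
#'   shrinkage).
#' @return List with `eta`, `CL_i`, `V_i` and `predictions` (data frame
#'   of observation times and MAP-predicted concentrations).
#' @export
map_individual <- function(subject, pop, prior = TRUE) {
  stopifnot(inherits(pop, "pb_params"))
  if (is.data.frame(subject)) {
    recs <- subject_records(subject)
    if (length(recs) != 1L)
      stop("subject must contain exactly one ID")
    subject <- recs[[1]]
  }
  if (is.null(subject$weight) || is.null(subject$age))
    stop("subject covariates (weight, age) are required")
  rec <- subject_scales(list(subject), pop)[[1]]
  omega <- pop$omega_CL
  predfun <- direct_predictor(rec, pop)
  eta_hat <- 0
  if (length(rec$obs_time) > 0 && (omega > 0 || !prior)) {
    lj <- subject_logjoint(rec$dv, predfun, pop$sigma_add,
                           if (prior) omega else 0)
    b <- if (prior) 6 * omega + 0.5 else 3
    op <- optimize(lj, c(-b, b), maximum = TRUE, tol = 1e-8)
    eta_hat <- op$maximum
  }
  preds <- if (length(rec$obs_time))
    data.frame(time = rec$obs_time, pred = predfun(eta_hat)[, 1])
  else data.frame(time = numeric(0), pred = numeric(0))
  list(eta = eta_hat,
       CL_i = individual_clearance(pop, rec$weight, rec$age, rec$sex,
                                   eta_hat),
       V_i = rec$V_i, predictions = preds)
}
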