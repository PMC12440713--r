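# Model-evaluation toolbox: external-validation error metrics, normalized
# prediction distribution errors (NPDE), and a simplified / prediction-
# corrected visual predictive check on predose concentrations.

#' Prediction error metrics (ME, MRE, RMSE)
#'
#' Bias and precision of model predictions against observations:
#' \deqn{ME = \sum (pred - obs) / n \quad (mg/L)}
#' \deqn{MRE = 100 \sum ((pred - obs)/obs) / n \quad (\%)}
#' \deqn{RMSE = 100 \sqrt{\sum ((pred - obs)/obs)^2 / n} \quad (\%)}
#' Overprediction gives positive ME. Observations equal to zero cannot
#' enter the relative metrics and are excluded with a warning.
#'
#' @param observed,predicted numeric vectors, mg/L.
#' @return List with `me`, `mre`, `rmse`, `n`.
#' @examples
#' validation_metrics(observed = c(10, 20), predicted = c(11, 18))
#' # ME -0.5 mg/L, MRE 0%, RMSE 10%
#' @export
validation_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length")
  if (!length(observed)) stop("no observations")
  keep <- observed > 0
  if (any(!keep)) {
    warning(sum(!keep), " observation(s) <= 0 excluded from metrics")
    observed <- observed[keep]; predicted <- predicted[keep]
  }
  if (!length(observed)) stop("no positive observations")
  err <- predicted - observed
  rel <- err / observed
  list(me = mean(err), mre = 100 * mean(rel),
       rmse = 100 * sqrt(mean(rel^2)), n = length(observed))
}

# Simulate K replicate observation matrices for each subject under the
# population model (shared-design spline cache when possible).
simulate_replicates <- function(records, pop, K) {
  preds <- make_predictors(records, pop,
                           span = 4.5 * pop$omega_CL + 0.1)
  n <- length(records)
  etas <- matrix(rnorm(n * K, 0, pop$omega_CL), n, K)
  sims <- vector("list", n)
  for (i in seq_len(n)) {
    f <- preds[[i]](etas[i, ])
    sims[[i]] <- f + rnorm(length(f), 0, pop$sigma_add)
  }
  sims   # each [n_obs_i x K]
}

#' Normalized prediction distribution errors
#'
#' Simulates `K` replicates of the dataset under the population model,
#' decorrelates each subject's observation vector with the empirical
#' mean and Cholesky factor of its simulated covariance, and maps the
#' rank of each decorrelated observation among its decorrelated
#' simulations through the inverse normal. Under a correct model the
#' NPDE are standard normal. Ties are broken by seeded uniform jitter;
#' for subjects with a single observation the decorrelation reduces to
#' marginal standardization.
#'
#' @param data an event table.
#' @param pop a [pb_params()] object.
#' @param K number of simulated replicates (>= 500 recommended).
#' @param seed integer seed.
#' @return List of class `pb_npde`: `values` (data frame `ID`, `TIME`,
#'   `npde`), `mean`, `variance`, `t_p` (t-test of mean 0), `shapiro_p`
#'   (normality).
#' @export
npde <- function(data, pop, K = 1000, seed = NULL) {
  stopifnot(inherits(pop, "pb_params"), K >= 2)
  records <- subject_records(data)
  records <- Filter(function(r) length(r$obs_time) > 0, records)
  with_seed(seed, {
    sims <- simulate_replicates(records, pop, K)
    vals <- lapply(seq_along(records), function(i) {
      y <- records[[i]]$dv
      S <- sims[[i]]
      m <- rowMeans(S)
      Sc <- S - m
      if (length(y) == 1L) {
        L <- matrix(sqrt(mean(Sc^2)), 1, 1)
      } else {
        V <- (Sc %*% t(Sc)) / (K - 1)
        L <- t(chol(V))
      }
      ystar <- forwardsolve(L, y - m)
      sstar <- forwardsolve(L, Sc)
      pde <- vapply(seq_along(y), function(j) {
        less <- sum(sstar[j, ] < ystar[j])
        ties <- sum(sstar[j, ] == ystar[j])
        (less + runif(1) * (ties + 1)) / (K + 1)
      }, numeric(1))
      data.frame(ID = records[[i]]$id, TIME = records[[i]]$obs_time,
                 npde = qnorm(pde))
    })
    out <- do.call(rbind, vals)
    n <- nrow(out)
    tstat <- mean(out$npde) / (sd(out$npde) / sqrt(n))
    structure(list(values = out, mean = mean(out$npde),
                   variance = var(out$npde),
                   t_p = 2 * stats::pt(-abs(tstat), n - 1),
                   shapiro_p = shapiro.test(out$npde)$p.value),
              class = "pb_npde")
  })
}

#' Visual predictive check on predose concentrations
#'
#' Simplified VPC for sparse trough data: predose observations are binned
#' (by weight tertile by default), observed percentiles (5/50/95) are
#' overlaid on the envelope of the same percentiles across `K` datasets
#' simulated from the population model. With `prediction_corrected =
#' TRUE` each observation (and simulation) is rescaled by the ratio of
#' its bin's median population prediction to the subject's own population
#' prediction, normalizing out dose and covariate differences within
#' bins.
#'
#' @param data an event table containing predose observations.
#' @param pop a [pb_params()] object.
#' @param K number of simulated replicate datasets.
#' @param bins either `"weight_tertile"` or explicit numeric weight
#'   break points.
#' @param seed integer seed.
#' @param prediction_corrected logical.
#' @param ci envelope coverage for the simulated percentile bands.
#' @return List of class `pb_vpc` with `observed` (per-bin observed
#'   percentiles), `simulated` (per-bin envelope for each percentile),
#'   `bins`, and `correction` (per-observation factors, 1 when
#'   uncorrected).
#' @export
vpc_predose <- function(data, pop, K = 500, bins = "weight_tertile",
                        seed = NULL, prediction_corrected = FALSE,
                        ci = 0.90) {
  stopifnot(inherits(pop, "pb_params"), K >= 1)
  records <- subject_records(data)
  records <- Filter(function(r) length(r$obs_time) > 0, records)
  if (!length(records)) stop("no observations for VPC")
  wt <- vapply(records, `[[`, numeric(1), "weight")
  nobs <- vapply(records, function(r) length(r$obs_time), integer(1))
  wt_obs <- rep(wt, nobs)
  obs <- unlist(lapply(records, `[[`, "dv"))
  if (identical(bins, "weight_tertile")) {
    brk <- unique(quantile(wt_obs, c(0, 1 / 3, 2 / 3, 1)))
    if (length(brk) < 3) brk <- range(wt_obs) + c(-1, 1)
  } else brk <- sort(unique(bins))
  bin_id <- cut(wt_obs, brk, include.lowest = TRUE)
  # merge empty bins into their lower neighbour
  counts <- table(bin_id)
  if (any(counts == 0)) {
    warning("empty VPC bin(s) merged with neighbours")
    brk <- brk[-(which(counts == 0) + 1L)]
    bin_id <- cut(wt_obs, brk, include.lowest = TRUE)
  }
  probs <- c(0.05, 0.5, 0.95)
  with_seed(seed, {
    # population predictions (eta = 0) for prediction correction
    corr <- rep(1, length(obs))
    if (prediction_corrected) {
      ppred <- unlist(lapply(records, function(r) {
        rec <- subject_scales(list(r), pop)[[1]]
        direct_predictor(rec, pop)(0)[, 1]
      }))
      med_by_bin <- tapply(ppred, bin_id, median)
      corr <- unname(as.numeric(med_by_bin[bin_id]) / ppred)
    }
    sims <- simulate_replicates(records, pop, K)
    simmat <- do.call(rbind, sims)          # [n_obs_total x K]
    obs_c <- obs * corr
    simmat_c <- simmat * corr
    observed <- do.call(rbind, lapply(levels(bin_id), function(b) {
      q <- quantile(obs_c[bin_id == b], probs)
      data.frame(bin = b, n = sum(bin_id == b),
                 p5 = q[1], p50 = q[2], p95 = q[3])
    }))
    a <- (1 - ci) / 2
    simulated <- do.call(rbind, lapply(levels(bin_id), function(b) {
      sel <- bin_id == b
      per_rep <- apply(simmat_c[sel, , drop = FALSE], 2, quantile,
                       probs = probs)     # [3 x K]
      do.call(rbind, lapply(seq_along(probs), function(j) {
        data.frame(bin = b, percentile = 100 * probs[j],
                   lower = quantile(per_rep[j, ], a),
                   median = quantile(per_rep[j, ], 0.5),
                   upper = quantile(per_rep[j, ], 1 - a))
      }))
    }))
    rownames(observed) <- rownames(simulated) <- NULL
    structure(list(observed = observed, simulated = simulated,
                   bins = brk, correction = corr,
                   prediction_corrected = prediction_corrected, K = K),
              class = "pb_vpc")
  })
}

#' External validation of a population model
#'
#' Computes [validation_metrics()] on an external dataset in the two
#' prediction modes used for model qualification: *a priori* (population
#' prediction from covariates only, `eta = 0`) and *MAP-updated*
#' (per-subject Bayesian update from that subject's own observations,
#' after which the same observations are predicted; this measures how
#' well the model explains a patient's data once individualized, and by
#' shrinkage can only improve the fit to those observations).
#'
#' @param validation_data an event table, disjoint from the training
#'   data.
#' @param pop a [pb_params()] object (the fitted population model).
#' @return List with `a_priori` and `map_updated` metric lists and
#'   `pairs` (per-observation data frame with both predictions).
#' @export
external_validate <- function(validation_data, pop) {
  stopifnot(inherits(pop, "pb_params"))
  records <- subject_records(validation_data)
  records <- Filter(function(r) length(r$obs_time) > 0, records)
  keep <- vapply(records, function(r)
    is.finite(r$weight) && is.finite(r$age), logical(1))
  if (any(!keep))
    warning(sum(!keep), " subject(s) without covariates excluded")
  records <- records[keep]
  if (!length(records)) stop("empty validation set")
  pairs <- do.call(rbind, lapply(records, function(r) {
    rec <- subject_scales(list(r), pop)[[1]]
    apriori <- direct_predictor(rec, pop)(0)[, 1]
    mapfit <- map_individual(r, pop)
    data.frame(ID = r$id, TIME = r$obs_time, observed = r$dv,
               pred_a_priori = apriori, pred_map = mapfit$predictions$pred,
               eta_map = mapfit$eta)
  }))
  list(a_priori = validation_metrics(pairs$observed, pairs$pred_a_priori),
       map_updated = validation_metrics(pairs$observed, pairs$pred_map),
       pairs = pairs)
}
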