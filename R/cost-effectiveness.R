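#' Cost and utility schedule for the cost-effectiveness model
#'
#' Holds the one-off initial cost of each treatment policy, the daily cost of
#' a day spent in each state under each policy, the per-state utility weights
#' (QALY-years per year alive in the state), the annual discount rate applied
#' identically to costs and QALYs, the horizon in days, and the
#' willingness-to-pay grid.
#'
#' Discounting uses the daily factor `rho = (1 + annual)^(-1/365)`; day `t`
#' contributions are multiplied by `rho^t`, and the initial cost is not
#' discounted.  A day in state `s` accrues `utility[s] / 365` QALYs.
#'
#' @param initial_cost length-2 vector `c(aad = , icd = )` of policy start-up
#'   costs (money).
#' @param daily_cost matrix (states x 2, columns `aad`, `icd`) of per-day
#'   state costs (money/day).
#' @param utility per-state utility weights in `[0, 1]`; must be 0 for states
#'   with zero cost that are absorbing (death).
#' @param annual_discount annual discount rate (fraction/year, in `[0, 1)`).
#' @param horizon_days time horizon T in days.
#' @param lambda willingness-to-pay grid (money per QALY).
#' @param space the [state_space()] the costs refer to.
#' @return object of class `cost_schedule`.
#' @seealso [icd_cost_schedule()] for the device-vs-drug schedule.
#' @export
cost_schedule <- function(initial_cost, daily_cost, utility,
                          annual_discount = 0.035, horizon_days,
                          lambda = 20000, space) {
  stopifnot(inherits(space, "state_space"))
  daily_cost <- as.matrix(daily_cost)
  stopifnot(length(initial_cost) == 2L, ncol(daily_cost) == 2L,
            nrow(daily_cost) == space$n, length(utility) == space$n)
  if (any(daily_cost < 0)) stopf("daily costs must be non-negative")
  if (annual_discount < 0 || annual_discount >= 1) stopf("discount rate must be in [0,1)")
  for (a in space$absorbing)
    if (any(daily_cost[a, ] != 0) || utility[a] != 0)
      stopf("absorbing (death) state %d must have zero cost and utility", a)
  structure(list(initial_cost = setNames(as.numeric(initial_cost), c("aad", "icd")),
                 daily_cost = daily_cost, utility = as.numeric(utility),
                 annual_discount = annual_discount,
                 daily_factor = daily_discount_factor(annual_discount),
                 horizon_days = as.integer(horizon_days),
                 lambda = as.numeric(lambda), space = space),
            class = "cost_schedule")
}

#' Daily discount factor from an annual rate
#' @param annual annual discount rate (fraction/year).
#' @return `(1 + annual)^(-1/365)`.
#' @export
daily_discount_factor <- function(annual) (1 + annual)^(-1 / 365)

#' Device-versus-drug cost schedule (UK costing)
#'
#' Initial costs of 23841 (device implantation) and 1566 (drug initiation);
#' daily state costs of 2.30/2.43 out of hospital (device/drug), 526
#' (arrhythmic admission), 519.50 (other cardiac), 296.50 (non-cardiac), 646
#' (device maintenance), 5495.50 (device replacement), 122 (drug side
#' effects) and 0 (death), hospital costs common to both arms; utility 0.75
#' in every alive state; 3.5%/year discounting of both costs and QALYs; a
#' 100-year horizon.
#'
#' @param lambda willingness-to-pay grid (default 20000/QALY).
#' @return a [cost_schedule()] on [icd_state_space()].
#' @export
icd_cost_schedule <- function(lambda = 20000) {
  common <- c(526, 519.50, 296.50, 646, 5495.50, 122, 0)
  cost_schedule(initial_cost = c(aad = 1566, icd = 23841),
                daily_cost = cbind(aad = c(2.43, common), icd = c(2.30, common)),
                utility = c(rep(0.75, 7), 0),
                annual_discount = 0.035, horizon_days = 100L * 365L,
                lambda = lambda, space = icd_state_space())
}

#' Patient profile for cohort projection
#'
#' The covariate values (fractional values allowed, e.g. `female = 0.13` for
#' a mixed-sex cohort) and starting age of the person whose lifetime costs
#' and QALYs are projected.  The treatment covariate is set by the projection
#' itself (one run per policy), so it is not part of the profile.
#'
#' @param age starting age in years.
#' @param covariates named list of baseline covariate values other than
#'   treatment.
#' @return object of class `patient_profile`.
#' @export
patient_profile <- function(age, covariates = list()) {
  structure(list(age = age, covariates = covariates), class = "patient_profile")
}

#' The "typical patient" of the device-vs-drug analysis
#'
#' Age 63 at treatment start, low ejection fraction, 13% female (the cohort
#' sex mix entered as a fractional covariate), treated in the UK (the country
#' covariate is configurable as the source data span two countries).
#'
#' @param uk country covariate value (default 1 = UK).
#' @return a [patient_profile()].
#' @export
typical_patient <- function(uk = 1) {
  patient_profile(age = 63, covariates = list(female = 0.13, lvef = 1, uk = uk))
}

# daily transition-matrix regimes for a profile under treatment covariate
# value `treat`: returns list(cube = R x R x n_regime array, regime = day ->
# slice map of length T).  Slices are deduplicated across days whose
# covariate vectors coincide (piecewise age gives <= 3 slices; polynomial age
# gives one per day).
build_day_regimes <- function(theta, config, profile, treat, T) {
  R <- config$space$n
  ages <- profile$age + seq_len(T) / 365
  tr <- config$age_transform
  if (tr$type == "piecewise") {          # few slices: one per age band present
    band <- findInterval(ages, tr$cutpoints)
    uidx <- which(!duplicated(band))
    regime <- match(band, band[uidx])
  } else if (tr$type == "polynomial") {  # age varies every day
    uidx <- seq_len(T)
    regime <- uidx
  } else {
    uidx <- 1L
    regime <- rep(1L, T)
  }
  df <- as.data.frame(c(list(treat = treat), profile$covariates))
  df <- df[rep(1L, length(uidx)), , drop = FALSE]
  df$age <- ages[uidx]
  Xu <- cbind(1, covariate_matrix(config, df))
  nreg <- nrow(Xu)
  cube <- array(0, dim = c(R, R, nreg))
  for (r in seq_len(R)) {
    if (r %in% config$space$absorbing) { cube[r, r, ] <- 1; next }
    cm <- config$coef_maps[[r]]
    eta <- cbind(0, Xu %*% row_beta(theta, config, r))
    m <- eta[, 1L]
    for (j in seq_len(ncol(eta) - 1L) + 1L) m <- pmax(m, eta[, j])
    w <- exp(eta - m)
    pr <- w / rowSums(w)
    cube[r, c(cm$ref, cm$dests), ] <- t(pr)
  }
  list(cube = cube, regime = as.integer(regime))
}

#' State-occupancy distribution after t days
#'
#' Starting from probability 1 in state 1 at day 0, propagates
#' `pi_t = pi_(t-1) P_t` with the daily transition matrix rebuilt as the
#' patient ages (age advanced by `t/365` years each day).
#'
#' @param theta free-parameter vector.
#' @param config a [model_config()].
#' @param profile a [patient_profile()].
#' @param t day (`t = 0` returns the starting vector).
#' @param treat treatment covariate value used in the projection (1 = drug
#'   arm, 0 = device arm), when the configuration includes `treat`.
#' @return occupancy probability vector over the states.
#' @export
propagate_occupancy <- function(theta, config, profile, t, treat = 0) {
  R <- config$space$n
  pi0 <- c(1, numeric(R - 1L))
  names(pi0) <- config$space$states
  if (t == 0L) return(pi0)
  reg <- build_day_regimes(theta, config, profile, treat, t)
  setNames(cpp_propagate(reg$cube, reg$regime, pi0, as.integer(t)),
           config$space$states)
}

#' Lifetime expected discounted cost and QALYs for one policy
#'
#' Implements the cohort sum: expected cost is the initial cost plus
#' `sum_t rho^t (pi_t . c_u)`; expected benefit replaces the cost vector with
#' `utility/365` (QALYs per day) under identical discounting.
#'
#' @inheritParams propagate_occupancy
#' @param schedule a [cost_schedule()].
#' @param u policy indicator: 1 = device (ICD), 0 = drug (AAD).  Sets both the
#'   initial/daily cost column and the treatment covariate (which codes drug
#'   therapy as 1).
#' @return named vector `c(cost = E(C_u), qaly = E(B_u))`.
#' @export
expected_cost_benefit <- function(theta, config, profile, schedule, u) {
  stopifnot(u %in% c(0, 1), all(is.finite(theta)))
  arm <- if (u == 1) "icd" else "aad"
  treat <- if (u == 1) 0 else 1          # covariate codes drug therapy as 1
  T <- schedule$horizon_days
  if (T == 0L)
    return(c(cost = unname(schedule$initial_cost[arm]), qaly = 0))
  reg <- build_day_regimes(theta, config, profile, treat, T)
  disc <- schedule$daily_factor^seq_len(T)
  acc <- cpp_ce_accumulate(reg$cube, reg$regime,
                           c(1, numeric(config$space$n - 1L)), disc,
                           schedule$daily_cost[, arm], schedule$utility / 365)
  c(cost = unname(schedule$initial_cost[arm]) + acc[1L], qaly = acc[2L])
}

#' Microsimulation estimate of lifetime cost and QALYs (stochastic oracle)
#'
#' Simulates `n` individual daily trajectories under the same day-varying
#' transition matrices as [expected_cost_benefit()] and averages their
#' discounted costs and QALYs.  This is the package's independent check of
#' the cohort (matrix-propagation) sum: the two agree within Monte-Carlo
#' error.
#'
#' @inheritParams expected_cost_benefit
#' @param n number of simulated individuals.
#' @param seed RNG seed.
#' @return list with means `cost` and `qaly`, their Monte-Carlo standard
#'   errors `cost_se`, `qaly_se`, and `n`.
#' @export
simulate_ce_microsim <- function(theta, config, profile, schedule, u, n,
                                 seed = 1L) {
  stopifnot(u %in% c(0, 1))
  arm <- if (u == 1) "icd" else "aad"
  treat <- if (u == 1) 0 else 1
  T <- schedule$horizon_days
  reg <- build_day_regimes(theta, config, profile, treat, T)
  disc <- schedule$daily_factor^seq_len(T)
  absorbing <- seq_len(config$space$n) %in% config$space$absorbing
  set.seed(as.integer(seed))
  sims <- cpp_microsim(reg$cube, reg$regime, 1L, disc,
                       schedule$daily_cost[, arm], schedule$utility / 365,
                       absorbing, as.integer(n))
  list(cost = unname(schedule$initial_cost[arm]) + mean(sims[, 1L]),
       qaly = mean(sims[, 2L]),
       cost_se = stats::sd(sims[, 1L]) / sqrt(n),
       qaly_se = stats::sd(sims[, 2L]) / sqrt(n), n = n)
}

#' One-stage probabilistic sensitivity analysis of incremental cost and QALYs
#'
#' Evaluates [expected_cost_benefit()] under both policies at every posterior
#' draw, so the returned per-draw incremental cost and QALYs are a sample
#' from their joint posterior (parameter uncertainty fully propagated,
#' correlations included).
#'
#' @param sample a [sample_posterior()] result.
#' @param config the fitted [model_config()].
#' @param profile a [patient_profile()].
#' @param schedule a [cost_schedule()].
#' @param draws optional indices of posterior draws to use (default all).
#' @return object of class `ce_result`: per-draw `cost1`, `qaly1` (device),
#'   `cost0`, `qaly0` (drug), `dC`, `dB`, with the schedule attached.
#' @export
run_ce <- function(sample, config, profile, schedule, draws = NULL) {
  idx <- draws %||% seq_len(nrow(sample$draws))
  stopifnot(length(idx) >= 1L)
  out <- matrix(NA_real_, length(idx), 4L,
                dimnames = list(NULL, c("cost1", "qaly1", "cost0", "qaly0")))
  for (i in seq_along(idx)) {
    th <- sample$draws[idx[i], ]
    out[i, 1:2] <- expected_cost_benefit(th, config, profile, schedule, u = 1)
    out[i, 3:4] <- expected_cost_benefit(th, config, profile, schedule, u = 0)
  }
  res <- as.data.frame(out)
  res$dC <- res$cost1 - res$cost0
  res$dB <- res$qaly1 - res$qaly0
  structure(res, class = c("ce_result", "data.frame"),
            lambda = schedule$lambda, model = sample$config_label)
}

#' Probability of cost-effectiveness
#'
#' Fraction of posterior draws with positive incremental net benefit
#' `lambda * dB - dC`; evaluated over a grid of `lambda` it traces the
#' cost-effectiveness acceptability curve.
#'
#' @param ce a [run_ce()] result (or any data frame with `dC`, `dB`).
#' @param lambda willingness-to-pay value(s); defaults to the schedule grid.
#' @return named vector of probabilities, one per `lambda`.
#' @export
pce <- function(ce, lambda = NULL) {
  if (nrow(ce) == 0L) stopf("empty cost-effectiveness result")
  lambda <- lambda %||% attr(ce, "lambda")
  stopifnot(all(lambda >= 0))
  setNames(vapply(lambda, function(l) mean(l * ce$dB - ce$dC > 0), numeric(1)),
           format(lambda, trim = TRUE, scientific = FALSE))
}

#' Write / read a cost schedule as JSON
#'
#' Mirrors the costing table: initial costs per arm, per-state daily costs,
#' utilities, discount rate, horizon and willingness-to-pay grid, plus the
#' state space so the file is self-contained.  Round trips are lossless.
#'
#' @param schedule a [cost_schedule()].
#' @param path file path.
#' @return `read_cost_schedule` returns the reconstructed [cost_schedule()].
#' @export
write_cost_schedule <- function(schedule, path) {
  obj <- list(initial_cost = as.list(schedule$initial_cost),
              daily_cost = list(aad = schedule$daily_cost[, "aad"],
                                icd = schedule$daily_cost[, "icd"]),
              utility = schedule$utility,
              annual_discount = schedule$annual_discount,
              horizon_days = schedule$horizon_days,
              lambda = schedule$lambda,
              states = schedule$space$states,
              absorbing = schedule$space$absorbing,
              permitted = unname(schedule$space$permitted))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cost_schedule
#' @export
read_cost_schedule <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  space <- state_space(obj$states, as.integer(obj$absorbing),
                       matrix(as.integer(as.matrix(obj$permitted)), ncol = 2L))
  cost_schedule(initial_cost = c(aad = obj$initial_cost$aad,
                                 icd = obj$initial_cost$icd),
                daily_cost = cbind(aad = as.numeric(obj$daily_cost$aad),
                                   icd = as.numeric(obj$daily_cost$icd)),
                utility = as.numeric(obj$utility),
                annual_discount = obj$annual_discount,
                horizon_days = obj$horizon_days,
                lambda = as.numeric(obj$lambda), space = space)
}

#' Per-draw incremental net monetary benefit
#'
#' @param ce a [run_ce()] result.
#' @param lambda willingness-to-pay (money per QALY); defaults to the first
#'   value of the schedule grid.
#' @return numeric vector `lambda * dB - dC`, one value per posterior draw.
#' @export
inb <- function(ce, lambda = NULL) {
  lambda <- (lambda %||% attr(ce, "lambda"))[1L]
  lambda * ce$dB - ce$dC
}

#' Summarize a cost-effectiveness posterior
#'
#' @param object a [run_ce()] result.
#' @param lambda willingness-to-pay for the reported PCE (first schedule value
#'   by default).
#' @param ... unused.
#' @return one-row data frame: posterior means and 95\% equal-tailed intervals
#'   of incremental cost and QALYs, the ICER (ratio of the posterior means,
#'   not the mean ratio), and PCE(lambda).
#' @export
summary.ce_result <- function(object, lambda = NULL, ...) {
  lambda <- (lambda %||% attr(object, "lambda"))[1L]
  qC <- quantile(object$dC, c(0.025, 0.975))
  qB <- quantile(object$dB, c(0.025, 0.975))
  data.frame(model = attr(object, "model") %||% NA_character_,
             dC = mean(object$dC), dC_lo = qC[1L], dC_hi = qC[2L],
             dB = mean(object$dB), dB_lo = qB[1L], dB_hi = qB[2L],
             icer = mean(object$dC) / mean(object$dB),
             pce = unname(pce(object, lambda)), lambda = lambda,
             row.names = NULL)
}
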