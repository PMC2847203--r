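#' Conditional predictive ordinate by the harmonic-mean estimator
#'
#' The leave-one-out predictive density of observation i is estimated by
#' importance sampling with the full-data posterior as proposal: the CPO is
#' the harmonic mean of the per-draw likelihoods `f(x_i | theta_r)` over the
#' posterior sample.  All arithmetic is done in log space (log-sum-exp of the
#' negated log-likelihoods), so the result is finite for per-draw
#' log-likelihoods down to -700 and beyond.
#'
#' The harmonic-mean estimator can be unstable when a few draws dominate the
#' sum of inverse likelihoods; the function reports the largest single-draw
#' share of that sum and the Monte-Carlo standard error of the running mean
#' of `1/f`, and warns when one draw carries more than 5\% of the total.  No
#' truncation or stabilization is applied.
#'
#' @param log_lik matrix of per-draw log-likelihoods (draws x observations),
#'   or a vector for a single observation.
#' @param warn_dominance warn when one draw's weight exceeds this share.
#' @return data frame with one row per observation: `log_cpo`, `cpo`,
#'   `max_weight` (largest single-draw share), and `rel_se` (relative
#'   Monte-Carlo standard error of the mean of `1/f`).
#' @export
cpo_harmonic_mean <- function(log_lik, warn_dominance = 0.05) {
  if (is.vector(log_lik)) log_lik <- matrix(log_lik, ncol = 1L)
  if (!all(is.finite(log_lik))) stopf("non-finite per-draw log-likelihood")
  N <- nrow(log_lik)
  out <- data.frame(log_cpo = numeric(ncol(log_lik)), cpo = NA_real_,
                    max_weight = NA_real_, rel_se = NA_real_)
  for (i in seq_len(ncol(log_lik))) {
    neg <- -log_lik[, i]
    lse <- logsumexp(neg)                 # log sum_r 1/f(x_i|theta_r)
    out$log_cpo[i] <- log(N) - lse
    w <- exp(neg - lse)
    out$max_weight[i] <- max(w)
    inv <- exp(neg - max(neg))            # scaled inverse likelihoods
    out$rel_se[i] <- stats::sd(inv) / (sqrt(N) * mean(inv))
  }
  out$cpo <- exp(out$log_cpo)
  heavy <- sum(out$max_weight > warn_dominance)
  if (heavy > 0L)
    warning(sprintf(
      "harmonic-mean CPO: a single draw carries > %.0f%% of the weight for %d observation(s); the estimator may be unstable",
      100 * warn_dominance, heavy), call. = FALSE)
  out
}

#' Log pseudo-marginal-likelihood
#'
#' Sum of the per-observation log CPOs; also reported on the `-2 log(PML)`
#' deviance-like scale used for model comparison tables.
#'
#' @param log_cpo vector of per-observation log CPOs (e.g. the `log_cpo`
#'   column of [cpo_harmonic_mean()]).
#' @return list with `log_pml` and `minus2_log_pml`.
#' @export
log_pml <- function(log_cpo) {
  total <- sum(log_cpo)
  list(log_pml = total, minus2_log_pml = -2 * total)
}

#' Deviance information criterion
#'
#' `Dbar` is the posterior mean of the per-draw deviance, the effective
#' number of parameters is `p_D = Dbar - D_hat` where `D_hat` is the plug-in
#' deviance, and `DIC = D_hat + 2 p_D = Dbar + p_D`.
#'
#' @param deviance_draws per-draw deviances (-2 log likelihood).
#' @param plug_in_deviance deviance at the posterior-mean linear predictors.
#' @return list with `Dbar`, `p_D`, `DIC`, `plug_in`.
#' @export
dic <- function(deviance_draws, plug_in_deviance) {
  stopifnot(length(deviance_draws) >= 1L)
  Dbar <- mean(deviance_draws)
  p_D <- Dbar - plug_in_deviance
  list(Dbar = Dbar, p_D = p_D, DIC = plug_in_deviance + 2 * p_D,
       plug_in = plug_in_deviance)
}

#' Per-observation DIC contributions
#'
#' Decomposes the DIC over the (patient, year, from-state) rows:
#' `DIC_i = Dbar_i + (Dbar_i - Dhat_i)` with `Dbar_i` the posterior-mean
#' per-row deviance and `Dhat_i` the per-row deviance at the posterior-mean
#' linear predictors; the contributions sum to the total DIC.
#'
#' @param sample a [sample_posterior()] result.
#' @param data,config the data and configuration the sample was fitted to.
#' @return vector of `DIC_i`, one per data row.
#' @export
dic_decomposition <- function(sample, data, config) {
  ll <- row_loglik_draws(sample, data, config)
  Dbar_i <- -2 * colMeans(ll)
  Dhat_i <- -2 * plug_in_row_loglik(sample, data, config)
  2 * Dbar_i - Dhat_i
}

# per-row log-likelihood at the posterior-mean linear predictors (the plug-in
# parameterization: predictors averaged over draws, not theta)
plug_in_row_loglik <- function(sample, data, config) {
  engine <- build_lik_engine(data, config)
  engine_row_loglik(engine, mean_group_etas(engine, sample$draws))
}

#' Full predictive-adequacy assessment of a fitted model
#'
#' Computes, from one MCMC fit: per-row log CPOs and the total
#' `-2 log(PML)` (harmonic-mean estimator), the DIC with its effective number
#' of parameters, and the per-row DIC contributions used for
#' Bayesian-bootstrap model weighting.
#'
#' @inheritParams dic_decomposition
#' @return object of class `fit_assessment`: `log_cpo` and `dic_i` vectors
#'   (one entry per row, named by patient/year/from-state), `cpo_diag`
#'   (stability diagnostics), and totals `minus2_log_pml`, `Dbar`, `p_D`,
#'   `DIC`, `plug_in`.  The comparison `DIC <= -2 log(PML)` is expected on
#'   well-behaved fits and is reported, not asserted.
#' @export
assess_fit <- function(sample, data, config) {
  ll <- row_loglik_draws(sample, data, config)
  cpo <- cpo_harmonic_mean(ll)
  pml <- log_pml(cpo$log_cpo)
  plug_row <- plug_in_row_loglik(sample, data, config)
  plug_dev <- -2 * sum(plug_row)
  d <- dic(sample$deviance, plug_dev)
  dic_i <- 2 * (-2 * colMeans(ll)) - (-2 * plug_row)
  ids <- sprintf("%s/%s/%s", data$patient, data$year, data$from_state)
  structure(list(log_cpo = setNames(cpo$log_cpo, ids),
                 dic_i = setNames(dic_i, ids), cpo_diag = cpo,
                 minus2_log_pml = pml$minus2_log_pml, log_pml = pml$log_pml,
                 Dbar = d$Dbar, p_D = d$p_D, DIC = d$DIC, plug_in = d$plug_in,
                 n = length(plug_row), model = sample$config_label),
            class = "fit_assessment")
}

#' @export
print.fit_assessment <- function(x, ...) {
  cat(sprintf("fit assessment (model %s, %d rows):\n", x$model, x$n))
  cat(sprintf("  plug-in deviance %.1f, p_D %.1f, DIC %.1f, -2 log(PML) %.1f\n",
              x$plug_in, x$p_D, x$DIC, x$minus2_log_pml))
  if (x$DIC > x$minus2_log_pml)
    cat("  note: DIC exceeds -2 log(PML); usually DIC is lower on well-behaved fits\n")
  invisible(x)
}

#' Export per-row assessment contributions as CSV
#'
#' One row per (patient, year, from-state) observation with its log CPO and
#' DIC contribution, for downstream bootstrapping.
#'
#' @param assessment a [assess_fit()] result.
#' @param data the fitted [transition_data()].
#' @param path CSV path.
#' @export
write_assessment_csv <- function(assessment, data, path) {
  write.csv(data.frame(patient = data$patient, year = data$year,
                       from_state = data$from_state,
                       log_cpo = unname(assessment$log_cpo),
                       dic_i = unname(assessment$dic_i)),
            path, row.names = FALSE)
  invisible(path)
}
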