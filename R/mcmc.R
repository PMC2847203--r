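#' Posterior sampling by adaptive Metropolis-within-Gibbs
#'
#' Samples the free parameters of a multi-state multinomial-logit model by
#' univariate random-walk Metropolis updates cycling over the parameters
#' (Metropolis within Gibbs).  Proposal standard deviations adapt during
#' burn-in towards a target acceptance rate of 0.44 (Robbins-Monro on the log
#' scale) and are frozen afterwards, so the kept chain is a genuine Markov
#' chain.  Initial values are the prior means.
#'
#' @param data a [transition_data()].
#' @param config a [model_config()].
#' @param priors a [prior_spec()]; defaults to [prior_spec()]`(config)`.
#' @param n_iter number of kept iterations (posterior draws).
#' @param n_burnin number of discarded adaptation iterations.
#' @param seed integer RNG seed; the run is exactly reproducible.
#' @param init optional initial parameter vector (default: prior means).
#' @param init_step initial proposal standard deviation.
#' @param target_accept adaptation target acceptance rate.
#' @param store_row_loglik if `TRUE`, store the per-(patient, year, from-state)
#'   row log-likelihood at every kept draw (needed for CPO / predictive model
#'   assessment).
#' @return an object of class `posterior_sample`: kept draws (matrix with one
#'   named column per free parameter), per-draw deviance (-2 log likelihood,
#'   multinomial constant included), per-parameter acceptance rates, and the
#'   sampler settings.
#' @export
sample_posterior <- function(data, config, priors = prior_spec(config),
                             n_iter = 2000L, n_burnin = 500L, seed = 1L,
                             init = NULL, init_step = 0.2, target_accept = 0.44,
                             store_row_loglik = FALSE) {
  stopifnot(n_iter >= 1L, n_burnin >= 0L)
  engine <- build_lik_engine(data, config)
  P <- config$n_free
  stopifnot(nrow(priors) == P)
  set.seed(as.integer(seed))

  theta <- if (is.null(init)) priors$mean else init
  stopifnot(length(theta) == P)

  etas <- lapply(seq_along(engine$groups), function(g) group_eta(engine, theta, g))
  gll <- vapply(seq_along(engine$groups),
                function(g) group_loglik(engine, g, etas[[g]]), numeric(1))
  if (length(gll) && !all(is.finite(gll)))
    stopf("non-finite log-likelihood at initial values")

  # slots touched by each parameter: per group, the (design column, eta column)
  # pairs whose coefficient is that parameter
  aff <- vector("list", P)
  for (g in seq_along(engine$groups)) {
    cm <- config$coef_maps[[engine$groups[[g]]$r]]
    hit <- which(cm$map > 0L, arr.ind = TRUE)
    for (h in seq_len(nrow(hit))) {
      p <- cm$map[hit[h, 1L], hit[h, 2L]]
      aff[[p]] <- c(aff[[p]], list(list(g = g, kx = hit[h, 1L], j = hit[h, 2L] + 1L)))
    }
  }

  lstep <- rep(log(init_step), P)
  acc_n <- numeric(P)
  total <- n_burnin + n_iter
  draws <- matrix(NA_real_, n_iter, P, dimnames = list(NULL, config$par_names))
  deviance <- numeric(n_iter)
  row_ll <- if (store_row_loglik) matrix(NA_real_, n_iter, engine$n_rows) else NULL

  # flat views of the hot quantities (avoid repeated list traversal per update)
  Xus <- lapply(engine$groups, `[[`, "Xu")
  CTs <- lapply(engine$groups, `[[`, "CT")
  Ntots <- lapply(engine$groups, `[[`, "Ntot")
  gll_of <- function(g, eta) sum(CTs[[g]] * eta) - sum(Ntots[[g]] * row_logsumexp(eta))
  pr_mean <- priors$mean; pr_sd <- priors$sd
  # per parameter: affected groups and, per group, the (kx, j) index pairs
  aff_flat <- lapply(aff, function(slots) {
    gs <- unique(vapply(slots, `[[`, integer(1), "g"))
    lapply(gs, function(g) {
      sel <- Filter(function(sl) sl$g == g, slots)
      list(g = g,
           kx = vapply(sel, `[[`, integer(1), "kx"),
           j = vapply(sel, `[[`, integer(1), "j"))
    })
  })

  for (it in seq_len(total)) {
    adapt_gain <- if (it <= n_burnin) min(0.25, 2 / sqrt(it)) else 0
    for (p in seq_len(P)) {
      d <- rnorm(1L) * exp(lstep[p])
      hits <- aff_flat[[p]]
      new_eta <- vector("list", length(hits))
      new_gllv <- numeric(length(hits))
      dll <- 0
      for (gi in seq_along(hits)) {
        h <- hits[[gi]]
        eta <- etas[[h$g]]
        for (q in seq_along(h$kx)) eta[, h$j[q]] <- eta[, h$j[q]] + Xus[[h$g]][, h$kx[q]] * d
        new_eta[[gi]] <- eta
        new_gllv[gi] <- gll_of(h$g, eta)
        dll <- dll + new_gllv[gi] - gll[h$g]
      }
      la <- dll +
        dnorm(theta[p] + d, pr_mean[p], pr_sd[p], log = TRUE) -
        dnorm(theta[p], pr_mean[p], pr_sd[p], log = TRUE)
      acc_p <- if (is.finite(la)) min(1, exp(la)) else 0
      if (runif(1L) < acc_p) {
        theta[p] <- theta[p] + d
        for (gi in seq_along(hits)) {
          etas[[hits[[gi]]$g]] <- new_eta[[gi]]
          gll[hits[[gi]]$g] <- new_gllv[gi]
        }
        if (it > n_burnin) acc_n[p] <- acc_n[p] + 1
      }
      lstep[p] <- lstep[p] + adapt_gain * (acc_p - target_accept)
    }
    if (it > n_burnin) {
      k <- it - n_burnin
      draws[k, ] <- theta
      deviance[k] <- -2 * (sum(gll) + engine$logC_total)
      if (store_row_loglik) row_ll[k, ] <- engine_row_loglik(engine, etas)
    }
  }

  structure(list(draws = draws, deviance = deviance, row_loglik = row_ll,
                 accept = acc_n / n_iter, step = exp(lstep),
                 seed = as.integer(seed), n_iter = n_iter, n_burnin = n_burnin,
                 config_label = config$label, n_free = P),
            class = "posterior_sample")
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat(sprintf("posterior sample: %d draws of %d parameters (model %s, burn-in %d, seed %d)\n",
              x$n_iter, x$n_free, x$config_label, x$n_burnin, x$seed))
  cat(sprintf("  mean acceptance rate %.2f; mean deviance %.1f\n",
              mean(x$accept), mean(x$deviance)))
  invisible(x)
}

#' @export
summary.posterior_sample <- function(object, probs = c(0.025, 0.5, 0.975), ...) {
  qs <- t(apply(object$draws, 2L, quantile, probs = probs))
  data.frame(par = colnames(object$draws), mean = colMeans(object$draws),
             sd = apply(object$draws, 2L, stats::sd), qs,
             check.names = FALSE, row.names = NULL)
}

#' Posterior-mean linear predictors per data row
#'
#' Averages each row's linear predictors (log odds against the reference
#' destination) over the posterior draws.  Because the predictors are linear
#' in the parameters this equals the predictors at the posterior-mean
#' parameters; the averaging route is the canonical parameterization for the
#' plug-in deviance.
#'
#' @param sample a [sample_posterior()] result.
#' @param data,config the data and configuration the sample was fitted to.
#' @return matrix (rows x states) of mean log odds: 0 in the reference column,
#'   `NA` on non-permitted destinations.
#' @export
posterior_mean_linear_predictors <- function(sample, data, config) {
  stopifnot(nrow(sample$draws) >= 1L)
  engine <- build_lik_engine(data, config)
  means <- mean_group_etas(engine, sample$draws)
  out <- matrix(NA_real_, engine$n_rows, config$space$n,
                dimnames = list(NULL, config$space$states))
  for (g in seq_along(engine$groups)) {
    grp <- engine$groups[[g]]
    out[grp$rows, grp$cols] <- means[[g]][engine$row_pat[grp$rows], , drop = FALSE]
  }
  out
}

# running mean over draws of each group's eta matrix (reference column incl.)
mean_group_etas <- function(engine, draws) {
  n <- nrow(draws)
  means <- lapply(seq_along(engine$groups),
                  function(g) group_eta(engine, draws[1L, ], g) / n)
  if (n > 1L) for (i in 2:n)
    for (g in seq_along(engine$groups))
      means[[g]] <- means[[g]] + group_eta(engine, draws[i, ], g) / n
  means
}

# per-row log-likelihood at every kept draw (rows of the result index draws)
row_loglik_draws <- function(sample, data, config) {
  if (!is.null(sample$row_loglik)) return(sample$row_loglik)
  engine <- build_lik_engine(data, config)
  n <- nrow(sample$draws)
  out <- matrix(NA_real_, n, engine$n_rows)
  for (i in seq_len(n)) {
    etas <- lapply(seq_along(engine$groups),
                   function(g) group_eta(engine, sample$draws[i, ], g))
    out[i, ] <- engine_row_loglik(engine, etas)
  }
  out
}
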