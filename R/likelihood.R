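# Likelihood engine: the multinomial log-likelihood of yearly transition rows
# under a model configuration.  Rows sharing a from-state and identical design
# vectors are collapsed to unique patterns once, so MCMC sweeps touch only
# small matrices; the (theta-independent) multinomial coefficients are summed
# once and cached.

build_lik_engine <- function(data, config) {
  stopifnot(inherits(data, "transition_data"), inherits(config, "model_config"))
  if (!identical(attr(data, "space")$permitted, config$space$permitted))
    stopf("data and config use different state spaces")
  R <- config$space$n
  counts <- unname(as.matrix(data[paste0("n", seq_len(R))]))
  X <- cbind(rep(1, nrow(data)), covariate_matrix(config, data))
  logC_row <- unname(lgamma(data$N + 1) - rowSums(lgamma(counts + 1)))

  groups <- list()
  row_group <- integer(nrow(data)); row_pat <- integer(nrow(data))
  for (r in sort(unique(data$from_state))) {
    rows <- which(data$from_state == r)
    cm <- config$coef_maps[[r]]
    cols <- c(cm$ref, cm$dests)               # reference first
    Xg <- X[rows, , drop = FALSE]
    key <- apply(Xg, 1L, paste, collapse = "\r")
    ukey <- unique(key)
    pat <- match(key, ukey)
    Xu <- Xg[!duplicated(key), , drop = FALSE]
    CT <- matrix(0, nrow = length(ukey), ncol = length(cols))
    Crow <- counts[rows, cols, drop = FALSE]
    for (j in seq_along(rows)) CT[pat[j], ] <- CT[pat[j], ] + Crow[j, ]
    gid <- length(groups) + 1L
    groups[[gid]] <- list(r = r, Xu = Xu, CT = CT, Ntot = rowSums(CT),
                          cols = cols, Crow = Crow, rows = rows)
    row_group[rows] <- gid
    row_pat[rows] <- pat
  }
  list(groups = groups, logC_total = sum(logC_row), logC_row = logC_row,
       row_group = row_group, row_pat = row_pat, n_rows = nrow(data),
       n_free = config$n_free, config = config)
}

# linear predictors (incl. leading reference-zero column) for one group
group_eta <- function(engine, theta, g) {
  grp <- engine$groups[[g]]
  cm <- engine$config$coef_maps[[grp$r]]
  B <- matrix(0, nrow = nrow(cm$map), ncol = ncol(cm$map))
  nz <- cm$map > 0L
  B[nz] <- theta[cm$map[nz]]
  cbind(0, grp$Xu %*% B)
}

group_loglik <- function(engine, g, eta) {
  grp <- engine$groups[[g]]
  lse <- row_logsumexp(eta)
  sum(grp$CT * eta) - sum(grp$Ntot * lse)
}

engine_loglik <- function(engine, theta, include_const = TRUE) {
  ll <- sum(vapply(seq_along(engine$groups),
                   function(g) group_loglik(engine, g, group_eta(engine, theta, g)),
                   numeric(1)))
  if (include_const) ll + engine$logC_total else ll
}

# per-(patient,year,from-state) row log-likelihoods from cached group etas
engine_row_loglik <- function(engine, etas) {
  out <- numeric(engine$n_rows)
  for (g in seq_along(engine$groups)) {
    grp <- engine$groups[[g]]
    eta <- etas[[g]]
    LP <- eta - row_logsumexp(eta)
    out[grp$rows] <- rowSums(grp$Crow * LP[engine$row_pat[grp$rows], , drop = FALSE])
  }
  out + engine$logC_row
}

#' Multinomial log-likelihood of transition data
#'
#' Sum over (patient, year, from-state) rows of the multinomial log
#' probability of the observed destination counts, including the multinomial
#' coefficient (so per-row values are genuine predictive log probabilities);
#' `0 * log 0` contributes 0.
#'
#' @param theta free-parameter vector.
#' @param data a [transition_data()].
#' @param config a [model_config()].
#' @param per_row if `TRUE`, return the vector of per-row log-likelihoods
#'   instead of the total.
#' @return total log-likelihood (or per-row vector).
#' @export
log_likelihood <- function(theta, data, config, per_row = FALSE) {
  if (nrow(data) == 0L) return(if (per_row) numeric(0) else 0)
  engine <- build_lik_engine(data, config)
  if (!per_row) return(engine_loglik(engine, theta))
  etas <- lapply(seq_along(engine$groups), function(g) group_eta(engine, theta, g))
  engine_row_loglik(engine, etas)
}

# ---- priors ------------------------------------------------------------------

#' Normal prior specification for the free parameters
#'
#' Defaults are widely dispersed normal(0, 10) priors on every free parameter.
#' When the configuration has the common death row with a treatment effect
#' (`b_D_treat`), that coefficient gets an informative normal(0.414, 0.16)
#' prior (log odds ratio of death under drug therapy versus device, from a
#' fixed-effect meta-analysis of earlier trials).
#'
#' @param config a [model_config()].
#' @param mean,sd defaults applied to every parameter.
#' @param overrides named list `name = c(mean, sd)` of per-parameter overrides.
#' @return data frame of class `prior_spec` with columns `par`, `mean`, `sd`.
#' @export
prior_spec <- function(config, mean = 0, sd = 10, overrides = list()) {
  pr <- data.frame(par = config$par_names, mean = mean, sd = sd,
                   stringsAsFactors = FALSE)
  if ("b_D_treat" %in% pr$par && !("b_D_treat" %in% names(overrides)))
    overrides$b_D_treat <- c(0.414, 0.16)
  for (nm in names(overrides)) {
    i <- match(nm, pr$par)
    if (is.na(i)) stopf("prior override for unknown parameter '%s'", nm)
    pr$mean[i] <- overrides[[nm]][1L]
    pr$sd[i] <- overrides[[nm]][2L]
  }
  if (any(pr$sd <= 0)) stopf("prior sd must be positive")
  class(pr) <- c("prior_spec", "data.frame")
  pr
}

#' Log prior density
#'
#' @param theta free-parameter vector.
#' @param priors a [prior_spec()].
#' @return sum of normal log densities.
#' @export
log_prior <- function(theta, priors) {
  stopifnot(length(theta) == nrow(priors))
  if (any(priors$sd <= 0)) stopf("prior sd must be positive")
  sum(dnorm(theta, priors$mean, priors$sd, log = TRUE))
}
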