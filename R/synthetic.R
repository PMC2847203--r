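#' Synthetic-cohort configuration
#'
#' Describes a cohort resembling the device-vs-drug study: two-country
#' recruitment, mostly male, mostly low ejection fraction, starting age near
#' 63, administrative censoring from uniform staggered entry with mean
#' follow-up about 3.68 years and maximum 7.04 years, and a known
#' ground-truth parameter vector so every downstream stage can be validated.
#'
#' @param n number of patients.
#' @param aad_frac fraction allocated to the drug arm (`treat = 1`).
#' @param female_prev,lvef_prev,uk_frac covariate prevalences.
#' @param age_mean,age_sd,age_range starting-age distribution (truncated
#'   normal, years).
#' @param followup_range censoring range in years (uniform; the default
#'   `c(0.32, 7.04)` gives mean follow-up 3.68 and maximum 7.04 years).
#' @param theta_star true free-parameter vector (defaults per
#'   [default_true_theta()] when `NULL`).
#' @param seed RNG seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n = 965L, aad_frac = 0.22, female_prev = 0.13,
                          lvef_prev = 0.70, uk_frac = 0.55,
                          age_mean = 63, age_sd = 8, age_range = c(35, 82),
                          followup_range = c(0.32, 7.04),
                          theta_star = NULL, seed = 1L) {
  probs <- c(aad_frac, female_prev, lvef_prev, uk_frac)
  if (any(probs < 0 | probs > 1)) stopf("prevalences must be in [0,1]")
  if (any(followup_range <= 0) || diff(followup_range) < 0)
    stopf("follow-up range must be positive and increasing")
  structure(list(n = as.integer(n), aad_frac = aad_frac,
                 female_prev = female_prev, lvef_prev = lvef_prev,
                 uk_frac = uk_frac, age_mean = age_mean, age_sd = age_sd,
                 age_range = age_range, followup_range = followup_range,
                 theta_star = theta_star, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default ground-truth parameters for a model configuration
#'
#' Documented constants chosen so yearly event counts resemble the sparsity
#' of the motivating study: rare deaths (about 5\%/year at reference
#' covariates), rare cause-specific admissions (about 0.1--0.2/year each),
#' week-scale hospital stays, a drug-vs-device mortality log odds ratio of
#' 0.414, arm-specific admission patterns (no device-maintenance admissions
#' in the drug arm, more drug-toxicity admissions), and age effects that rise
#' with age.
#'
#' @param config a [model_config()].
#' @return named numeric vector over `config$par_names`.
#' @export
default_true_theta <- function(config) {
  # centred-age (age-63)/10 polynomial: gently rising in mid life, steep at
  # old age, near flat for the youngest (a plausible log-odds-vs-age curve
  # that a three-band step function cannot reproduce)
  poly_death <- c(0.55, 0.12, 0.05, 0.02)
  poly_adm <- c(0.3, 0.1, 0, 0)
  val <- function(nm) {
    if (grepl("^mu_1[2-7]$", nm)) return(-8)
    if (grepl("^mu_[2-7][2-7]$", nm)) return(1.8)
    if (nm == "mu_D") return(-8.9)
    row <- if (grepl("^b_D_", nm)) "death"
    else if (grepl("^b_1[2-7]_", nm)) "adm" else "stay"
    cov <- sub("^b_(D|[0-9]+)_", "", nm)
    if (row == "death")
      return(switch(cov, treat = 0.414, female = -0.1, lvef = 0.5, uk = 0.1,
                    age60_70 = 0.4, age70p = 0.9,
                    age1 = poly_death[1], age2 = poly_death[2],
                    age3 = poly_death[3], age4 = poly_death[4], 0))
    if (row == "adm") {
      s <- as.integer(substr(nm, 4L, 4L))
      return(switch(cov,
                    treat = if (s %in% 5:6) -2 else if (s == 7L) 1.5 else 0.2,
                    female = -0.1, lvef = 0.3, uk = 0.1,
                    age60_70 = 0.2, age70p = 0.4,
                    age1 = poly_adm[1], age2 = poly_adm[2], 0))
    }
    switch(cov, uk = 0.2, age60_70 = 0.1, age70p = 0.2, 0)
  }
  setNames(vapply(config$par_names, val, numeric(1)), config$par_names)
}

#' Simulate a cohort of daily multi-state histories
#'
#' Draws covariates and an administrative censoring time per patient, then
#' simulates the daily chain from state 1 under the model's own
#' [transition_probabilities()] (generator and fitter share one code path),
#' with age advanced at each follow-up-year boundary (covariates are constant
#' within a year, as the yearly aggregation assumes).  Transitions are
#' aggregated into (patient, year, from-state) multinomial rows; follow-up
#' ends at death or censoring.
#'
#' @param cohort a [cohort_config()].
#' @param model a [model_config()] (its baseline covariates among `treat`,
#'   `female`, `lvef`, `uk` are drawn with the configured prevalences; any
#'   other baseline covariate is Bernoulli(0.5)).
#' @return a [transition_data()]; the true parameters are in attribute
#'   `theta_star`, per-patient death days (NA if censored) in `death_day`.
#' @export
simulate_cohort <- function(cohort, model) {
  theta <- cohort$theta_star %||% default_true_theta(model)
  if (length(theta) != model$n_free)
    stopf("theta_star has length %d, expected %d", length(theta), model$n_free)
  space <- model$space
  R <- space$n
  absorbing <- seq_len(R) %in% space$absorbing
  set.seed(cohort$seed)

  prev <- c(treat = cohort$aad_frac, female = cohort$female_prev,
            lvef = cohort$lvef_prev, uk = cohort$uk_frac)
  draw_cov <- function(nm) {
    p <- if (nm %in% names(prev)) prev[[nm]] else 0.5
    as.numeric(runif(1L) < p)
  }
  age0 <- numeric(cohort$n)
  for (i in seq_len(cohort$n)) {
    repeat {
      a <- rnorm(1L, cohort$age_mean, cohort$age_sd)
      if (a >= cohort$age_range[1L] && a <= cohort$age_range[2L]) break
    }
    age0[i] <- a
  }
  censor_days <- pmax(1L, round(runif(cohort$n, cohort$followup_range[1L],
                                      cohort$followup_range[2L]) * 365))

  P_cache <- new.env(parent = emptyenv())
  get_P <- function(covs, age) {
    key <- paste(c(unlist(covs), round(age, 6)), collapse = "/")
    P <- P_cache[[key]]
    if (is.null(P)) {
      P <- transition_matrix(theta, model, c(covs, list(age = age)))
      P_cache[[key]] <- P
    }
    P
  }

  cap <- cohort$n * 8L                       # grown on demand
  pat <- integer(cap); yr <- integer(cap); fs <- integer(cap)
  agev <- numeric(cap)
  covm <- matrix(NA_real_, cap, length(model$baseline))
  cntm <- matrix(0L, cap, R)
  nr <- 0L
  grow <- function() {
    cap <<- cap * 2L
    length(pat) <<- cap; length(yr) <<- cap; length(fs) <<- cap
    length(agev) <<- cap
    covm <<- rbind(covm, matrix(NA_real_, nrow(covm), ncol(covm)))
    cntm <<- rbind(cntm, matrix(0L, nrow(cntm), ncol(cntm)))
  }
  death_day <- rep(NA_integer_, cohort$n)
  for (i in seq_len(cohort$n)) {
    covs <- setNames(lapply(model$baseline, draw_cov), model$baseline)
    covv <- as.numeric(unlist(covs, use.names = FALSE))
    state <- 1L
    day <- 0L
    year <- 0L
    while (day < censor_days[i] && !absorbing[state]) {
      year <- year + 1L
      ndays <- min(365L, censor_days[i] - day)
      age_y <- floor(age0[i]) + (year - 1L)   # integer age, constant in-year
      P <- get_P(covs, age_y)
      counts <- matrix(0L, R, R)
      state_new <- cpp_sim_segment(P, state, ndays, counts, absorbing)
      used <- sum(counts)
      if (absorbing[state_new]) death_day[i] <- day + used
      day <- day + used
      for (r in which(.rowSums(counts, R, R) > 0L)) {
        nr <- nr + 1L
        if (nr > cap) grow()
        pat[nr] <- i; yr[nr] <- year; fs[nr] <- r; agev[nr] <- age_y
        if (length(covv)) covm[nr, ] <- covv
        cntm[nr, ] <- counts[r, ]
      }
      state <- state_new
    }
  }
  df <- data.frame(patient = pat[seq_len(nr)], year = yr[seq_len(nr)],
                   from_state = fs[seq_len(nr)], age = agev[seq_len(nr)])
  for (j in seq_along(model$baseline)) df[[model$baseline[j]]] <- covm[seq_len(nr), j]
  for (s in seq_len(R)) df[[paste0("n", s)]] <- cntm[seq_len(nr), s]
  out <- transition_data(df, space)
  attr(out, "theta_star") <- theta
  attr(out, "death_day") <- death_day
  out
}

#' Small seeded fixture bundle for end-to-end validation
#'
#' Emits three data sets from known truths: (a) a tiny two-state alive/dead
#' cohort with a single free parameter, whose posterior can be computed by
#' dense numerical integration; (b) a medium eight-state cohort from the
#' base-case truth for parameter-recovery checks; (c) a pair of cohorts
#' generated under the base-case (piecewise age) truth and under the
#' quartic-age truth, for model-selection power checks.
#'
#' @param seed master seed; per-fixture seeds are derived deterministically.
#' @param n_b,n_c cohort sizes for fixtures (b) and (c).
#' @return list with elements `a`, `b`, `c`; each holds `data`, `config` and
#'   `truth` (fixture `c` has `m1` and `m7` sub-fixtures).
#' @export
make_fixture_suite <- function(seed = 1L, n_b = 120L, n_c = 300L) {
  two_state <- build_model_config(list(
    space = alive_dead_state_space(), baseline = character(0),
    slots = data.frame(r = 1L, s = 2L, k = 0L, par_name = "mu"),
    label = "alive_dead"))
  cc_a <- cohort_config(n = 8L, followup_range = c(0.4, 1.2),
                        theta_star = c(mu = -4.5),
                        seed = derive_seed(seed, "fixture_a"))
  a <- list(config = two_state, truth = c(mu = -4.5),
            data = simulate_cohort(cc_a, two_state))

  m1 <- build_model_config("M1")
  cc_b <- cohort_config(n = n_b, seed = derive_seed(seed, "fixture_b"))
  b <- list(config = m1, truth = default_true_theta(m1),
            data = simulate_cohort(cc_b, m1))

  m7 <- build_model_config("M7")
  cc_c1 <- cohort_config(n = n_c, seed = derive_seed(seed, "fixture_c1"))
  cc_c7 <- cohort_config(n = n_c, seed = derive_seed(seed, "fixture_c7"))
  cc <- list(m1 = list(config = m1, truth = default_true_theta(m1),
                       data = simulate_cohort(cc_c1, m1)),
             m7 = list(config = m7, truth = default_true_theta(m7),
                       data = simulate_cohort(cc_c7, m7)))
  list(a = a, b = b, c = cc)
}
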