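# Shared fixtures, built once per test run (all generated in code; no files).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

m1_config <- function() fixture("m1", function() build_model_config("M1"))

# tiny two-state alive/dead model with one free parameter (daily death log odds)
two_state_config <- function() fixture("two_state", function() {
  build_model_config(list(
    space = alive_dead_state_space(), baseline = character(0),
    slots = data.frame(r = 1L, s = 2L, k = 0L, par_name = "mu"),
    label = "alive_dead"))
})

# the seeded fixture bundle (a: two-state, b: medium M1, c: M1/M7 pair)
fixture_suite <- function() fixture("suite", function() make_fixture_suite(42L, n_b = 60L, n_c = 120L))

# typical covariate setting for single-row evaluations
m1_covs <- function(treat = 0, female = 0, lvef = 1, uk = 1, age = 63)
  list(treat = treat, female = female, lvef = lvef, uk = uk, age = age)

# one M1-truth transition_data row built by hand
m1_row <- function(r = 1L, counts, covs = m1_covs(), patient = 1L, year = 1L) {
  R <- 8L
  stopifnot(length(counts) == R)
  df <- data.frame(patient = patient, year = year, from_state = r,
                   treat = covs$treat, female = covs$female, lvef = covs$lvef,
                   uk = covs$uk, age = covs$age)
  for (s in seq_len(R)) df[[paste0("n", s)]] <- counts[s]
  df
}

empty_m1_data <- function() {
  df <- m1_row(counts = rep(0L, 8L))[0L, ]
  transition_data(df, icd_state_space())
}

quick_fit <- function(data, config, n_iter = 600L, n_burnin = 300L, seed = 1L, ...) {
  sample_posterior(data, config, n_iter = n_iter, n_burnin = n_burnin,
                   seed = seed, ...)
}

# two-state cost schedule: alive costs `daily` per day, utility 0.75
two_state_schedule <- function(initial = c(aad = 100, icd = 500), daily = 5,
                               discount = 0.035, horizon_days = 365L,
                               lambda = 20000) {
  cost_schedule(initial_cost = initial,
                daily_cost = cbind(aad = c(daily, 0), icd = c(daily, 0)),
                utility = c(0.75, 0), annual_discount = discount,
                horizon_days = horizon_days, lambda = lambda,
                space = alive_dead_state_space())
}
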