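test_that("state space invariants hold and violations are rejected", {
  ss <- icd_state_space()
  expect_equal(ss$n, 8L)
  expect_equal(permitted_dests(ss, 1L), 1:8)
  for (r in 2:7) expect_equal(permitted_dests(ss, r), sort(c(1L, r, 8L)))
  expect_equal(permitted_dests(ss, 8L), 8L)
  # absorbing state with an exit, transient state with no exit
  expect_error(state_space(c("a", "b"), absorbing = 2L,
                           permitted = rbind(c(1, 1), c(1, 2), c(2, 2), c(2, 1))),
               "absorbing")
  expect_error(state_space(c("a", "b"), absorbing = 2L,
                           permitted = rbind(c(1, 1), c(2, 2))),
               "reach no other")
})

test_that("variant factories produce the documented structures", {
  m1 <- build_model_config("M1")
  expect_equal(m1$covariates$name,
               c("treat", "female", "lvef", "uk", "age60_70", "age70p"))
  # death-row tying: one shared parameter set across all source states
  death <- m1$slots[m1$slots$s == 8L, ]
  expect_equal(sort(unique(death$par_name[death$k == 0L])), "mu_D")
  expect_equal(length(unique(death$par_name)), 7L)   # mu_D + 6 covariates
  # stay rows: only country, and not for drug side effects
  stay <- m1$slots[m1$slots$r > 1L & m1$slots$s == m1$slots$r & m1$slots$k > 0L, ]
  kept <- stay[!is.na(stay$par_name), ]
  expect_true(all(kept$k == match("uk", m1$covariates$name)))
  expect_false(any(kept$r == 7L))
  # no country effect on admission for drug side effects
  adm7 <- m1$slots[m1$slots$r == 1L & m1$slots$s == 7L, ]
  expect_true(is.na(adm7$par_name[adm7$k == match("uk", m1$covariates$name)]))

  m5 <- build_model_config("M5")
  expect_equal(m5$age_transform, list(type = "polynomial", degree = 2L,
                                      center = 63, scale = 10))
  expect_true(all(c("b_D_age1", "b_D_age2") %in% m5$par_names))
  expect_false(any(grepl("age60_70", m5$par_names)))

  m10 <- build_model_config("M10")
  expect_true(all(paste0("b_D_treat_age", 1:4) %in% m10$par_names))

  expect_error(build_model_config("M11"), "unknown model label")
})

test_that("explicit structures work and malformed slot tables are rejected", {
  cfg <- two_state_config()
  expect_equal(cfg$n_free, 1L)
  expect_equal(build_parameter_index(cfg)$n_free, 1L)
  # slot on a non-permitted transition
  expect_error(build_model_config(list(
    space = alive_dead_state_space(), baseline = character(0),
    slots = data.frame(r = 2L, s = 1L, k = 0L, par_name = "x"))),
    "slot table")
  # incomplete coverage
  expect_error(build_model_config(list(
    space = icd_state_space(), baseline = character(0),
    slots = data.frame(r = 1L, s = 2L, k = 0L, par_name = "x"))),
    "slot table")
})

test_that("linear predictors follow the slot map and death-row tie", {
  m1 <- m1_config()
  th <- rep(0, m1$n_free)
  eta <- linear_predictors(th, m1, m1_covs(), 1L)
  expect_equal(unname(eta), rep(0, 7))
  # a single coefficient moves only its own slot
  th2 <- th; th2[match("b_12_treat", m1$par_names)] <- 0.7
  eta2 <- linear_predictors(th2, m1, m1_covs(treat = 1), 1L)
  expect_equal(unname(eta2["arrhythmic"]), 0.7)
  expect_equal(unname(eta2[names(eta2) != "arrhythmic"]), rep(0, 6))
  # tied death row reproduces the same log odds from every source state
  th3 <- th; th3[match("mu_D", m1$par_names)] <- -3.2
  th3[match("b_D_lvef", m1$par_names)] <- 0.5
  death_eta <- vapply(1:7, function(r)
    linear_predictors(th3, m1, m1_covs(), r)[["death"]], numeric(1))
  expect_equal(death_eta, rep(-2.7, 7))
  # fractional covariate values enter linearly
  th4 <- th; th4[match("b_12_female", m1$par_names)] <- 1
  expect_equal(unname(linear_predictors(th4, m1, m1_covs(female = 0.13), 1L)["arrhythmic"]),
               0.13)
  expect_error(linear_predictors(th, m1, list(treat = 0), 1L), "missing covariate")
})

test_that("transition probabilities are a proper inverse multinomial logit", {
  m1 <- m1_config()
  th <- rep(0, m1$n_free)
  expect_equal(unname(transition_probabilities(th, m1, m1_covs(), 1L)), rep(1 / 8, 8))
  p2 <- transition_probabilities(th, m1, m1_covs(), 2L)
  expect_equal(unname(p2[c(1, 2, 8)]), rep(1 / 3, 3))
  expect_equal(sum(p2[3:7]), 0)
  p8 <- transition_probabilities(th, m1, m1_covs(), 8L)
  expect_equal(unname(p8), c(rep(0, 7), 1))
  # overflow contract: finite probabilities at |log odds| = 700
  cfg <- two_state_config()
  expect_equal(unname(transition_probabilities(c(700), cfg, list(), 1L)),
               c(0, 1), tolerance = 1e-12)
  expect_equal(unname(transition_probabilities(c(-700), cfg, list(), 1L)),
               c(1, 0), tolerance = 1e-12)
})

test_that("probability rows sum to one and vanish off-pattern for random draws", {
  set.seed(7)
  for (label in c("M1", "M2", "M7", "M10")) {
    cfg <- build_model_config(label)
    for (rep in 1:5) {
      th <- rnorm(cfg$n_free, 0, 2)
      covs <- m1_covs(treat = rbinom(1, 1, 0.5), female = runif(1),
                      lvef = rbinom(1, 1, 0.5), uk = rbinom(1, 1, 0.5),
                      age = runif(1, 40, 90))
      for (r in 1:8) {
        p <- transition_probabilities(th, cfg, covs, r)
        expect_equal(sum(p), 1, tolerance = 1e-12)
        expect_true(all(p[setdiff(1:8, permitted_dests(cfg$space, r))] == 0))
      }
    }
  }
})

test_that("permuting source states within the death tie leaves the likelihood unchanged", {
  m1 <- m1_config()
  set.seed(3)
  th <- rnorm(m1$n_free, 0, 0.5)
  # make the non-tied slots of rows 2 and 5 coincide, so swapping which source
  # state a death is attributed to only exercises the tied death parameters
  th[match("mu_55", m1$par_names)] <- th[match("mu_22", m1$par_names)]
  th[match("b_55_uk", m1$par_names)] <- th[match("b_22_uk", m1$par_names)]
  d1 <- rbind(m1_row(r = 2L, counts = c(3L, 20L, 0L, 0L, 0L, 0L, 0L, 1L)),
              m1_row(r = 5L, counts = c(3L, 0L, 0L, 0L, 20L, 0L, 0L, 0L), year = 2L))
  d2 <- rbind(m1_row(r = 2L, counts = c(3L, 20L, 0L, 0L, 0L, 0L, 0L, 0L)),
              m1_row(r = 5L, counts = c(3L, 0L, 0L, 0L, 20L, 0L, 0L, 1L), year = 2L))
  t1 <- transition_data(d1, icd_state_space())
  t2 <- transition_data(d2, icd_state_space())
  expect_equal(log_likelihood(th, t1, m1), log_likelihood(th, t2, m1))
})

test_that("model config JSON round trip is lossless", {
  for (label in c("M1", "M6", "M9")) {
    cfg <- build_model_config(label)
    path <- withr::local_tempfile(fileext = ".json")
    write_model_config(cfg, path)
    back <- read_model_config(path)
    expect_equal(back$n_free, cfg$n_free)
    expect_equal(back$par_names, cfg$par_names)
    expect_equal(back$slots, cfg$slots)
    expect_equal(back$age_transform, cfg$age_transform)
    expect_equal(back$space$permitted, cfg$space$permitted)
  }
})
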