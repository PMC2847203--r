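test_that("occupancy propagation starts at state 1 and respects absorption", {
  m1 <- m1_config()
  th <- default_true_theta(m1)
  prof <- typical_patient()
  expect_equal(unname(propagate_occupancy(th, m1, prof, 0L)),
               c(1, rep(0, 7)))
  # occupancy sums to one and death mass is non-decreasing
  days <- c(1L, 30L, 365L, 1200L)
  occ <- t(vapply(days, function(t) propagate_occupancy(th, m1, prof, t), numeric(8)))
  expect_equal(rowSums(occ), rep(1, length(days)), tolerance = 1e-10)
  expect_true(all(diff(occ[, 8]) >= 0))
  # certain death from every transient state -> all mass dead from day 1
  cfg <- two_state_config()
  expect_equal(unname(propagate_occupancy(c(700), cfg, patient_profile(63), 1L)),
               c(0, 1), tolerance = 1e-12)
  expect_equal(unname(propagate_occupancy(c(700), cfg, patient_profile(63), 50L)),
               c(0, 1), tolerance = 1e-12)
})

test_that("expected cost/benefit honours the horizon and degenerate dynamics", {
  cfg <- two_state_config()
  sched <- two_state_schedule(horizon_days = 0L)
  expect_equal(expected_cost_benefit(c(-3), cfg, patient_profile(63), sched, u = 1),
               c(cost = 500, qaly = 0))
  expect_equal(expected_cost_benefit(c(-3), cfg, patient_profile(63), sched, u = 0),
               c(cost = 100, qaly = 0))
  # certain death on day 1: only the initial cost remains
  sched2 <- two_state_schedule(horizon_days = 400L)
  expect_equal(expected_cost_benefit(c(700), cfg, patient_profile(63), sched2, u = 1),
               c(cost = 500, qaly = 0), tolerance = 1e-10)
})

test_that("the no-event limit reproduces the geometric-series closed form", {
  cfg <- two_state_config()
  Td <- 5L * 365L
  sched <- two_state_schedule(horizon_days = Td)
  got <- expected_cost_benefit(c(-700), cfg, patient_profile(63), sched, u = 1)
  rho <- daily_discount_factor(0.035)
  geo <- rho * (1 - rho^Td) / (1 - rho)
  expect_equal(unname(got["cost"]), 500 + 5 * geo, tolerance = 1e-8)
  expect_equal(unname(got["qaly"]), 0.75 / 365 * geo, tolerance = 1e-8)
})

test_that("expected cost decreases as the discount rate rises", {
  m1 <- m1_config()
  th <- default_true_theta(m1)
  costs <- vapply(c(0, 0.035, 0.1), function(d) {
    sched <- icd_cost_schedule()
    sched$annual_discount <- d
    sched$daily_factor <- daily_discount_factor(d)
    sched$horizon_days <- 3L * 365L
    expected_cost_benefit(th, m1, typical_patient(), sched, u = 1)[["cost"]]
  }, numeric(1))
  expect_true(all(diff(costs) < 0))
})

test_that("cohort propagation agrees with a seeded microsimulation", {
  m1 <- m1_config()
  th <- default_true_theta(m1)
  sched <- icd_cost_schedule()
  sched$horizon_days <- 4L * 365L
  det <- expected_cost_benefit(th, m1, typical_patient(), sched, u = 0)
  sim <- simulate_ce_microsim(th, m1, typical_patient(), sched, u = 0,
                              n = 4000L, seed = 17)
  expect_lt(abs(sim$cost - det[["cost"]]), 3 * sim$cost_se)
  expect_lt(abs(sim$qaly - det[["qaly"]]), 3 * sim$qaly_se)
})

test_that("run_ce switches only the treatment covariate and initial cost", {
  # a config where treatment is inert: the two-state model has no covariates
  cfg <- two_state_config()
  sched <- two_state_schedule(horizon_days = 200L)
  smp <- structure(list(draws = matrix(c(-5, -6, -7), ncol = 1,
                                       dimnames = list(NULL, "mu")),
                        config_label = "alive_dead"),
                   class = "posterior_sample")
  ce <- run_ce(smp, cfg, patient_profile(63), sched)
  expect_equal(nrow(ce), 3L)
  expect_equal(ce$dC, rep(500 - 100, 3))     # initial-cost difference only
  expect_equal(ce$dB, rep(0, 3))
  single <- run_ce(smp, cfg, patient_profile(63), sched, draws = 2L)
  expect_equal(nrow(single), 1L)
  expect_equal(single$cost1 - 500, single$cost0 - 100)
})

test_that("treatment effects flow through the device/drug arms", {
  m1 <- m1_config()
  th <- default_true_theta(m1)            # drug arm has higher mortality
  sched <- icd_cost_schedule()
  sched$horizon_days <- 3L * 365L
  icd <- expected_cost_benefit(th, m1, typical_patient(), sched, u = 1)
  aad <- expected_cost_benefit(th, m1, typical_patient(), sched, u = 0)
  expect_gt(icd[["qaly"]], aad[["qaly"]])
  expect_gt(icd[["cost"]], aad[["cost"]])
})

test_that("pce counts positive incremental net benefit draws", {
  ce <- structure(data.frame(dC = c(100, -50), dB = c(0.01, 0.02)),
                  class = c("ce_result", "data.frame"), lambda = 20000)
  expect_equal(unname(pce(ce, 20000)), 1)
  ce2 <- structure(data.frame(dC = c(5, 10, 1), dB = c(0, 0, 0)),
                   class = c("ce_result", "data.frame"), lambda = 20000)
  expect_equal(unname(pce(ce2, 31847)), 0)
  ce3 <- structure(data.frame(dC = c(-1, 1, -2, 2), dB = rep(0.5, 4)),
                   class = c("ce_result", "data.frame"), lambda = 0)
  expect_equal(unname(pce(ce3, 0)), 0.5)
  # vectorized over a lambda grid -> CEAC, and ICER uses ratio of means
  expect_equal(unname(pce(ce, c(0, 20000))), c(0.5, 1))
  s <- summary(ce, lambda = 20000)
  expect_equal(s$icer, mean(ce$dC) / mean(ce$dB))
  expect_error(pce(ce[0, ]), "empty")
})

test_that("cost schedule validation enforces the death-state and rate bounds", {
  expect_error(cost_schedule(c(1, 2), cbind(c(1, 1), c(1, 1)), c(0.75, 0.5),
                             0.035, 10L, 20000, alive_dead_state_space()),
               "zero cost and utility")
  expect_error(cost_schedule(c(1, 2), cbind(c(-1, 0), c(1, 0)), c(0.75, 0),
                             0.035, 10L, 20000, alive_dead_state_space()),
               "non-negative")
  expect_error(cost_schedule(c(1, 2), cbind(c(1, 0), c(1, 0)), c(0.75, 0),
                             1.2, 10L, 20000, alive_dead_state_space()),
               "discount")
  sched <- icd_cost_schedule()
  expect_equal(sched$initial_cost, c(aad = 1566, icd = 23841))
  expect_equal(sched$daily_cost[1, ], c(aad = 2.43, icd = 2.30))
  expect_equal(sched$horizon_days, 36500L)
})
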