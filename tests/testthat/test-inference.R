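# independent per-row oracle: linear predictors assembled directly from the
# slot table (no coefficient maps / engine aggregation), pmf via dmultinom
oracle_row_loglik <- function(theta, row, config) {
  r <- row$from_state
  x <- c(1, markovcea:::covariate_vector(config, as.list(row[c(config$baseline, "age")])))
  dests <- permitted_dests(config$space, r)
  ref <- reference_dest(config$space, r)
  eta <- setNames(rep(0, length(dests)), dests)
  sl <- config$slots[config$slots$r == r & config$slots$par_id > 0L, ]
  for (i in seq_len(nrow(sl)))
    eta[as.character(sl$s[i])] <- eta[as.character(sl$s[i])] +
      theta[sl$par_id[i]] * x[sl$k[i] + 1L]
  p <- exp(eta - max(eta)); p <- p / sum(p)
  counts <- as.numeric(row[paste0("n", seq_len(config$space$n))])
  dmultinom(counts[dests], prob = p, log = TRUE)
}

test_that("log likelihood matches direct multinomial evaluation", {
  m1 <- m1_config()
  expect_equal(log_likelihood(rep(0, 59), empty_m1_data(), m1), 0)

  one <- transition_data(m1_row(counts = c(0L, 1L, rep(0L, 6L))), icd_state_space())
  expect_equal(log_likelihood(rep(0, 59), one, m1), log(1 / 8))

  yr <- transition_data(m1_row(counts = c(363L, 1L, 1L, rep(0L, 5L))), icd_state_space())
  expect_equal(log_likelihood(rep(0, 59), yr, m1),
               lgamma(366) - lgamma(364) + 365 * log(1 / 8))
  expect_equal(log_likelihood(rep(0, 59), yr, m1),
               dmultinom(c(363, 1, 1, rep(0, 5)), prob = rep(1 / 8, 8), log = TRUE))

  # counts on a forbidden pair are rejected with the row number
  bad <- m1_row(r = 2L, counts = c(0L, 5L, 1L, rep(0L, 5L)))
  expect_error(transition_data(bad, icd_state_space()), "row 1.*non-permitted")
})

test_that("log likelihood agrees with the slot-table/dmultinom oracle on random data", {
  set.seed(11)
  for (label in c("M1", "M7")) {
    cfg <- build_model_config(label)
    for (rep in 1:4) {
      th <- rnorm(cfg$n_free, 0, 0.8)
      rows <- do.call(rbind, lapply(1:6, function(i) {
        r <- sample(c(1L, 2L, 5L), 1L)
        dests <- permitted_dests(icd_state_space(), r)
        counts <- integer(8)
        counts[dests] <- as.integer(rmultinom(1, sample(5:60, 1), rep(1, length(dests))))
        m1_row(r = r, counts = counts, patient = i,
               covs = m1_covs(treat = rbinom(1, 1, 0.5), female = runif(1),
                              lvef = rbinom(1, 1, 0.5), uk = rbinom(1, 1, 0.5),
                              age = sample(45:85, 1)))
      }))
      dat <- transition_data(rows, icd_state_space())
      want <- sum(vapply(seq_len(nrow(dat)), function(i)
        oracle_row_loglik(th, dat[i, ], cfg), numeric(1)))
      expect_equal(log_likelihood(th, dat, cfg), want, tolerance = 1e-10)
      expect_equal(log_likelihood(th, dat, cfg, per_row = TRUE),
                   vapply(seq_len(nrow(dat)), function(i)
                     oracle_row_loglik(th, dat[i, ], cfg), numeric(1)),
                   tolerance = 1e-10)
    }
  }
})

test_that("log prior is a sum of normal densities with the documented defaults", {
  m1 <- m1_config()
  pr <- prior_spec(m1)
  expect_equal(pr$mean[pr$par == "b_D_treat"], 0.414)
  expect_equal(pr$sd[pr$par == "b_D_treat"], 0.16)
  expect_true(all(pr$sd[pr$par != "b_D_treat"] == 10))
  expect_equal(log_prior(pr$mean, pr), sum(log(1 / (pr$sd * sqrt(2 * pi)))))
  # single parameter at one prior sd from the mean
  cfg <- two_state_config()
  pr1 <- prior_spec(cfg)
  expect_equal(log_prior(10, pr1), dnorm(1, log = TRUE) - log(10))
  # translation invariance
  pr2 <- prior_spec(m1, overrides = setNames(
    lapply(seq_along(m1$par_names), function(i) c(i / 10, 2)), m1$par_names))
  th <- rnorm(59)
  pr3 <- pr2; pr3$mean <- pr2$mean + 1.7
  expect_equal(log_prior(th, pr2), log_prior(th + 1.7, pr3))
  pr_bad <- pr1; pr_bad$sd <- -1
  expect_error(log_prior(0, pr_bad), "sd must be positive")
})

test_that("prior-only runs reproduce the prior, including the informative death effect", {
  m1 <- m1_config()
  smp <- quick_fit(empty_m1_data(), m1, n_iter = 3000L, n_burnin = 500L, seed = 5)
  s <- summary(smp)
  i <- match("b_D_treat", s$par)
  expect_equal(s$mean[i], 0.414, tolerance = 0.02)
  expect_equal(s$sd[i], 0.16, tolerance = 0.03)
  # diffuse parameters: mean within MC error of 0, sd near 10
  other <- s[-i, ]
  expect_true(all(abs(other$mean) < 10 * 4 / sqrt(100)))  # ESS-conservative bound
  expect_equal(median(other$sd), 10, tolerance = 0.2)
})

test_that("MCMC matches dense numerical integration on the two-state model", {
  fx <- fixture_suite()
  dat <- fx$a$data
  cfg <- fx$a$config
  smp <- quick_fit(dat, cfg, n_iter = 6000L, n_burnin = 1000L, seed = 9)
  # dense-grid posterior: binomial-style likelihood x normal(0,10) prior
  grid <- seq(-9, 0, length.out = 4001)
  lp <- vapply(grid, function(m) log_likelihood(m, dat, cfg), numeric(1)) +
    dnorm(grid, 0, 10, log = TRUE)
  w <- exp(lp - max(lp)); w <- w / sum(w)
  cdf <- cumsum(w)
  want <- vapply(c(0.1, 0.25, 0.5, 0.75, 0.9),
                 function(q) grid[which.min(abs(cdf - q))], numeric(1))
  got <- unname(quantile(smp$draws[, 1], c(0.1, 0.25, 0.5, 0.75, 0.9)))
  expect_equal(got, want, tolerance = 0.05)
  expect_equal(mean(smp$draws[, 1]), sum(grid * w), tolerance = 0.05)
})

test_that("chains are reproducible by seed and agree across seeds", {
  fx <- fixture_suite()
  s1 <- quick_fit(fx$a$data, fx$a$config, n_iter = 2500L, seed = 21)
  s1b <- quick_fit(fx$a$data, fx$a$config, n_iter = 2500L, seed = 21)
  expect_identical(s1$draws, s1b$draws)
  s2 <- quick_fit(fx$a$data, fx$a$config, n_iter = 2500L, seed = 22)
  expect_false(identical(s1$draws, s2$draws))
  # split-chain Gelman-Rubin over the two seeds
  chains <- cbind(s1$draws[, 1], s2$draws[, 1])
  n <- nrow(chains)
  W <- mean(apply(chains, 2, var))
  B <- n * var(colMeans(chains))
  rhat <- sqrt(((n - 1) / n * W + B / n) / W)
  expect_lt(rhat, 1.1)
})

test_that("parameter recovery holds on a medium synthetic cohort", {
  fx <- fixture_suite()
  smp <- quick_fit(fx$b$data, fx$b$config, n_iter = 1500L, n_burnin = 600L, seed = 31)
  s <- summary(smp)
  truth <- fx$b$truth[s$par]
  z <- abs(s$mean - truth) / s$sd
  expect_gt(mean(z < 3), 0.95)
})

test_that("posterior-mean linear predictors average draws and equal predictors at the mean", {
  fx <- fixture_suite()
  m1 <- m1_config()
  dat <- transition_data(rbind(
    m1_row(counts = c(360L, 2L, 1L, 1L, 0L, 0L, 1L, 0L)),
    m1_row(r = 2L, counts = c(4L, 9L, 0L, 0L, 0L, 0L, 0L, 1L), year = 2L)),
    icd_state_space())
  smp <- quick_fit(dat, m1, n_iter = 40L, n_burnin = 50L, seed = 2)

  single <- smp; single$draws <- smp$draws[1L, , drop = FALSE]
  eta1 <- posterior_mean_linear_predictors(single, dat, m1)
  expect_equal(eta1[1, 2:8],
               linear_predictors(smp$draws[1L, ], m1, m1_covs(), 1L),
               ignore_attr = "names")
  two <- smp; two$draws <- smp$draws[1:2, , drop = FALSE]
  eta2 <- posterior_mean_linear_predictors(two, dat, m1)
  e_a <- linear_predictors(smp$draws[1L, ], m1, m1_covs(), 1L)
  e_b <- linear_predictors(smp$draws[2L, ], m1, m1_covs(), 1L)
  expect_equal(unname(eta2[1, 2:8]), unname((e_a + e_b) / 2))
  # linearity: averaging predictors == predictors at averaged theta
  full <- posterior_mean_linear_predictors(smp, dat, m1)
  at_mean <- linear_predictors(colMeans(smp$draws), m1, m1_covs(), 1L)
  expect_equal(unname(full[1, 2:8]), unname(at_mean), tolerance = 1e-10)
  expect_true(all(full[, 1] == 0))            # reference column
  expect_true(all(is.na(full[2, 3:7])))       # non-permitted pairs
})
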