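test_that("gamma frailty has mean 1 and variance theta", {
  expect_identical(draw_frailty(0, 5), rep(1, 5))
  set.seed(101)
  z <- draw_frailty(0.25, 1e5)
  expect_true(all(z > 0))
  expect_lt(abs(mean(z) - 1), 0.005)
  expect_lt(abs(var(z) - 0.25), 0.01)
  expect_error(draw_frailty(-0.1), ">= 0")
})

test_that("the recursion reproduces closed-form event times for given uniforms", {
  wb <- hazard_model("weibull", scale = 1, shape = 2)
  # -log a = 1, 3: t1 = 1, t2 = 1 + (sqrt(1 + 3) - 1) = 2
  path <- simulate_subject(wb, 1, riskfree_spec(), censor_time = 10,
                           uniforms = c(exp(-1), exp(-3), exp(-200)))
  expect_equal(path$times, c(1, 2))
  # risk-free d = 0.5 after every event: T2 = sqrt(3 + 1.5^2)
  path <- simulate_subject(wb, 1, riskfree_spec(0.5, 1), censor_time = 10,
                           uniforms = c(exp(-1), exp(-3), exp(-200)),
                           riskfree_uniforms = rep(0.5, 3))
  expect_equal(path$times[1:2], c(1, sqrt(5.25)))
  expect_true(all(path$riskfree))
  # no event before censoring when -log(a1) > Lambda(C) * factor
  path <- simulate_subject(wb, 1, censor_time = 2,
                           uniforms = exp(-(cum_hazard(wb, 2) + 0.1)))
  expect_length(path$times, 0)
})

test_that("a subject's records tile [0, C] with risk-free holes", {
  wb <- hazard_model("weibull", scale = 4 / sqrt(2), shape = 0.5)
  tab <- simulate_recurrent(wb, riskfree = riskfree_spec(0.25, 1),
                            censoring = censoring_spec(2), n = 30, seed = 4)
  expect_s3_class(tab, "cp_table")
  expect_true(all(tab$start < tab$stop))
  by_id <- split(tab, tab$id)
  for (s in by_id) {
    expect_equal(s$start[1], 0)
    k <- nrow(s)
    # last record censored at C = 2 unless it ends in an event
    expect_true(s$stop[k] == 2 || s$status[k] == 1)
    if (k > 1) {
      # holes of exactly d after events followed by risk-free intervals
      expect_true(all(s$start[-1] - s$stop[-k] >= 0))
      # intervals disjoint and ordered
      expect_true(all(diff(s$start) > 0))
    }
    # with p = 1 consecutive events are at least d apart
    ev <- s$stop[s$status == 1]
    if (length(ev) > 1) expect_true(all(diff(ev) >= 0.25))
  }
})

test_that("dataset simulation is seed-deterministic and leaves the RNG alone", {
  wb <- hazard_model("weibull", scale = 2, shape = 1.5)
  eff <- effect_spec(beta = c(0.5, -0.2),
                     covariates = list(cov_bernoulli(0.4), cov_normal(0, 1)),
                     frailty_variance = 0.3)
  set.seed(77)
  before <- .Random.seed
  a <- simulate_recurrent(wb, eff, censoring = censoring_spec(2, 0.5),
                          n = 50, seed = 123, keep_frailty = TRUE)
  expect_identical(.Random.seed, before)
  b <- simulate_recurrent(wb, eff, censoring = censoring_spec(2, 0.5),
                          n = 50, seed = 123, keep_frailty = TRUE)
  expect_identical(a, b)
  c_ <- simulate_recurrent(wb, eff, censoring = censoring_spec(2, 0.5),
                           n = 50, seed = 124)
  expect_false(identical(a$stop, c_$stop))
})

test_that("expected events per subject equals the cumulative hazard", {
  wb <- hazard_model("weibull", scale = 4 / sqrt(2), shape = 0.5)
  counts <- unlist(lapply(1:10, function(s) {
    tab <- simulate_recurrent(wb, censoring = censoring_spec(2),
                              n = 100, seed = 300 + s)
    events_per_subject(tab, 100)
  }))
  expect_lt(abs(mean(counts) - 4), 0.15)
  # risk-free intervals strictly reduce the expected number of events
  counts_rf <- unlist(lapply(1:10, function(s) {
    tab <- simulate_recurrent(wb, riskfree = riskfree_spec(0.25, 1),
                              censoring = censoring_spec(2),
                              n = 100, seed = 300 + s)
    events_per_subject(tab, 100)
  }))
  expect_lt(mean(counts_rf), mean(counts))
})

test_that("covariate generators honour their contracts", {
  wb <- hazard_model("weibull", scale = 1, shape = 1)
  eff <- effect_spec(beta = c(0.3, 0, 0.1),
                     covariates = list(cov_balanced(), cov_fixed(2),
                                       cov_bernoulli(0.5)))
  tab <- simulate_recurrent(wb, eff, censoring = censoring_spec(1),
                            n = 51, seed = 9)
  one_per_id <- tab[!duplicated(tab$id), ]
  expect_identical(sum(one_per_id$x1), 25)  # exactly floor(n/2) ones
  expect_true(all(one_per_id$x2 == 2))
  expect_true(all(one_per_id$x3 %in% c(0, 1)))
})

test_that("single-subject tables end in a censoring record", {
  wb <- hazard_model("weibull", scale = 1, shape = 1)
  tab <- simulate_recurrent(wb, censoring = censoring_spec(2), n = 1,
                            seed = 5)
  expect_gte(nrow(tab), 1)
  k <- nrow(tab)
  expect_true(tab$stop[k] == 2 || tab$status[k] == 1)
})

test_that("invalid simulation inputs are rejected", {
  wb <- hazard_model("weibull", scale = 1, shape = 1)
  expect_error(simulate_recurrent(wb, censoring = censoring_spec(2), n = 0),
               "n must be")
  expect_error(simulate_subject(wb, effect_factor = 0, censor_time = 1),
               "effect_factor")
  expect_error(simulate_subject(wb, censor_time = -1), "censor_time")
  expect_error(effect_spec(beta = 1, covariates = list()), "same length")
  expect_error(riskfree_spec(-1, 0.5), "duration")
  expect_error(censoring_spec(2, 1.2), "dropout_prob")
})
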