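test_that("Nelson-Aalen increments follow the hand count", {
  # one censored subject, no events: estimate identically 0
  t0 <- data.frame(id = 1, start = 0, stop = 2, status = 0)
  na0 <- nelson_aalen(t0)
  expect_length(na0$time, 0)
  expect_identical(predict(na0, c(0.5, 2)), c(0, 0))

  # two subjects on (0, 2], one event at t = 1: increment 1/2
  t1 <- data.frame(id = c(1, 1, 2), start = c(0, 1, 0),
                   stop = c(1, 2, 2), status = c(1, 0, 0))
  na1 <- nelson_aalen(t1)
  expect_equal(na1$time, 1)
  expect_equal(na1$n_risk, 2L)
  expect_equal(na1$cumhaz, 0.5)
  expect_equal(predict(na1, c(0.9, 1, 1.7)), c(0, 0.5, 0.5))
})

test_that("risk-free holes reduce the Nelson-Aalen denominator", {
  # subject 1 is off risk on (1, 1.5]; subject 2 events at 1.25
  tab <- data.frame(id = c(1, 1, 2, 2),
                    start = c(0, 1.5, 0, 1.25),
                    stop = c(1, 2, 1.25, 2),
                    status = c(1, 0, 1, 0))
  na <- nelson_aalen(tab)
  expect_equal(na$time, c(1, 1.25))
  expect_equal(na$n_risk, c(2L, 1L))   # subject 1 absent at t = 1.25
  expect_equal(na$increment, c(0.5, 1))
})

test_that("adding an event-free subject only lowers the estimate", {
  tab <- data.frame(id = c(1, 1, 2), start = c(0, 1, 0),
                    stop = c(1, 2, 2), status = c(1, 0, 0))
  bigger <- rbind(tab, data.frame(id = 3, start = 0, stop = 2, status = 0))
  a <- nelson_aalen(tab)
  b <- nelson_aalen(bigger)
  expect_identical(a$n_event, b$n_event)
  expect_true(all(b$n_risk >= a$n_risk))
  expect_true(all(b$increment <= a$increment))
})

test_that("a symmetric two-subject layout gives beta = 0", {
  tab <- data.frame(id = c(1, 1, 2, 2),
                    start = c(0, 1, 0, 0.5),
                    stop = c(1, 2, 0.5, 2),
                    status = c(1, 0, 1, 0),
                    x1 = c(1, 1, 0, 0))
  fit <- agfit(tab)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), 0, tolerance = 1e-8)
  # with two subjects the cluster scores cancel exactly, so use naive SEs
  wt <- wald_test(fit, robust = FALSE)
  expect_equal(wt$p, 1, tolerance = 1e-6)
  expect_false(wt$reject)
})

test_that("monotone likelihood is flagged, never silently returned", {
  # x = 1 subject always fails first: likelihood increases in beta forever
  tab <- data.frame(id = c(1, 2), start = c(0, 0), stop = c(1, 2),
                    status = c(1, 1), x1 = c(1, 0))
  fit <- agfit(tab)
  expect_false(fit$converged)
  expect_error(wald_test(fit), "converged")
})

test_that("degenerate analysis inputs raise errors", {
  expect_error(agfit(data.frame(id = 1, start = 0, stop = 1, status = 0,
                                x1 = 1)), "constant")
  expect_error(agfit(data.frame(id = c(1, 2), start = 0, stop = c(1, 2),
                                status = 0, x1 = c(0, 1))), "no events")
  expect_error(nelson_aalen(data.frame(id = 1, start = 1, stop = 1,
                                       status = 1)), "start >= stop")
  expect_error(nelson_aalen(data.frame(start = 0, stop = 1)), "status")
})

test_that("fit agrees with the reference implementation on start-stop data", {
  skip_if_not_installed("survival")
  hm <- hazard_model("weibull", scale = 4 / sqrt(2), shape = 0.5)
  eff <- effect_spec(beta = c(1, -0.5),
                     covariates = list(cov_bernoulli(0.5), cov_normal(0, 1)),
                     frailty_variance = 0.2)
  d <- simulate_recurrent(hm, eff, censoring = censoring_spec(2, 0.3),
                          n = 200, seed = 21)
  fit <- agfit(d)
  cf <- survival::coxph(
    survival::Surv(start, stop, status) ~ x1 + x2 + survival::cluster(id),
    data = d, ties = "breslow",
    control = survival::coxph.control(timefix = FALSE))
  expect_equal(unname(coef(fit)), unname(coef(cf)), tolerance = 1e-6)
  expect_equal(unname(fit$naive_se), unname(sqrt(diag(cf$naive.var))),
               tolerance = 1e-6)
  expect_equal(unname(fit$robust_se), unname(sqrt(diag(cf$var))),
               tolerance = 1e-6)
})

test_that("single-record-per-subject data reduce to classical Cox regression", {
  skip_if_not_installed("survival")
  hm <- hazard_model("gompertz", scale = 0.8, shape = 0.4)
  eff <- effect_spec(beta = 0.7, covariates = list(cov_bernoulli(0.5)))
  d <- simulate_recurrent(hm, eff, censoring = censoring_spec(3), n = 150,
                          seed = 31)
  first <- d[!duplicated(d$id), ]
  fit <- agfit(first)
  cf <- survival::coxph(survival::Surv(stop, status) ~ x1, data = first,
                        ties = "breslow", robust = TRUE,
                        control = survival::coxph.control(timefix = FALSE))
  expect_equal(unname(coef(fit)), unname(coef(cf)), tolerance = 1e-6)
  expect_equal(unname(fit$naive_se), sqrt(diag(cf$naive.var)),
               tolerance = 1e-6)
  expect_equal(unname(fit$robust_se), sqrt(diag(cf$var)),
               tolerance = 1e-6)
})

test_that("Wald tests use the requested SE flavour and level", {
  hm <- hazard_model("weibull", scale = 4 / sqrt(2), shape = 0.5)
  eff <- effect_spec(beta = 1, covariates = list(cov_bernoulli(0.5)),
                     frailty_variance = 0.4)
  d <- simulate_recurrent(hm, eff, censoring = censoring_spec(2), n = 120,
                          seed = 41)
  fit <- agfit(d)
  wr <- wald_test(fit, robust = TRUE)
  wn <- wald_test(fit, robust = FALSE)
  expect_equal(wr$se, unname(fit$robust_se))
  expect_equal(wn$se, unname(fit$naive_se))
  expect_equal(wr$p, 2 * pnorm(-abs(unname(coef(fit)) / wr$se)))
  expect_identical(wr$reject, abs(wr$z) > qnorm(0.975))
  # a stricter level can only lose rejections
  expect_true(wald_test(fit, level = 0.05)$reject >=
                wald_test(fit, level = 1e-6)$reject)
  expect_error(wald_test(fit, level = 1.5), "level")
})
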