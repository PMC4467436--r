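test_that("Kaplan-Meier product-limit estimator: hand examples and conventions", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$time, c(1, 3))
  expect_equal(km2$surv, c(2 / 3, 0))
  expect_warning(flat <- km_estimate(c(5, 10), c(0, 0)), "no events")
  expect_length(flat$surv, 0)
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "nonnegative")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(6)
  tt <- round(rexp(40, 0.1), 1)
  km <- km_estimate(tt, rep(1, 40))
  expect_equal(km$surv, vapply(km$time, function(t) mean(tt > t), numeric(1)),
               tolerance = 1e-12)
})

test_that("KM estimates and Greenwood SE match the survival package", {
  set.seed(7)
  tt <- sample(1:30, 50, replace = TRUE)  # heavy ties
  ev <- rbinom(50, 1, 0.7)
  km <- km_estimate(tt, ev)
  sf <- summary(survival::survfit(survival::Surv(tt, ev) ~ 1))
  expect_equal(km$time, sf$time)
  expect_equal(km$surv, sf$surv, tolerance = 1e-12)
  expect_equal(km$se, sf$std.err, tolerance = 1e-12)
})

test_that("log-rank test: degenerate, hand-checkable and oracle cases", {
  tt <- c(3, 5, 8, 10, 12, 15); ev <- c(1, 1, 0, 1, 1, 1)
  same <- logrank_test(c(tt, tt), c(ev, ev), rep(1:2, each = 6))
  expect_equal(unname(same$statistic["chisq"]), 0, tolerance = 1e-12)
  expect_equal(same$p.value, 1)

  g <- rep(1:2, 3)
  mine <- logrank_test(tt, ev, g)
  ref <- survival::survdiff(survival::Surv(tt, ev) ~ g)
  expect_equal(unname(mine$statistic["chisq"]), ref$chisq, tolerance = 1e-10)

  # three groups, with ties
  set.seed(8)
  tt3 <- sample(1:20, 60, replace = TRUE); ev3 <- rbinom(60, 1, 0.8)
  g3 <- rep(1:3, 20)
  mine3 <- logrank_test(tt3, ev3, g3)
  ref3 <- survival::survdiff(survival::Surv(tt3, ev3) ~ g3)
  expect_equal(unname(mine3$statistic["chisq"]), ref3$chisq,
               tolerance = 1e-10)
  expect_equal(unname(mine3$statistic["df"]), 2)
  expect_error(logrank_test(tt, ev, rep(1, 6)), "2 non-empty groups")
})

test_that("Cox fit matches the reference implementation on tied fixtures", {
  set.seed(9)
  for (i in 1:5) {
    n <- 20
    d <- data.frame(time = sample(1:12, n, replace = TRUE),
                    event = rbinom(n, 1, 0.7),
                    x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
    if (sum(d$event) < 3 || sd(d$x2) == 0) next
    f <- cox_fit(d, c("x1", "x2"))
    g <- survival::coxph(survival::Surv(time, event) ~ x1 + x2, data = d,
                         ties = "efron")
    expect_equal(coef(f), coef(g), tolerance = 1e-6)
    expect_equal(unname(as.numeric(logLik(f))), g$loglik[2], tolerance = 1e-8)
    expect_equal(f$se, sqrt(diag(vcov(g))), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("Cox null recovery, invariances and error handling", {
  set.seed(10)
  n <- 2000
  d <- data.frame(time = rexp(n, 0.002), event = 1, x = rnorm(n))
  f <- cox_fit(d, "x")
  expect_lt(abs(coef(f)), 0.1)
  ci <- confint(f)
  expect_lt(ci[1], 0); expect_gt(ci[2], 0)

  # time-unit invariance and covariate-rescaling equivariance
  d_days <- d; d_days$time <- d$time * 24
  expect_equal(coef(cox_fit(d_days, "x")), coef(f), tolerance = 1e-8)
  d_scaled <- d; d_scaled$x <- d$x / 10
  expect_equal(unname(coef(cox_fit(d_scaled, "x"))), unname(coef(f)) * 10,
               tolerance = 1e-6)

  d$const <- 1
  expect_error(cox_fit(d, c("x", "const")), "constant covariate.*const")
  expect_error(cox_fit(data.frame(time = 1:3, event = 0, x = rnorm(3)), "x"),
               "at least one event")
  d$x[1:5] <- NA
  expect_message(cox_fit(d[1:100, ], "x"), "dropping 5")
})

test_that("monotone-likelihood divergence is detected and flagged", {
  d <- data.frame(time = 1:20, event = rep(1, 20),
                  x = c(rep(1, 10), rep(0, 10)))  # x=1 always dies first
  expect_warning(f <- cox_fit(d, "x"), "divergence")
  expect_true(f$diverged)
})

test_that("predicted curves: centering identity and monotonicity", {
  set.seed(11)
  n <- 300
  x <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.002 * exp(0.7 * x))
  d <- data.frame(time = tt, event = 1, x = x, age = rnorm(n, 58, 10))
  f <- cox_fit(d, c("x", "age"))
  cv <- predicted_curves(f, "x", levels = c(0, 1))
  # higher risk level gives a pointwise lower curve
  expect_true(all(cv[[2]]$surv <= cv[[1]]$surv))
  # profile at the dataset means reproduces the baseline curve
  cv_mean <- predicted_curves(f, "x", levels = f$means["x"])
  bh <- coexsig:::breslow_basehaz(f)
  expect_equal(cv_mean[[1]]$surv, exp(-bh$cumhaz), tolerance = 1e-12)
  expect_error(predicted_curves(f, "x", profile = c(nope = 1)),
               "absent from the model")
  expect_error(predicted_curves(f, "zz"), "not a model covariate")
})

test_that("per-subtype analysis recovers a planted treatment interaction", {
  cfg <- sim_config(10, 2000, subtype_proportions = c(A = 0.5, B = 0.5),
                    survival = list(treatment_log_hr = data.frame(
                      subtype = "A", treatment = "radiotherapy",
                      log_hr = -1.25),
                      censoring_rate = 1e-4, accrual_horizon = 3650),
                    rng_seed = 13)
  sim <- simulate_expression(cfg)
  cl <- simulate_clinical(cfg, sim$truth)
  res <- subtype_treatment_analysis(cl, sim$truth$sample_subtype)
  tab <- res$table
  a_rad <- tab[tab$subtype == "A" & tab$treatment == "radiotherapy", ]
  b_rad <- tab[tab$subtype == "B" & tab$treatment == "radiotherapy", ]
  expect_gt(a_rad$hr, 0.22); expect_lt(a_rad$hr, 0.37)
  expect_lt(b_rad$ci_lower, 1); expect_gt(b_rad$ci_upper, 1)

  # a sparse stratum is analyzed but flagged
  few <- cl[c(which(cl$subtype == "A")[1:40], which(cl$subtype == "B")), ]
  few$subtype[1:40] <- "tiny"
  few <- few[c(1:40, which(few$subtype == "B")[1:500]), ]
  few$event[1:40] <- c(rep(1, 5), rep(0, 35))
  expect_warning(subtype_treatment_analysis(few, setNames(few$subtype,
                                                          few$sample)),
                 "fewer than 10 events")
})
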