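test_that("Kaplan-Meier estimates match hand-computed product limits", {
  km <- km_estimate(data.frame(time = c(1, 2, 3), event = c(1, 1, 1)))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # censoring at 2 leaves the curve unchanged there
  km2 <- km_estimate(data.frame(time = c(1, 2, 3), event = c(1, 0, 1)))
  expect_equal(km2$surv[km2$time == 1], 2 / 3)
  expect_equal(km2$surv[km2$time == 3], 0)
  expect_true(all(diff(km2$surv) <= 0))
  expect_true(all(km2$lower <= km2$surv + 1e-12 &
                    km2$surv <= km2$upper + 1e-12))
  expect_warning(km_estimate(data.frame(time = 1:3, event = c(0, 0, 0))),
                 "zero events")
})

test_that("the empirical KM curve tracks the true exponential survivor function", {
  set.seed(40)
  t <- rexp(200, 1)
  km <- km_estimate(data.frame(time = t, event = rep(1, 200)))
  expect_lt(max(abs(km$surv - exp(-km$time))), 0.1)
  # time-scale invariance: survival values unchanged, axis rescaled
  km5 <- km_estimate(data.frame(time = 5 * t, event = rep(1, 200)))
  expect_equal(km5$surv, km$surv)
  expect_equal(km5$time, 5 * km$time)
})

test_that("log-rank matches the hand-computed 4-subject fixture", {
  # group a: events at 1 and 3; group b: event at 2, censored at 4.
  # observed-minus-expected for a = 2 - (1/2 + 1/3 + 1/2) = 2/3,
  # variance = 1/4 + 2/9 + 1/4 = 13/18, chi-square = (2/3)^2/(13/18) = 8/13.
  d <- data.frame(time = c(1, 3, 2, 4), event = c(1, 1, 1, 0),
                  grp = c("a", "a", "b", "b"))
  lr <- logrank_test(d, "grp")
  expect_equal(lr$statistic, 8 / 13, tolerance = 1e-10)
  expect_equal(lr$df, 1L)
  expect_equal(lr$p_value, pchisq(8 / 13, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  # swapping group labels leaves the statistic unchanged
  d2 <- d; d2$grp <- c("b", "b", "a", "a")
  expect_equal(logrank_test(d2, "grp")$statistic, lr$statistic)
  # two identical groups: no signal
  sym <- data.frame(time = rep(1:3, 2), event = 1,
                    grp = rep(c("a", "b"), each = 3))
  expect_equal(logrank_test(sym, "grp")$statistic, 0, tolerance = 1e-12)
  expect_equal(logrank_test(sym, "grp")$p_value, 1)
  expect_error(logrank_test(data.frame(time = 1:3, event = 1, grp = "a"),
                            "grp"), "two groups")
})

test_that("Cox fits expose HRs with Wald CIs and reject degenerate inputs", {
  set.seed(41)
  n <- 400
  g <- factor(rep(c("high", "low"), n / 2), levels = c("high", "low"))
  d <- data.frame(time = rexp(n, 0.1 * ifelse(g == "low", 2, 1)),
                  event = 1, grp = g)
  fit <- cox_fit(d, "grp")
  expect_s3_class(fit, "cox_fit")
  expect_equal(fit$hazard_ratios$hr, exp(unname(fit$coefficients)))
  expect_true(fit$hazard_ratios$lower < fit$hazard_ratios$hr &
                fit$hazard_ratios$hr < fit$hazard_ratios$upper)
  expect_lte(fit$loglik_null, fit$loglik)
  expect_error(cox_fit(data.frame(time = 1:4, event = c(1, 1, 0, 1),
                                  grp = "a"), "grp"), "constant")
  # complete separation is an explicit error, never a silent huge HR
  sep <- data.frame(time = c(1, 2, 3, 10, 11, 12),
                    event = c(1, 1, 1, 1, 1, 1),
                    grp = rep(c("b", "a"), each = 3))
  expect_error(suppressWarnings(cox_fit(sep, "grp")),
               "separation|converge|diverged")
})

test_that("row order does not affect log-rank or Cox results", {
  set.seed(42)
  n <- 120
  d <- data.frame(time = rexp(n, 0.2), event = rbinom(n, 1, 0.7),
                  grp = sample(c("high", "low"), n, TRUE))
  perm <- sample(n)
  expect_equal(logrank_test(d[perm, ], "grp")$statistic,
               logrank_test(d, "grp")$statistic, tolerance = 1e-12)
  expect_equal(cox_fit(d[perm, ], "grp")$coefficients,
               cox_fit(d, "grp")$coefficients, tolerance = 1e-9)
})

test_that("Breslow and Efron ties agree exactly on tie-free data", {
  set.seed(43)
  d <- data.frame(time = rexp(150, 0.2), event = 1,
                  grp = sample(c("high", "low"), 150, TRUE))
  expect_equal(cox_fit(d, "grp", ties = "breslow")$coefficients,
               cox_fit(d, "grp", ties = "efron")$coefficients,
               tolerance = 1e-12)
})

test_that("nested likelihood-ratio tests behave at the boundaries", {
  set.seed(44)
  n <- 300
  d <- data.frame(time = rexp(n, 0.2), event = rbinom(n, 1, 0.8),
                  x = rnorm(n), z = rnorm(n))
  full <- cox_fit(d, c("x", "z"))
  expect_equal(lrt_nested(full, full)$statistic, 0)
  expect_equal(lrt_nested(full, full)$p_value, 1)
  reduced <- cox_fit(d, "x")
  lrt <- lrt_nested(full, reduced)
  expect_equal(lrt$df, 1L)
  expect_error(lrt_nested(reduced, full), "nested")
  other <- cox_fit(d[1:200, ], "x")
  expect_error(lrt_nested(full, other), "different records")
})

test_that("the LRT detects a true simulated effect at cohort scale", {
  set.seed(45)
  rejections <- replicate(40, {
    n <- 1500
    cls <- binary_proximity_frame(n)$frame$proximity_class
    d <- simulate_step_survival(cls, hr_low = 2)
    d$grp <- factor(cls, levels = c("high", "low"))
    d$noise <- rnorm(n)
    full <- cox_fit(d, c("noise", "grp"))
    reduced <- cox_fit(d, "noise")
    lrt_nested(full, reduced)$p_value < 0.05
  })
  expect_gt(mean(rejections), 0.9)
})

test_that("the proportionality test is calibrated and detects reversal", {
  set.seed(46)
  # smoke bound: proportional data, pure-noise covariate
  d <- data.frame(time = rexp(500, 0.2), event = rbinom(500, 1, 0.8),
                  x = rnorm(500))
  z <- ph_test(cox_fit(d, "x"))
  expect_gt(z$p_value[z$term == "x"], 0.001)
  expect_error(ph_test(cox_fit(
    data.frame(time = c(1, 2, 9, 10), event = c(1, 0, 0, 1),
               x = c(0.3, 1.2, -0.5, 0.8)), "x")), "3 events")

  # an effect that reverses sign mid-follow-up is flagged
  set.seed(47)
  reversal_times <- function(x, t0 = 5, h_hi = 0.4, h_lo = 0.05,
                             h_ref = 0.15) {
    n <- length(x)
    u <- -log(runif(n))
    t <- ifelse(x == 0, u / h_ref,
                ifelse(u < h_hi * t0, u / h_hi, t0 + (u - h_hi * t0) / h_lo))
    t
  }
  rejected <- replicate(50, {
    x <- rbinom(1500, 1, 0.5)
    d <- data.frame(time = reversal_times(x), event = 1, x = x)
    z <- ph_test(cox_fit(d, "x"))
    z$p_value[z$term == "x"] < 0.05
  })
  expect_gt(mean(rejected), 0.8)
})
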