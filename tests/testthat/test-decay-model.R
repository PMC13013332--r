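test_that("model_value obeys its closed-form identities", {
  # day 0 equals the scale, for any rate/offset
  expect_equal(model_value(0.37, 0.12, 10, 0), 10)
  # asymptote Bi * c
  expect_equal(model_value(0.1, 0.3, 10, 1e9), 3)
  # pure half-life with zero offset
  expect_equal(model_value(log(2) / 8, 0, 16, 8), 8)
  # strictly decreasing in day for c < 1
  v <- model_value(0.05, 0.2, 12, 0:100)
  expect_true(all(diff(v) < 0))
})

test_that("profile_scale matches its closed form and a grid-search oracle", {
  # single observation at day 0: f(0) = 1, so Bi = y
  expect_equal(profile_scale(7.3, 0, 0.1, 0.3), 7.3)
  # noiseless data generated with Bi = 12 recovered exactly
  lam <- log(2) / 8; cc <- 0.25
  days <- c(0, 10, 40)
  y <- model_value(lam, cc, 12, days)
  expect_equal(profile_scale(y, days, lam, cc), 12, tolerance = 1e-12)
  # two noisy points: equals the argmin of the 1-D quadratic by dense grid
  set.seed(4)
  days2 <- c(0, 86)
  y2 <- model_value(lam, cc, 12, days2) + rnorm(2, 0, 0.8)
  f <- (1 - cc) * exp(-lam * days2) + cc
  grid <- seq(1e-6, 2 * max(y2) / min(f), length.out = 200001)
  sse_grid <- vapply(grid, function(b) sum((y2 - b * f)^2), numeric(1))
  expect_equal(profile_scale(y2, days2, lam, cc), grid[which.min(sse_grid)],
               tolerance = 1e-4)
})

test_that("noiseless cohorts are recovered to near machine precision", {
  lam <- log(2) / 8; cc <- 0.3; Bis <- c(5, 10, 15, 20, 25)
  tab <- make_noiseless_cohort(lam, cc, Bis)
  fit <- fit_decay(tab)
  expect_true(fit$converged)
  expect_lt(abs(fit$lam - lam) / lam, 1e-6)
  expect_lt(abs(fit$c - cc) / cc, 1e-6)
  expect_lt(max(abs(fit$scales - Bis) / Bis), 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("variable projection agrees with joint all-parameter optimization", {
  set.seed(21)
  tab <- make_noisy_cohort(sd = 0.4)
  fit <- fit_decay(tab)
  d <- tab[tab$endpoint == "SUVMAX", ]
  pidx <- as.integer(factor(d$patient_id))
  joint_sse <- function(p) {
    lam <- p[1]; cc <- p[2]; Bi <- p[3:7]
    sum((d$value - Bi[pidx] *
           ((1 - cc) * exp(-lam * d$day_adjusted) + cc))^2)
  }
  joint <- optim(unname(c(fit$lam, fit$c, fit$scales)) * 1.3, joint_sse,
                 method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(fit$sse, joint$value, tolerance = 1e-6)
  expect_equal(unname(fit$lam), joint$par[1], tolerance = 1e-4)
  expect_equal(unname(fit$c), joint$par[2], tolerance = 1e-4)
})

test_that("fit is scale- and time-unit-equivariant on noiseless data", {
  lam <- log(2) / 8; cc <- 0.3; Bis <- c(5, 10, 15, 20, 25)
  tab <- make_noiseless_cohort(lam, cc, Bis)
  fit <- fit_decay(tab)
  # multiplying one patient's values by k multiplies its scale by k only
  tab2 <- tab
  sel <- tab2$patient_id == "P03"
  tab2$value[sel] <- tab2$value[sel] * 4
  fit2 <- fit_decay(tab2)
  expect_equal(fit2$lam, fit$lam, tolerance = 1e-6)
  expect_equal(fit2$c, fit$c, tolerance = 1e-6)
  expect_equal(unname(fit2$scales["P03"] / fit$scales["P03"]), 4,
               tolerance = 1e-6)
  # rescaling days by s rescales lam by 1/s, leaves c and SSE invariant
  tab3 <- as_observation_table(data.frame(
    patient_id = tab$patient_id, day = tab$day * 2,
    endpoint = tab$endpoint, value = tab$value
  ))
  fit3 <- fit_decay(adjust_cohort(tab3))
  expect_equal(fit3$lam, fit$lam / 2, tolerance = 1e-6)
  expect_equal(fit3$c, fit$c, tolerance = 1e-6)
})

test_that("R-squared is 1 exactly iff residuals vanish", {
  tab <- make_noiseless_cohort()
  expect_equal(fit_decay(tab)$r_squared, 1, tolerance = 1e-12)
  set.seed(5)
  noisy <- make_noisy_cohort(sd = 0.5)
  expect_lt(fit_decay(noisy)$r_squared, 1)
})

test_that("estimator bias vanishes as the noise level shrinks", {
  lam <- log(2) / 8; cc <- 0.3
  errs <- vapply(c(0.5, 0.05, 0.005), function(s) {
    set.seed(99)
    fit <- fit_decay(make_noisy_cohort(lam = lam, c = cc, sd = s))
    abs(fit$lam - lam)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("under-determined designs are rejected", {
  tab <- as_observation_table(data.frame(
    patient_id = c("P1", "P1", "P2"), day = c(0, 30, 0),
    endpoint = "SUVMAX", value = c(10, 5, 8)
  ))
  expect_error(fit_decay(adjust_cohort(tab)), "nder-determined")
  expect_error(fit_decay(adjust_cohort(tab[1:2, ])), "2 patients")
})

test_that("predictions follow the model and the delta-method SE is sound", {
  set.seed(31)
  tab <- make_noisy_cohort(sd = 0.4)
  fit <- fit_decay(tab)
  # day 0 mean equals the patient's scale
  p0 <- predict(fit, "P02", 0)
  expect_equal(p0$mean, unname(fit$scales["P02"]))
  # large-day mean approaches the plateau Bi * c
  pinf <- predict(fit, "P02", 1e6)
  expect_equal(pinf$mean, unname(fit$scales["P02"] * fit$c),
               tolerance = 1e-10)
  expect_true(all(predict(fit, "P01", c(0, 10, 50))$se_mean >= 0))
  expect_error(predict(fit, "NOPE", 0), "unknown patient")
})

test_that("delta-method SE of the mean agrees with a parametric bootstrap", {
  set.seed(77)
  tab <- make_noisy_cohort(sd = 0.4)
  fit <- fit_decay(tab)
  target <- predict(fit, "P03", 60)
  d <- tab[tab$endpoint == "SUVMAX", ]
  mu <- predict(fit, d$patient_id, d$day_adjusted)$mean
  boot <- replicate(500, {
    d2 <- d
    d2$value <- pmax(mu + rnorm(nrow(d), 0, sqrt(fit$mse)), 0)
    f2 <- tryCatch(fit_decay(d2, start = c(fit$lam, fit$c)),
                   error = function(e) NULL)
    if (is.null(f2)) NA_real_ else predict(f2, "P03", 60)$mean
  })
  expect_equal(target$se_mean, sd(boot, na.rm = TRUE), tolerance = 0.15)
})

test_that("half-time is the log-2 transform of the rate with a Wald interval", {
  set.seed(13)
  tab <- make_noisy_cohort(sd = 0.2)
  fit <- fit_decay(tab)
  ht <- half_time(fit)
  expect_equal(ht$t_half, log(2) / fit$lam)
  # interval endpoints are the order-reversed image of the rate's interval
  expect_equal(ht$ci_low, log(2) / ht$lam_ci[["high"]])
  expect_equal(ht$ci_high, log(2) / ht$lam_ci[["low"]])
  expect_true(ht$ci_low <= ht$t_half && ht$t_half <= ht$ci_high)
  # closed-form spot values
  fit2 <- fit
  fit2$lam <- log(2)
  expect_equal(half_time(fit2)$t_half, 1)
  fit2$lam <- log(2) / 8.28
  expect_equal(half_time(fit2)$t_half, 8.28)
})
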