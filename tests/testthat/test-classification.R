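test_that("standardized residuals are centered, signed, and exactly scaled", {
  set.seed(8)
  tab <- make_noisy_cohort(sd = 0.3)
  fit <- fit_decay(tab)
  mu <- predict(fit, "P04", 60)$mean
  expect_equal(standardized_residual(fit, "P04", 60, mu), 0)
  # back out the denominator, then a value at mean + 2 denom scores exactly 2
  denom <- 1 / standardized_residual(fit, "P04", 60, mu + 1)
  expect_equal(standardized_residual(fit, "P04", 60, mu + 2 * denom), 2,
               tolerance = 1e-12)
  # below the curve -> negative
  expect_lt(standardized_residual(fit, "P04", 60, mu - 1), 0)
  # the individual-prediction denominator dominates the mean-only one
  z_pred <- standardized_residual(fit, "P04", 60, mu + 1)
  z_mean <- standardized_residual(fit, "P04", 60, mu + 1, se_type = "mean")
  expect_lt(z_pred, z_mean)
})

test_that("patient classification respects eligibility and strict thresholds", {
  set.seed(8)
  tab <- make_noisy_cohort(sd = 0.3)
  fit <- fit_decay(tab)
  calls <- classify_cohort(fit, tab)
  # design has days {0, 7, 30, 86}: day 30 is NOT eligible (strict), day 86 is
  expect_true(all(calls$n_eligible_obs == 1))
  expect_true(all(calls$day_of_z_max == 86))
  # flag is z_max > multiplier, strictly
  expect_equal(calls$flagged, calls$z_max > 2)
  with_boundary <- classify_cohort(fit, tab, sd_multiplier = max(calls$z_max))
  expect_false(any(with_boundary$flagged))
})

test_that("patients without enough data are excluded with a recorded reason", {
  set.seed(8)
  tab <- make_noisy_cohort(sd = 0.3)
  extra <- as_observation_table(rbind(
    as.data.frame(tab)[, c("patient_id", "day", "endpoint", "value")],
    data.frame(patient_id = c("P90", "P91", "P91"),
               day = c(40, 2, 20), endpoint = "SUVMAX",
               value = c(6, 10, 8))
  ))
  extra <- adjust_cohort(extra)
  fit <- fit_decay(extra)
  calls <- classify_cohort(fit, extra)
  excl <- attr(calls, "excluded")
  # P90 has a single time point; P91 has two but none after day 30
  expect_equal(excl$reason[excl$patient_id == "P90"], "TOO_FEW_OBS")
  expect_equal(excl$reason[excl$patient_id == "P91"], "NO_ELIGIBLE_DAY")
  expect_false(any(c("P90", "P91") %in% calls$patient_id))
})

test_that("a lone poor responder with 3-fold late values is flagged", {
  cfg <- sim_config(poor_responder_fraction = 0, seed = 9)
  sim <- simulate_cohort(cfg)
  tab <- adjust_cohort(sim$observations)
  d <- tab[tab$endpoint == "SUVMAX", ]
  # contaminate one patient: late values inflated 3-fold above the curve
  late <- d$patient_id == "P001" & d$day_adjusted > 30
  expect_gte(sum(late), 1)
  d$value[late] <- d$value[late] * 3
  fit <- fit_decay(d)
  calls <- classify_cohort(fit, d)
  expect_true(calls$flagged[calls$patient_id == "P001"])
})

test_that("most inlier observations stay within 2 SD of the fitted curve", {
  cfg <- sim_config(poor_responder_fraction = 0, seed = 14)
  sim <- simulate_cohort(cfg)
  tab <- adjust_cohort(sim$observations)
  fit <- fit_decay(tab, endpoint = "SUVMAX")
  oz <- attr(classify_cohort(fit, tab), "observation_z")
  expect_gte(mean(abs(oz$z) < 2), 0.95)
})

test_that("raising the SD multiplier never increases the flagged count", {
  cfg <- sim_config(seed = 2)
  sim <- simulate_cohort(cfg)
  tab <- adjust_cohort(sim$observations)
  fit <- fit_decay(tab, endpoint = "SUVMAX")
  counts <- vapply(c(0.5, 1, 1.5, 2, 3),
                   function(m) sum(classify_cohort(fit, tab,
                                                   sd_multiplier = m)$flagged),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("contingency tables count patients by event x flag", {
  calls <- data.frame(patient_id = c("P1", "P2"), flagged = c(TRUE, FALSE))
  outcomes <- data.frame(patient_id = c("P1", "P2"),
                         pfs_months = c(5, 30), event = c(TRUE, FALSE))
  tab <- contingency_table(calls, outcomes)
  expect_equal(unname(tab), matrix(c(1L, 0L, 0L, 1L), 2, 2))
  expect_equal(sum(tab), nrow(calls))
  expect_error(contingency_table(calls, outcomes[1, ]), "P2")
  expect_error(contingency_table(calls[0, ], outcomes), "no risk calls")
})

test_that("prevalence and LOOCV eligibility follow the stated rules", {
  mk <- function(k, n) data.frame(patient_id = as.character(seq_len(n)),
                                  flagged = seq_len(n) <= k)
  expect_equal(prevalence(mk(6, 35)), 6 / 35)
  expect_equal(prevalence(mk(0, 10)), 0)
  expect_equal(prevalence(mk(11, 35)), 11 / 35)
  # needs prevalence > 15% AND association p < 0.05
  expect_true(validation_eligibility(mk(6, 35), 0.0003))
  expect_false(validation_eligibility(mk(5, 35), 0.0014))  # 14% fails
  expect_false(validation_eligibility(mk(11, 35), 0.2630)) # not associated
})
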