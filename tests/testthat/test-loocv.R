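test_that("cross-validated residuals track full-data residuals on a
           homogeneous cohort", {
  cfg <- sim_config(poor_responder_fraction = 0, seed = 5)
  sim <- simulate_cohort(cfg)
  adj <- adjust_cohort(sim$observations)
  rec <- loocv_run(adj, sim$outcomes, "SUVMAX")
  expect_gt(loocv_vs_full(rec)$rho, 0.9)
  expect_lt(median(abs(rec$z_loocv - rec$z_full)), 0.25)
  expect_true(all(rec$day > 30))
  # deterministic: rerunning gives identical records
  rec2 <- loocv_run(adj, sim$outcomes, "SUVMAX")
  expect_equal(as.data.frame(rec), as.data.frame(rec2))
})

test_that("cross-validated residuals converge to full-data residuals as the
           cohort grows", {
  cfg <- sim_config(n_patients = 200, poor_responder_fraction = 0, seed = 6)
  sim <- simulate_cohort(cfg)
  adj <- adjust_cohort(sim$observations)
  rec <- loocv_run(adj, sim$outcomes, "SUVMAX")
  expect_lte(median(abs(rec$z_loocv - rec$z_full)), 0.05)
})

test_that("patients with one distinct time point are excluded from LOOCV", {
  tab <- as_observation_table(data.frame(
    patient_id = rep(c("A", "B", "C"), times = c(4, 4, 1)),
    day = c(0, 20, 50, 86, 0, 25, 55, 90, 40),
    endpoint = "SUVMAX",
    value = c(10, 5, 3.9, 3.3, 20, 9, 7.5, 6.6, 4)
  ))
  outcomes <- data.frame(patient_id = c("A", "B", "C"),
                         pfs_months = c(10, 20, 30),
                         event = c(TRUE, FALSE, FALSE))
  rec <- loocv_run(adjust_cohort(tab), outcomes, "SUVMAX")
  excl <- attr(rec, "excluded")
  expect_equal(excl$reason[excl$patient_id == "C"], "TOO_FEW_OBS")
  expect_false("C" %in% rec$patient_id)
})

test_that("no training-set leakage: the held-out patient's data cannot move
           their training fit", {
  cfg <- sim_config(n_patients = 12, poor_responder_fraction = 0, seed = 3)
  sim <- simulate_cohort(cfg)
  adj <- adjust_cohort(sim$observations)
  rec1 <- loocv_run(adj, sim$outcomes, "SUVMAX")
  # perturb one patient's observations wildly
  adj2 <- adj
  sel <- adj2$patient_id == "P005" & adj2$endpoint == "SUVMAX"
  adj2$value[sel] <- adj2$value[sel] * 7
  rec2 <- loocv_run(adj2, sim$outcomes, "SUVMAX")
  tr1 <- attr(rec1, "training")[["P005"]]
  tr2 <- attr(rec2, "training")[["P005"]]
  # training optima may differ by optimizer tolerance (the warm start moves
  # with the full fit) but not by anything resembling a 7-fold perturbation
  expect_equal(tr1$lam, tr2$lam, tolerance = 1e-3)
  expect_equal(tr1$c, tr2$c, tolerance = 1e-3)
  expect_equal(tr1$n_obs, tr2$n_obs)
})

test_that("the association delegate agrees with the Fisher module and flags
           degenerate margins", {
  cfg <- sim_config(poor_responder_fraction = 0, seed = 5)
  sim <- simulate_cohort(cfg)
  adj <- adjust_cohort(sim$observations)
  rec <- loocv_run(adj, sim$outcomes, "SUVMAX")
  assoc <- loocv_association(rec)
  expect_equal(assoc$p_two_sided,
               fisher_exact_2x2(assoc$table)$p_two_sided)
  # all flags false -> degenerate margin, p = 1
  rec0 <- rec
  rec0$flagged_loocv <- FALSE
  a0 <- loocv_association(rec0)
  expect_equal(a0$p_two_sided, 1)
  expect_true(a0$degenerate)
})

test_that("a lone poor responder tied to the only event yields a significant
           cross-validated association", {
  cfg <- sim_config(poor_responder_fraction = 0, seed = 19)
  sim <- simulate_cohort(cfg)
  adj <- adjust_cohort(sim$observations)
  d <- adj[adj$endpoint == "SUVMAX", ]
  # contaminate the patient with the largest baseline (their deviation is
  # well-measured relative to the cohort's residual scale): late values far
  # above the curve, and the cohort's only PFS event
  fit0 <- fit_decay(d)
  poor_id <- names(which.max(fit0$scales))
  sel <- d$patient_id == poor_id & d$day_adjusted > 30
  d$value[sel] <- d$value[sel] * 4
  outcomes <- sim$outcomes
  outcomes$event <- outcomes$patient_id == poor_id
  outcomes$pfs_months[outcomes$event] <- 5
  rec <- suppressWarnings(loocv_run(d, outcomes, "SUVMAX"))
  expect_true(all(rec$flagged_loocv[rec$patient_id == poor_id]))
  expect_lt(loocv_association(rec)$p_two_sided, 0.05)
})

test_that("rank agreement statistics behave at the extremes", {
  fake <- data.frame(patient_id = "X", day = 40, value = 1,
                     z_full = c(0.3, -1, 2, 0.7, 1.1),
                     z_loocv = c(0.3, -1, 2, 0.7, 1.1),
                     flagged_loocv = FALSE, event = FALSE)
  expect_equal(loocv_vs_full(fake)$rho, 1)
  set.seed(30)
  fake$z_loocv <- rnorm(5)
  fake2 <- fake[rep(1:5, 20), ]
  fake2$z_full <- rnorm(100)
  fake2$z_loocv <- rnorm(100)
  expect_lt(abs(loocv_vs_full(fake2)$rho), 0.3)
})
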