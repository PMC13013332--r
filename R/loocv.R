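# Leave-one-out cross-validation of the residual-based risk classifier.
#
# For each held-out patient the shared parameters (lam, c) are refit on the
# remaining patients; the held-out patient's scale is then profiled from their
# own observations under the training parameters. The SD used to standardize
# a held-out observation combines (i) the training residual variance, (ii)
# the delta-method variance of the mean through the training (lam, c)
# covariance — with the profiled scale's total dependence on (lam, c) taken by
# central differences — and (iii) the conditional variance of the profiled
# scale given (lam, c), mse_train / sum(f(t_j)^2) over the patient's own
# design points.

# Held-out prediction mean/SD for one patient's observations under a training
# fit. Returns data.frame(day, value, mean, sd_pred, se_mean).
holdout_predict <- function(train_fit, days, values) {
  lam <- train_fit$lam
  cc <- train_fit$c
  mse <- train_fit$mse
  mfun <- function(th, t) {
    Bi <- profile_scale(values, days, th[1], th[2])
    model_value(th[1], th[2], Bi, t)
  }
  th <- c(lam, cc)
  f <- decay_shape(lam, cc, days)
  Bi <- profile_scale(values, days, lam, cc)
  mean <- model_value(lam, cc, Bi, days)
  # total derivative of the profiled prediction wrt (lam, c), central diffs
  h <- pmax(abs(th), 1) * 1e-6
  g <- sapply(1:2, function(k) {
    tp <- th; tm <- th
    tp[k] <- tp[k] + h[k]; tm[k] <- tm[k] - h[k]
    (mfun(tp, days) - mfun(tm, days)) / (2 * h[k])
  })
  g <- matrix(g, nrow = length(days))
  cov_lc <- train_fit$cov[c("lam", "c"), c("lam", "c")]
  v_mean <- rowSums((g %*% cov_lc) * g)
  v_scale <- f^2 * mse / sum(f^2)
  se_mean <- sqrt(pmax(v_mean + v_scale, 0))
  data.frame(day = days, value = values, mean = mean,
             se_mean = se_mean, sd_pred = sqrt(mse + se_mean^2))
}

#' Leave-one-out cross-validation of the poor-response classifier
#'
#' For each patient with at least two distinct-day observations: refit the
#' shared parameters on all other patients (warm-started from the full-data
#' optimum), profile the held-out patient's scale from their own data, and
#' standardize their post-`min_day` observations against the training model.
#' The same observations are also standardized under the full-data fit for
#' comparison.
#'
#' @param table Adjusted observation table (single endpoint selected via
#'   `endpoint`).
#' @param outcomes Outcome data frame ([read_outcomes()]).
#' @param endpoint Endpoint to analyze.
#' @param sd_multiplier Flag threshold (default 2).
#' @param min_day Strict lower day bound for eligible observations (30).
#' @param se_type Standardizing denominator, as in [standardized_residual()].
#' @return A `loocv_records` data frame, one row per eligible observation:
#'   `patient_id`, `day`, `value`, `z_full`, `z_loocv`, `flagged_loocv`,
#'   `event`. Attributes: `excluded` (patients with reasons), `training`
#'   (per-patient training-fit summaries for leakage audits), `failures`.
#' @export
loocv_run <- function(table, outcomes, endpoint, sd_multiplier = 2,
                      min_day = 30, se_type = c("prediction", "mean")) {
  se_type <- match.arg(se_type)
  table <- ensure_adjusted(table)
  endpoint <- match_endpoint(endpoint)
  d <- table[table$endpoint == endpoint, , drop = FALSE]
  ids <- unique(d$patient_id)
  if (length(ids) < 3) stop("need at least 3 patients for LOOCV", call. = FALSE)

  full_fit <- fit_decay(d, endpoint = endpoint)
  n_days <- tapply(d$day_adjusted, d$patient_id,
                   function(x) length(unique(x)))
  too_few <- names(n_days)[n_days < 2]
  eligible_ids <- setdiff(ids, too_few)

  records <- list()
  training <- list()
  failures <- character()
  no_eligible <- character()
  for (p in eligible_ids) {
    mine <- d[d$patient_id == p, , drop = FALSE]
    elig <- mine[mine$day_adjusted > min_day, , drop = FALSE]
    if (nrow(elig) == 0) {
      no_eligible <- c(no_eligible, p)
      next
    }
    train_tab <- d[d$patient_id != p, , drop = FALSE]
    train_fit <- tryCatch(
      fit_decay(train_tab, endpoint = endpoint,
                start = c(full_fit$lam, full_fit$c)),
      error = function(e) NULL
    )
    if (is.null(train_fit) || !isTRUE(train_fit$converged)) {
      failures <- c(failures, p)
      next
    }
    hp <- holdout_predict(train_fit, as.numeric(mine$day_adjusted),
                          mine$value)
    denom <- if (se_type == "prediction") hp$sd_pred else hp$se_mean
    z_all <- (hp$value - hp$mean) / denom
    keep <- mine$day_adjusted > min_day
    z_full <- standardized_residual(full_fit, elig$patient_id,
                                    elig$day_adjusted, elig$value,
                                    se_type = se_type)
    records[[p]] <- data.frame(
      patient_id = p, day = elig$day_adjusted, value = elig$value,
      z_full = z_full, z_loocv = z_all[keep],
      flagged_loocv = z_all[keep] > sd_multiplier,
      stringsAsFactors = FALSE
    )
    training[[p]] <- list(lam = train_fit$lam, c = train_fit$c,
                          n_obs = train_fit$n_obs,
                          n_patients = train_fit$n_patients)
  }
  if (length(records) == 0) stop("every LOOCV training fit failed",
                                 call. = FALSE)
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out <- merge(out, outcomes[, c("patient_id", "event")],
               by = "patient_id", all.x = TRUE, sort = FALSE)
  out <- out[order(out$patient_id, out$day), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- data.frame(
    patient_id = c(too_few, no_eligible),
    reason = c(rep("TOO_FEW_OBS", length(too_few)),
               rep("NO_ELIGIBLE_DAY", length(no_eligible))),
    stringsAsFactors = FALSE
  )
  attr(out, "training") <- training
  attr(out, "failures") <- failures
  attr(out, "full_fit") <- full_fit
  class(out) <- c("loocv_records", "data.frame")
  out
}

#' Association between cross-validated flags and PFS events
#'
#' Cross-tabulates the LOOCV flag against the PFS event, at the observation
#' level (default; every eligible observation is one record) or aggregated to
#' patients by their maximum cross-validated residual, and applies the
#' two-sided Fisher exact test.
#'
#' @param records `loocv_records` from [loocv_run()].
#' @param unit `"observation"` or `"patient"`.
#' @param sd_multiplier Threshold used for the patient-level aggregation.
#' @return The [fisher_exact_2x2()] result with the `table` attached.
#' @export
loocv_association <- function(records, unit = c("observation", "patient"),
                              sd_multiplier = 2) {
  unit <- match.arg(unit)
  if (nrow(records) < 1) stop("no LOOCV records", call. = FALSE)
  if (any(is.na(records$event))) {
    stop("missing outcome for patient(s): ",
         paste(unique(records$patient_id[is.na(records$event)]),
               collapse = ", "), call. = FALSE)
  }
  if (unit == "observation") {
    flag <- records$flagged_loocv
    event <- records$event
  } else {
    zmax <- tapply(records$z_loocv, records$patient_id, max)
    ev <- tapply(records$event, records$patient_id, any)
    flag <- zmax > sd_multiplier
    event <- as.logical(ev)
  }
  tab <- matrix(c(sum(!event & !flag), sum(!event & flag),
                  sum(event & !flag), sum(event & flag)),
                2, 2, byrow = TRUE,
                dimnames = list(event = c("no", "yes"),
                                response = c("inlier", "outlier")))
  res <- fisher_exact_2x2(tab)
  res$table <- tab
  res
}

#' Rank agreement between cross-validated and full-data residuals
#'
#' @param records `loocv_records` from [loocv_run()].
#' @return [spearman_rho()] of (`z_loocv`, `z_full`).
#' @export
loocv_vs_full <- function(records) {
  if (nrow(records) < 4) stop("need at least 4 records", call. = FALSE)
  spearman_rho(records$z_loocv, records$z_full)
}
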