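# Standardized-residual classification of poor treatment response.
#
# An observation deviating from the model-predicted mean by more than
# `sd_multiplier` standard deviations of the predicted value, at a model day
# strictly after `min_day` (default 30), marks its patient as a poor
# responder. The standardizing denominator is, by default, the SD of an
# individual predicted value, sqrt(mse + se_mean^2) — residual variance plus
# the delta-method variance of the mean — so that under the fitted model the
# standardized residuals are approximately standard normal and the flag rate
# at threshold 2 is near the 2.3% upper tail. `se_type = "mean"` switches to
# the bare SE of the mean.

#' Standardized residuals of observations under a fitted decay model
#'
#' z = (measured - predicted mean) / SD of the predicted value; positive when
#' the observation sits above the curve.
#'
#' @param fit A converged `decay_fit`.
#' @param patient_id,day,value Vectors describing the observations (recycled
#'   to a common length).
#' @param se_type `"prediction"` (default): denominator
#'   `sqrt(mse + se_mean^2)`; `"mean"`: denominator `se_mean` only.
#' @return Numeric vector of standardized residuals.
#' @export
standardized_residual <- function(fit, patient_id, day, value,
                                  se_type = c("prediction", "mean")) {
  se_type <- match.arg(se_type)
  p <- predict_points(fit, patient_id, day)
  denom <- if (se_type == "prediction") p$sd_pred else p$se_mean
  if (any(denom <= 0)) stop("degenerate (zero) prediction SE", call. = FALSE)
  (rep_len(value, nrow(p)) - p$mean) / denom
}

#' Classify every patient's treatment response from one endpoint's fit
#'
#' Eligible observations are those with `day_adjusted > min_day`. A patient is
#' flagged when the maximum standardized residual over eligible observations
#' strictly exceeds `sd_multiplier` ("any deviation" semantics). Patients with
#' fewer than two distinct-day observations (TOO_FEW_OBS) or without any
#' eligible observation (NO_ELIGIBLE_DAY) are excluded; exclusions are kept in
#' the `excluded` attribute with their reason.
#'
#' @param fit A converged `decay_fit`.
#' @param table Adjusted observation table containing the fit's endpoint.
#' @param sd_multiplier Flag threshold in SD units (default 2).
#' @param min_day Observations must lie strictly after this day (default 30).
#' @param se_type Passed to [standardized_residual()].
#' @return A `risk_calls` data frame with columns `patient_id`, `endpoint`,
#'   `z_max`, `day_of_z_max`, `flagged`, `n_eligible_obs`; attributes
#'   `excluded` (data frame of exclusions) and `observation_z` (per eligible
#'   observation residuals).
#' @export
classify_cohort <- function(fit, table, sd_multiplier = 2, min_day = 30,
                            se_type = c("prediction", "mean")) {
  stopifnot(inherits(fit, "decay_fit"), isTRUE(fit$converged))
  se_type <- match.arg(se_type)
  table <- ensure_adjusted(table)
  d <- table[table$endpoint == fit$endpoint, , drop = FALSE]
  d <- d[d$patient_id %in% names(fit$scales), , drop = FALSE]
  if (nrow(d) == 0) stop("no observations for endpoint ", fit$endpoint,
                         call. = FALSE)

  n_days <- tapply(d$day_adjusted, d$patient_id,
                   function(x) length(unique(x)))
  ids <- names(n_days)
  too_few <- ids[n_days < 2]
  eligible_tab <- d[d$day_adjusted > min_day &
                      !(d$patient_id %in% too_few), , drop = FALSE]
  assessable <- setdiff(ids, too_few)
  no_day <- setdiff(assessable, unique(eligible_tab$patient_id))

  excluded <- data.frame(
    patient_id = c(too_few, no_day),
    reason = c(rep("TOO_FEW_OBS", length(too_few)),
               rep("NO_ELIGIBLE_DAY", length(no_day))),
    stringsAsFactors = FALSE
  )

  if (nrow(eligible_tab) > 0) {
    z <- standardized_residual(fit, eligible_tab$patient_id,
                               eligible_tab$day_adjusted, eligible_tab$value,
                               se_type = se_type)
    obs_z <- data.frame(patient_id = eligible_tab$patient_id,
                        day = eligible_tab$day_adjusted,
                        value = eligible_tab$value, z = z,
                        flagged = z > sd_multiplier,
                        stringsAsFactors = FALSE)
    split_z <- split(obs_z, obs_z$patient_id)
    calls <- do.call(rbind, lapply(split_z, function(g) {
      k <- which.max(g$z)
      data.frame(patient_id = g$patient_id[1], endpoint = fit$endpoint,
                 z_max = g$z[k], day_of_z_max = g$day[k],
                 flagged = g$z[k] > sd_multiplier,
                 n_eligible_obs = nrow(g), stringsAsFactors = FALSE)
    }))
    rownames(calls) <- NULL
  } else {
    obs_z <- data.frame(patient_id = character(), day = numeric(),
                        value = numeric(), z = numeric(), flagged = logical())
    calls <- data.frame(patient_id = character(), endpoint = character(),
                        z_max = numeric(), day_of_z_max = numeric(),
                        flagged = logical(), n_eligible_obs = integer())
  }
  attr(calls, "excluded") <- excluded
  attr(calls, "observation_z") <- obs_z
  attr(calls, "sd_multiplier") <- sd_multiplier
  attr(calls, "min_day") <- min_day
  class(calls) <- c("risk_calls", "data.frame")
  calls
}

#' Cross-tabulate risk flags against PFS events
#'
#' Builds the 2x2 table with rows = PFS event \{no, yes\} and columns =
#' \{inlier, outlier\}. Every called patient must have an outcome; missing
#' outcomes raise a reconciliation error listing the ids.
#'
#' @param calls A `risk_calls` data frame (or any data frame with
#'   `patient_id` and `flagged`).
#' @param outcomes Outcome data frame from [read_outcomes()].
#' @return A 2x2 integer matrix with dimnames
#'   `list(event = c("no","yes"), response = c("inlier","outlier"))`.
#' @export
contingency_table <- function(calls, outcomes) {
  if (nrow(calls) == 0) stop("no risk calls to tabulate", call. = FALSE)
  missing_ids <- setdiff(calls$patient_id, outcomes$patient_id)
  if (length(missing_ids) > 0) {
    stop("no outcome for called patient(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  m <- merge(as.data.frame(calls)[, c("patient_id", "flagged")],
             outcomes[, c("patient_id", "event")], by = "patient_id")
  tab <- matrix(0L, 2, 2,
                dimnames = list(event = c("no", "yes"),
                                response = c("inlier", "outlier")))
  tab["no", "inlier"] <- sum(!m$event & !m$flagged)
  tab["no", "outlier"] <- sum(!m$event & m$flagged)
  tab["yes", "inlier"] <- sum(m$event & !m$flagged)
  tab["yes", "outlier"] <- sum(m$event & m$flagged)
  tab
}

#' Fraction of classified patients carrying the risk flag
#'
#' @param calls A `risk_calls` data frame.
#' @return Flagged count divided by total calls, in \[0, 1\].
#' @export
prevalence <- function(calls) {
  if (nrow(calls) < 1) stop("no risk calls", call. = FALSE)
  mean(calls$flagged)
}

#' Eligibility of an endpoint for cross-validated confirmation
#'
#' An endpoint qualifies for LOOCV confirmation when it shows sufficient
#' inter-individual variability — more than `prevalence_threshold` of
#' patients flagged — *and* a significant association with prognosis
#' (`association_p < alpha`).
#'
#' @param calls A `risk_calls` data frame (or a single prevalence in \[0,1\]).
#' @param association_p Two-sided Fisher p for the flag-outcome association.
#' @param prevalence_threshold Strict lower bound on prevalence (default 0.15).
#' @param alpha Significance level (default 0.05).
#' @return TRUE iff both conditions hold.
#' @export
validation_eligibility <- function(calls, association_p,
                                   prevalence_threshold = 0.15, alpha = 0.05) {
  prev <- if (is.numeric(calls) && length(calls) == 1) calls else prevalence(calls)
  isTRUE(prev > prevalence_threshold && association_p < alpha)
}
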