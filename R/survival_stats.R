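# Progression-free-survival layer, built on the survival package:
# Kaplan-Meier product-limit curves with Greenwood/log-log pointwise bands and
# Brookmeyer-Crowley median intervals, the log-rank test, reverse-KM median
# follow-up, and univariate Cox models with Efron tie handling.

#' Kaplan-Meier curve with pointwise bands and median
#'
#' Product-limit estimator with Greenwood variance and log-log pointwise
#' confidence bands. The median is the earliest time at which the survival
#' estimate drops to 0.5 or below; its interval comes from Brookmeyer-Crowley
#' inversion of the log-log band.
#'
#' @param times Positive event/censoring times (months).
#' @param events Logical (or 0/1) event indicators.
#' @param level Confidence level (default 0.95).
#' @return A `km_curve` list: `time`, `at_risk`, `survival`, `ci_low`,
#'   `ci_high` (at each observed time), `median`, `median_ci`, `n`.
#' @export
kaplan_meier <- function(times, events, level = 0.95) {
  stopifnot(length(times) == length(events))
  if (length(times) == 0) stop("empty input", call. = FALSE)
  if (any(times <= 0)) stop("times must be positive", call. = FALSE)
  events <- as.logical(events)
  sf <- survival::survfit(survival::Surv(times, events) ~ 1,
                          conf.type = "log-log", conf.int = level)
  st <- summary(sf)$table
  med <- unname(st["median"])
  out <- list(
    time = sf$time,
    at_risk = sf$n.risk,
    survival = sf$surv,
    ci_low = ifelse(is.na(sf$lower), 0, sf$lower),
    ci_high = ifelse(is.na(sf$upper), 1, sf$upper),
    median = if (is.na(med)) NA_real_ else med,
    median_ci = c(low = unname(st[paste0("0.95", "LCL")]),
                  high = unname(st[paste0("0.95", "UCL")])),
    n = length(times),
    level = level
  )
  class(out) <- "km_curve"
  out
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d\n", x$n))
  if (is.na(x$median)) {
    cat("  median: not reached\n")
  } else {
    cat(sprintf("  median: %.1f months (%.0f%% CI %s-%s)\n", x$median,
                100 * x$level,
                ifelse(is.na(x$median_ci[1]), "NA",
                       sprintf("%.1f", x$median_ci[1])),
                ifelse(is.na(x$median_ci[2]), "NA",
                       sprintf("%.1f", x$median_ci[2]))))
  }
  invisible(x)
}

#' Two-group log-rank test
#'
#' One-degree-of-freedom log-rank test with the hypergeometric variance at
#' each distinct event time.
#'
#' @param times Positive times.
#' @param events Event indicators.
#' @param group Two-level grouping vector.
#' @return List with `chisq`, `p`, and the per-group observed/expected counts.
#' @export
logrank_test <- function(times, events, group) {
  stopifnot(length(times) == length(events), length(times) == length(group))
  g <- factor(group)
  if (nlevels(g) != 2) stop("log-rank needs exactly two groups", call. = FALSE)
  events <- as.logical(events)
  if (sum(events) == 0) {
    return(list(chisq = 0, p = 1, observed = tapply(events, g, sum),
                expected = tapply(events, g, sum)))
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  list(chisq = unname(sd$chisq),
       p = pchisq(unname(sd$chisq), df = 1, lower.tail = FALSE),
       observed = sd$obs, expected = sd$exp)
}

#' Median follow-up by the reverse Kaplan-Meier method
#'
#' Runs the product-limit estimator with the censoring indicator treated as
#' the event (patients who progress are censored for follow-up).
#'
#' @param times Positive times.
#' @param events Event indicators (TRUE = progression).
#' @param level Confidence level.
#' @return A `km_curve` for the follow-up distribution; its `median` is the
#'   median follow-up.
#' @export
reverse_km_followup <- function(times, events, level = 0.95) {
  kaplan_meier(times, !as.logical(events), level = level)
}

#' Univariate Cox proportional-hazards model
#'
#' Partial-likelihood fit with Efron tie handling; reports the hazard ratio
#' per one-unit covariate increase with a Wald interval. Monotone likelihood
#' (perfect separation) is detected from the fitter's warning and flagged; the
#' interval is then unbounded.
#'
#' @param covariate Numeric covariate, one value per patient.
#' @param times Positive times.
#' @param events Event indicators.
#' @param level Confidence level (default 0.95).
#' @return A `cox_result` list: `hazard_ratio`, `ci_low`, `ci_high`, `beta`,
#'   `se`, `p`, `n_events`, `separation`.
#' @export
cox_univariate <- function(covariate, times, events, level = 0.95) {
  stopifnot(length(covariate) == length(times),
            length(times) == length(events))
  events <- as.logical(events)
  if (sum(events) < 2) stop("need at least 2 events", call. = FALSE)
  if (any(!is.finite(covariate))) stop("covariate must be finite", call. = FALSE)
  separation <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ covariate,
                    ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- unname(fit$coefficients[1])
  se <- sqrt(fit$var[1, 1])
  z <- qnorm(1 - (1 - level) / 2)
  out <- list(
    hazard_ratio = exp(beta),
    ci_low = if (separation) 0 else exp(beta - z * se),
    ci_high = if (separation) Inf else exp(beta + z * se),
    beta = beta, se = se,
    p = 2 * pnorm(-abs(beta / se)),
    n_events = sum(events),
    separation = separation
  )
  class(out) <- "cox_result"
  out
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox PH: HR %.3f (95%% CI %.3f-%.3f), p = %.4f%s\n",
              x$hazard_ratio, x$ci_low, x$ci_high, x$p,
              if (x$separation) " [monotone likelihood]" else ""))
  invisible(x)
}
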