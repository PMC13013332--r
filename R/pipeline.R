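# Pipeline orchestration: adjust -> fit -> classify -> associate -> survival
# -> (if eligible) LOOCV, per endpoint, with a consolidated report.

#' Pipeline configuration
#'
#' @param endpoints Endpoints to analyze.
#' @param cap_day Backdating cap (default 21).
#' @param sd_multiplier Risk-flag threshold in SD units (default 2).
#' @param min_day Strict day cut for eligible observations (default 30).
#' @param prevalence_threshold LOOCV eligibility prevalence bound (0.15).
#' @param alpha LOOCV eligibility significance level (0.05).
#' @param se_type Standardizing denominator for residuals.
#' @return A `run_config` list (echoed verbatim into the report).
#' @export
run_config <- function(endpoints = pet_endpoints(), cap_day = 21L,
                       sd_multiplier = 2, min_day = 30,
                       prevalence_threshold = 0.15, alpha = 0.05,
                       se_type = "prediction") {
  cfg <- list(endpoints = match_endpoint(endpoints),
              cap_day = as.integer(cap_day),
              sd_multiplier = sd_multiplier, min_day = min_day,
              prevalence_threshold = prevalence_threshold, alpha = alpha,
              se_type = se_type)
  class(cfg) <- "run_config"
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full response-kinetics pipeline
#'
#' Executes, per endpoint: backdating, the shared decay fit, half-time,
#' standardized-residual risk classification, the risk-by-outcome
#' cross-tabulation with Fisher's exact test and binary AUC, prevalence and
#' LOOCV eligibility, Kaplan-Meier PFS by risk group with the log-rank test,
#' reverse-KM median follow-up, a univariate Cox model of the
#' time-zero-extrapolated baseline value (log scale for MTV/TLG, raw for
#' SUVmax), and — when the endpoint is eligible — the LOOCV confirmation.
#'
#' @param observations A `pet_observations` table (raw days).
#' @param outcomes Outcome data frame ([read_outcomes()]).
#' @param config A [run_config()].
#' @return A `pet_report` list with one entry per endpoint plus the echoed
#'   config and cohort-level follow-up summary.
#' @export
run_pipeline <- function(observations, outcomes, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (!inherits(observations, "pet_observations")) {
    observations <- as_observation_table(observations)
  }
  stopifnot(is.data.frame(outcomes))
  adj <- stage("adjust", adjust_cohort(observations, cap_day = config$cap_day))
  followup <- stage("survival",
                    reverse_km_followup(outcomes$pfs_months, outcomes$event))
  km_all <- stage("survival", kaplan_meier(outcomes$pfs_months,
                                           outcomes$event))
  out <- list(config = config, followup = followup, km_all = km_all,
              endpoints = list())
  for (ep in config$endpoints) {
    if (!any(adj$endpoint == ep)) next
    fit <- stage(paste0("fit[", ep, "]"), fit_decay(adj, endpoint = ep))
    ht <- stage("half_time", suppressWarnings(half_time(fit)))
    calls <- stage("classify",
                   classify_cohort(fit, adj,
                                   sd_multiplier = config$sd_multiplier,
                                   min_day = config$min_day,
                                   se_type = config$se_type))
    tab <- stage("associate", contingency_table(calls, outcomes))
    fisher <- fisher_exact_2x2(tab)
    auc <- tryCatch(binary_auc(tab), error = function(e) NULL)
    prev <- prevalence(calls)
    eligible <- validation_eligibility(prev, fisher$p_two_sided,
                                       config$prevalence_threshold,
                                       config$alpha)
    m <- merge(as.data.frame(calls)[, c("patient_id", "flagged")],
               outcomes, by = "patient_id")
    lr <- if (length(unique(m$flagged)) == 2) {
      stage("survival", logrank_test(m$pfs_months, m$event, m$flagged))
    } else NULL
    km_by_flag <- lapply(split(m, m$flagged), function(g) {
      kaplan_meier(g$pfs_months, g$event)
    })
    # baseline (time-zero-extrapolated) covariate = the fitted scale
    cov_val <- fit$scales[m$patient_id]
    if (ep %in% c("MTV", "TLG")) cov_val <- log(cov_val)
    cox <- tryCatch(cox_univariate(cov_val, m$pfs_months, m$event),
                    error = function(e) NULL)
    loocv <- NULL
    if (eligible) {
      loocv <- stage(paste0("loocv[", ep, "]"), {
        rec <- loocv_run(adj, outcomes, endpoint = ep,
                         sd_multiplier = config$sd_multiplier,
                         min_day = config$min_day, se_type = config$se_type)
        list(records = rec,
             association = loocv_association(rec),
             rho = loocv_vs_full(rec))
      })
    }
    out$endpoints[[ep]] <- list(
      endpoint = ep, fit = fit, half_time = ht, calls = calls,
      contingency = tab, fisher = fisher, auc = auc, prevalence = prev,
      eligible = eligible, logrank = lr, km_by_flag = km_by_flag,
      cox_baseline = cox, loocv = loocv
    )
  }
  class(out) <- "pet_report"
  out
}

#' Render a pipeline report as text
#'
#' One block per endpoint, mirroring the usual reporting order: fitted
#' parameters (half-time to 2 dp), the risk-by-outcome cross-tab with
#' Fisher's p (4 dp) and AUC (2 dp), prevalence and eligibility, the log-rank
#' comparison, and the LOOCV block when run.
#'
#' @param report A `pet_report` from [run_pipeline()].
#' @return Character vector of report lines (invisibly printable via `cat`).
#' @export
render_report <- function(report) {
  stopifnot(inherits(report, "pet_report"))
  ln <- character()
  add <- function(...) ln <<- c(ln, sprintf(...))
  add("== Tumor response kinetics report ==")
  if (!is.na(report$followup$median)) {
    add("Median follow-up (reverse KM): %.1f months", report$followup$median)
  }
  if (!is.na(report$km_all$median)) {
    add("Median PFS: %.1f months (95%% CI %s-%s)", report$km_all$median,
        ifelse(is.na(report$km_all$median_ci[1]), "NA",
               sprintf("%.1f", report$km_all$median_ci[1])),
        ifelse(is.na(report$km_all$median_ci[2]), "NA",
               sprintf("%.1f", report$km_all$median_ci[2])))
  }
  for (res in report$endpoints) {
    add("")
    add("-- %s --", res$endpoint)
    add("half-time of decrease: %.2f days (95%% CI %.2f-%s)",
        res$half_time$t_half, res$half_time$ci_low,
        if (is.finite(res$half_time$ci_high))
          sprintf("%.2f", res$half_time$ci_high) else "Inf")
    add("asymptotic offset: %.3f; R-squared: %.4f", res$fit$c,
        res$fit$r_squared)
    tab <- res$contingency
    add("risk x PFS-event cross-tab (rows event no/yes, cols inlier/outlier):")
    add("  no : %d %d", tab["no", "inlier"], tab["no", "outlier"])
    add("  yes: %d %d", tab["yes", "inlier"], tab["yes", "outlier"])
    add("Fisher exact p = %.4f", res$fisher$p_two_sided)
    if (!is.null(res$auc)) {
      add("AUC = %.2f (95%% CI %.2f-%.2f)", res$auc$auc, res$auc$ci_low,
          res$auc$ci_high)
    }
    add("prevalence of risk flag: %.1f%%; LOOCV-eligible: %s",
        100 * res$prevalence, ifelse(res$eligible, "yes", "no"))
    if (!is.null(res$logrank)) {
      add("log-rank (flagged vs not): chisq = %.2f, p = %.4f",
          res$logrank$chisq, res$logrank$p)
    }
    if (!is.null(res$cox_baseline)) {
      add("Cox HR per unit baseline covariate: %.3f (95%% CI %.3f-%.3f)",
          res$cox_baseline$hazard_ratio, res$cox_baseline$ci_low,
          res$cox_baseline$ci_high)
    }
    if (!is.null(res$loocv)) {
      add("LOOCV: Fisher p = %.4f; Spearman rho (loocv vs full) = %.2f (95%% CI %.2f-%.2f)",
          res$loocv$association$p_two_sided, res$loocv$rho$rho,
          res$loocv$rho$ci_low, res$loocv$rho$ci_high)
    } else {
      add("LOOCV: not eligible")
    }
  }
  ln
}

#' @export
print.pet_report <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}
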