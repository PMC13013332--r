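# Cohort I/O: observation tables, outcome tables, and fit artifacts.
#
# Observations are kept in long format (one row per patient/endpoint/scan)
# because scan counts vary between patients. Days are integers relative to the
# start of induction chemotherapy (day 0); no calendar dates are parsed.

#' Build a validated observation table
#'
#' Validates and canonicalizes a long-format table of serial PET measurements.
#' Required columns: `patient_id`, `day` (integer days relative to start of
#' induction chemotherapy, may be negative), `endpoint` (one of
#' [pet_endpoints()], matched case-insensitively), `value` (nonnegative,
#' finite). Rows are sorted canonically by (patient, endpoint, day), so any
#' permutation of the same records yields an identical table.
#'
#' @param df A data frame with the required columns.
#' @param provenance Free-text label recording where the data came from.
#' @return A `pet_observations` data frame (canonically sorted) with a
#'   `provenance` attribute.
#' @export
as_observation_table <- function(df, provenance = "in-memory") {
  required <- c("patient_id", "day", "endpoint", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("observation table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    patient_id = as.character(df$patient_id),
    day = df$day,
    endpoint = match_endpoint(df$endpoint),
    value = df$value,
    stringsAsFactors = FALSE
  )
  if (!is.numeric(out$day) || any(!is.finite(out$day))) {
    stop("column 'day' must be finite numeric", call. = FALSE)
  }
  if (any(out$day != round(out$day))) {
    stop("column 'day' must contain integer day numbers", call. = FALSE)
  }
  out$day <- as.integer(out$day)
  if (!is.numeric(out$value) || any(!is.finite(out$value))) {
    stop("column 'value' must be finite numeric", call. = FALSE)
  }
  if (any(out$value < 0)) {
    stop("column 'value' must be nonnegative", call. = FALSE)
  }
  key <- paste(out$patient_id, out$endpoint, out$day, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate (patient, endpoint, day) record(s): ",
         paste(gsub("\r", "/", dup), collapse = "; "), call. = FALSE)
  }
  ord <- order(out$patient_id, out$endpoint, out$day)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- provenance
  class(out) <- c("pet_observations", "data.frame")
  out
}

#' Read serial PET observations from a delimited text file
#'
#' The file must have a header naming at least `patient_id`, `day`,
#' `endpoint`, `value`. Endpoint strings are matched case-insensitively
#' against [pet_endpoints()]. Malformed numeric fields raise a parse error
#' citing the offending data row.
#'
#' @param path Path to the file.
#' @param sep Field delimiter (default comma).
#' @return A validated `pet_observations` table (see [as_observation_table()]).
#' @export
read_observations <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, sep = sep, colClasses = "character",
                  stringsAsFactors = FALSE, check.names = TRUE)
  required <- c("patient_id", "day", "endpoint", "value")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  day <- suppressWarnings(as.numeric(raw$day))
  if (any(is.na(day))) {
    stop("non-numeric 'day' at data row(s): ",
         paste(which(is.na(day)), collapse = ", "), call. = FALSE)
  }
  value <- suppressWarnings(as.numeric(raw$value))
  if (any(is.na(value))) {
    stop("non-numeric 'value' at data row(s): ",
         paste(which(is.na(value)), collapse = ", "), call. = FALSE)
  }
  as_observation_table(
    data.frame(patient_id = raw$patient_id, day = day,
               endpoint = raw$endpoint, value = value,
               stringsAsFactors = FALSE),
    provenance = path
  )
}

#' Derive TLG records as the product SUVmax x MTV
#'
#' For every (patient, day) at which both a SUVMAX and an MTV record exist and
#' no explicit TLG record is present, appends a TLG record with value
#' SUVmax x MTV. Derivation is opt-in; the result's provenance notes it.
#'
#' @param table A `pet_observations` table.
#' @return The table with derived TLG rows appended (canonically sorted).
#' @export
derive_tlg <- function(table) {
  stopifnot(inherits(table, "pet_observations"))
  suv <- table[table$endpoint == "SUVMAX", ]
  mtv <- table[table$endpoint == "MTV", ]
  tlg <- table[table$endpoint == "TLG", ]
  m <- merge(suv[, c("patient_id", "day", "value")],
             mtv[, c("patient_id", "day", "value")],
             by = c("patient_id", "day"), suffixes = c("_suv", "_mtv"))
  have <- paste(tlg$patient_id, tlg$day)
  m <- m[!(paste(m$patient_id, m$day) %in% have), , drop = FALSE]
  if (nrow(m) == 0) return(table)
  new <- data.frame(patient_id = m$patient_id, day = m$day,
                    endpoint = "TLG", value = m$value_suv * m$value_mtv,
                    stringsAsFactors = FALSE)
  as_observation_table(
    rbind(as.data.frame(table)[, c("patient_id", "day", "endpoint", "value")],
          new),
    provenance = paste0(attr(table, "provenance"), " + derived TLG")
  )
}

#' Read per-patient outcomes (PFS) from a CSV file
#'
#' Expected columns: `patient_id`, `pfs_months` (positive), `event` (0/1 or
#' true/false; true means a progression/relapse was observed).
#'
#' @param path Path to the file.
#' @return A data frame with columns `patient_id`, `pfs_months`, `event`.
#' @export
read_outcomes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, colClasses = "character", stringsAsFactors = FALSE)
  required <- c("patient_id", "pfs_months", "event")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  pfs <- suppressWarnings(as.numeric(raw$pfs_months))
  if (any(is.na(pfs))) {
    stop("non-numeric 'pfs_months' at data row(s): ",
         paste(which(is.na(pfs)), collapse = ", "), call. = FALSE)
  }
  if (any(pfs <= 0)) {
    stop("'pfs_months' must be > 0; offending data row(s): ",
         paste(which(pfs <= 0), collapse = ", "), call. = FALSE)
  }
  ev_raw <- tolower(trimws(raw$event))
  ev <- rep(NA, length(ev_raw))
  ev[ev_raw %in% c("1", "true", "t", "yes")] <- TRUE
  ev[ev_raw %in% c("0", "false", "f", "no")] <- FALSE
  if (any(is.na(ev))) {
    stop("unknown 'event' encoding at data row(s): ",
         paste(which(is.na(ev)), collapse = ", "),
         " (expected 0/1 or true/false)", call. = FALSE)
  }
  if (anyDuplicated(raw$patient_id)) {
    stop("duplicate patient_id in outcomes: ",
         paste(unique(raw$patient_id[duplicated(raw$patient_id)]),
               collapse = ", "), call. = FALSE)
  }
  data.frame(patient_id = as.character(raw$patient_id), pfs_months = pfs,
             event = as.logical(ev), stringsAsFactors = FALSE)
}

#' Serialize a decay-model fit to a JSON artifact
#'
#' Writes all parameters (decay rate, offset, per-patient scales), the full
#' parameter covariance matrix, residual variance, degrees of freedom, R
#' squared, and the fit configuration at full numeric precision, so that
#' [read_fit()] round-trips the object losslessly.
#'
#' @param fit A `decay_fit` object from [fit_decay()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "decay_fit"))
  if (!isTRUE(fit$converged)) stop("refusing to serialize a non-converged fit",
                                   call. = FALSE)
  payload <- list(
    artifact = "petkinetics_decay_fit",
    endpoint = fit$endpoint,
    lam = fit$lam,
    c = fit$c,
    scales = as.list(fit$scales),
    param_names = fit$param_names,
    cov = fit$cov,
    mse = fit$mse,
    sse = fit$sse,
    dof = fit$dof,
    r_squared = fit$r_squared,
    n_obs = fit$n_obs,
    n_patients = fit$n_patients,
    converged = fit$converged,
    n_iter = fit$n_iter,
    singular_cov = fit$singular_cov,
    config = fit$config
  )
  ok <- tryCatch({
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("could not write fit artifact to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read a decay-model fit artifact written by [write_fit()]
#'
#' @param path Path to the JSON artifact.
#' @return A `decay_fit` object.
#' @export
read_fit <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$artifact, "petkinetics_decay_fit")) {
    stop(path, " is not a petkinetics fit artifact", call. = FALSE)
  }
  cov <- as.matrix(p$cov)
  dimnames(cov) <- list(p$param_names, p$param_names)
  fit <- list(
    endpoint = p$endpoint,
    lam = p$lam,
    c = p$c,
    scales = unlist(p$scales),
    param_names = p$param_names,
    cov = cov,
    mse = p$mse,
    sse = p$sse,
    dof = p$dof,
    r_squared = p$r_squared,
    n_obs = p$n_obs,
    n_patients = p$n_patients,
    converged = p$converged,
    n_iter = p$n_iter,
    singular_cov = p$singular_cov,
    config = p$config
  )
  class(fit) <- "decay_fit"
  fit
}
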