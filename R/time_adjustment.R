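# Backdating of pre-treatment scans onto the model time axis.
#
# Time is measured from the start of induction chemotherapy (day 0). Staging
# scans usually precede day 0; they are mapped onto the nonnegative model time
# axis with endpoint-specific rules:
#   * SUVMAX: assumed constant over the short pre-treatment window, so a scan
#     at a negative day is placed at day 0 (CONSTANT_TO_ZERO).
#   * MTV/TLG: pre-treatment growth is assumed to match post-treatment
#     shrinkage, so a scan at day -x is placed at model day +x (MIRROR),
#     capped at `cap_day` (default 21) for earlier scans (MIRROR_CAPPED).
# Scans at nonnegative days are left unchanged (rule NONE).

adjustment_rules <- c("NONE", "CONSTANT_TO_ZERO", "MIRROR", "MIRROR_CAPPED")

#' Backdate a raw scan day onto the model time axis
#'
#' @param day_raw Integer vector of raw scan days (may be negative).
#' @param endpoint Endpoint code(s), recycled against `day_raw`.
#' @param cap_day Positive integer; most-negative mirrored day (default 21).
#' @return Data frame with columns `day_adjusted` (nonnegative integer) and
#'   `adjustment_rule` (one of NONE, CONSTANT_TO_ZERO, MIRROR, MIRROR_CAPPED).
#' @export
#' @examples
#' adjust_time(c(-7, -10, -30, 5), c("SUVMAX", "MTV", "MTV", "TLG"))
adjust_time <- function(day_raw, endpoint, cap_day = 21L) {
  stopifnot(length(cap_day) == 1, cap_day > 0)
  endpoint <- match_endpoint(endpoint)
  n <- max(length(day_raw), length(endpoint))
  day_raw <- rep_len(as.integer(day_raw), n)
  endpoint <- rep_len(endpoint, n)
  day_adj <- day_raw
  rule <- rep("NONE", n)
  neg <- day_raw < 0
  suv <- neg & endpoint == "SUVMAX"
  day_adj[suv] <- 0L
  rule[suv] <- "CONSTANT_TO_ZERO"
  vol <- neg & endpoint != "SUVMAX"
  mirrored <- pmin(abs(day_raw), as.integer(cap_day))
  capped <- vol & abs(day_raw) > cap_day
  day_adj[vol] <- mirrored[vol]
  rule[vol] <- "MIRROR"
  rule[capped] <- "MIRROR_CAPPED"
  data.frame(day_adjusted = as.integer(day_adj),
             adjustment_rule = rule, stringsAsFactors = FALSE)
}

#' Backdate every observation in a cohort table
#'
#' Applies [adjust_time()] element-wise and appends `day_adjusted` and
#' `adjustment_rule` columns. The operation is idempotent: re-adjusting an
#' already-adjusted table recomputes the same columns from the raw days.
#'
#' @param table A `pet_observations` table.
#' @param cap_day Positive integer cap (default 21).
#' @param quiet Suppress the per-rule count summary message.
#' @return The table with adjustment columns added.
#' @export
adjust_cohort <- function(table, cap_day = 21L, quiet = TRUE) {
  stopifnot(inherits(table, "pet_observations"))
  adj <- adjust_time(table$day, table$endpoint, cap_day = cap_day)
  table$day_adjusted <- adj$day_adjusted
  table$adjustment_rule <- adj$adjustment_rule
  attr(table, "cap_day") <- as.integer(cap_day)
  if (!quiet) {
    counts <- table(factor(adj$adjustment_rule, levels = adjustment_rules))
    message("backdating: ",
            paste(names(counts), counts, sep = "=", collapse = ", "))
  }
  table
}

# Internal: require an adjusted table (or adjust on the fly when all days are
# already nonnegative).
ensure_adjusted <- function(table, cap_day = 21L) {
  if (!("day_adjusted" %in% names(table))) {
    table <- adjust_cohort(table, cap_day = cap_day)
  }
  table
}
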