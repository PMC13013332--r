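# Exact and rank-based association statistics: two-sided Fisher exact test,
# binary-predictor AUC with a DeLong interval, Spearman rank correlation with
# a Fisher-z interval.

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditions on the margins and enumerates all tables; the two-sided p-value
#' is the sum of hypergeometric probabilities not exceeding the observed
#' table's probability times (1 + 1e-7) (the point-probability rule used by
#' mainstream implementations). A zero margin yields p = 1 with a
#' degenerate-table flag.
#'
#' @param tab 2x2 matrix of nonnegative integer counts (rows = outcome,
#'   columns = exposure; the test is invariant to transposes and swaps).
#' @return List with `p_two_sided`, `p_observed_table` (hypergeometric
#'   probability of the observed table), and `degenerate`.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(24, 5, 0, 6), 2, 2))
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("cells must be nonnegative integers", call. = FALSE)
  }
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  n <- r1 + r2
  if (n == 0 || r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    return(list(p_two_sided = 1, p_observed_table = 1, degenerate = TRUE))
  }
  support <- max(0, r1 - c2):min(r1, c1)
  probs <- dhyper(support, c1, c2, r1)
  p_obs <- dhyper(a, c1, c2, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(p_two_sided = min(p, 1), p_observed_table = p_obs, degenerate = FALSE)
}

#' AUC of a binary risk flag for predicting a binary outcome
#'
#' For a binary predictor the ROC has a single interior point, so
#' AUC = (sensitivity + specificity) / 2. The confidence interval uses the
#' DeLong variance of the two-point ROC.
#'
#' @param tab 2x2 matrix laid out as rows = event \{no, yes\}, columns =
#'   \{inlier, outlier\} (as produced by [contingency_table()]).
#' @param level Confidence level (default 0.95).
#' @return List with `auc`, `ci_low`, `ci_high`, `se`, `sensitivity`,
#'   `specificity`.
#' @export
#' @examples
#' binary_auc(matrix(c(24, 5, 0, 6), 2, 2))
binary_auc <- function(tab, level = 0.95) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  a <- tab[1, 1]; b <- tab[1, 2]  # non-events: inlier, outlier
  cc <- tab[2, 1]; d <- tab[2, 2] # events: inlier, outlier
  m <- cc + d  # events
  nn <- a + b  # non-events
  if (m == 0 || nn == 0) stop("AUC undefined: need >= 1 event and >= 1 non-event",
                              call. = FALSE)
  sens <- d / m
  spec <- a / nn
  auc <- (sens + spec) / 2
  # DeLong structural components for binary scores (flag in {0,1}):
  # events with flag 1 have V10 = (a + b/2)/nn, flag 0 -> (a/2)/nn;
  # non-events with flag 0 have V01 = (d + cc/2)/m, flag 1 -> (d/2)/m.
  v10 <- c(rep((a + b / 2) / nn, d), rep((a / 2) / nn, cc))
  v01 <- c(rep((d + cc / 2) / m, a), rep((d / 2) / m, b))
  s10 <- if (m > 1) var(v10) else 0
  s01 <- if (nn > 1) var(v01) else 0
  se <- sqrt(s10 / m + s01 / nn)
  z <- qnorm(1 - (1 - level) / 2)
  list(auc = auc,
       ci_low = max(0, auc - z * se),
       ci_high = min(1, auc + z * se),
       se = se, sensitivity = sens, specificity = spec)
}

#' Spearman rank correlation with a Fisher-z confidence interval
#'
#' Pearson correlation of mid-ranks (ties receive average ranks); the CI uses
#' the Fisher z-transform with standard error \eqn{1/\sqrt{n-3}}.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @param level Confidence level (default 0.95).
#' @return List with `rho`, `ci_low`, `ci_high`, `n`.
#' @export
spearman_rho <- function(x, y, level = 0.95) {
  stopifnot(length(x) == length(y))
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  rho <- cor(rank(x), rank(y))
  z <- atanh(min(max(rho, -1 + 1e-15), 1 - 1e-15))
  se <- 1 / sqrt(n - 3)
  q <- qnorm(1 - (1 - level) / 2)
  list(rho = rho, ci_low = tanh(z - q * se), ci_high = tanh(z + q * se), n = n)
}
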