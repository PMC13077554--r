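#' Apply exclusion flags and produce the enrolment accounting table
#'
#' Splits a screened cohort into the analysis set and an accounting table
#' of per-reason exclusion counts, the bookkeeping behind a study
#' flowchart. A record is excluded iff `exclusion_reason` is non-missing;
#' an `included` flag that contradicts the reason column is an error.
#'
#' @param screened Data frame with an `exclusion_reason` column
#'   (`NA`/empty = included) and optionally a logical `included` column
#'   cross-checked against it.
#' @return A list with `analysis_set` (rows with no exclusion reason),
#'   `accounting` (data frame `reason`, `n`), `n_screened`, `n_excluded`,
#'   `n_analyzed`.
#' @export
apply_exclusions <- function(screened) {
  stopifnot(is.data.frame(screened))
  reason <- screened$exclusion_reason
  if (is.null(reason)) stop("screened needs an exclusion_reason column", call. = FALSE)
  reason[!is.na(reason) & reason == ""] <- NA
  excluded <- !is.na(reason)
  if (!is.null(screened$included)) {
    if (any(screened$included & excluded) || any(!screened$included & !excluded)) {
      stop("included flag contradicts exclusion_reason", call. = FALSE)
    }
  }
  acct <- if (any(excluded)) {
    tab <- table(reason[excluded])
    data.frame(reason = names(tab), n = as.integer(tab), row.names = NULL)
  } else {
    data.frame(reason = character(0), n = integer(0))
  }
  list(analysis_set = screened[!excluded, , drop = FALSE],
       accounting = acct,
       n_screened = nrow(screened),
       n_excluded = sum(excluded),
       n_analyzed = nrow(screened) - sum(excluded))
}

#' Detection rate of an outcome
#'
#' Proportion of patients meeting an outcome predicate (e.g. at least one
#' pathologically confirmed adenoma for the ADR), reported with numerator
#' and denominator.
#'
#' @param x Either a data frame plus a `predicate` function/column name,
#'   or a count of positives when `n` is given.
#' @param predicate Function mapping the data frame to a logical vector,
#'   or the name of a 0/1 column.
#' @param n Denominator when `x` is a count.
#' @return A list of class `detection_rate`: `rate`, `positives`,
#'   `denominator`, `percent` (rounded to one decimal, as printed in
#'   study tables).
#' @export
detection_rate <- function(x, predicate = NULL, n = NULL) {
  if (is.numeric(x) && !is.null(n)) {
    pos <- x; den <- n
  } else {
    stopifnot(is.data.frame(x))
    flag <- if (is.function(predicate)) predicate(x) else x[[predicate]]
    if (is.null(flag)) stop("unknown outcome column", call. = FALSE)
    pos <- sum(flag > 0); den <- nrow(x)
  }
  if (den <= 0) stop("empty denominator", call. = FALSE)
  structure(list(rate = pos / den, positives = pos, denominator = den,
                 percent = round_half_up(100 * pos / den, 1)),
            class = "detection_rate")
}

#' @export
print.detection_rate <- function(x, ...) {
  cat(sprintf("%d / %d = %.1f%%\n", x$positives, x$denominator, x$percent))
  invisible(x)
}

# Wilson score interval for a single proportion.
wilson_ci <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

#' Difference of two detection rates with Newcombe score interval
#'
#' Point estimate `p1 - p2` in percentage points with a 95% CI by the
#' Newcombe hybrid score method (square-and-add of the two Wilson
#' intervals), which yields the asymmetric intervals typical of published
#' rate comparisons; a Wald interval is available via `method`.
#'
#' @param x1,n1 Positives and denominator of the first group.
#' @param x2,n2 Positives and denominator of the second group (disjoint).
#' @param conf Confidence level.
#' @param method `"newcombe"` (default) or `"wald"`.
#' @return A list of class `rate_difference`: `diff_pp` (percentage
#'   points), `ci_pp` (length 2), `p1`, `p2`.
#' @export
rate_difference <- function(x1, n1, x2, n2, conf = 0.95,
                            method = c("newcombe", "wald")) {
  method <- match.arg(method)
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1; p2 <- x2 / n2
  d <- p1 - p2
  if (method == "newcombe") {
    w1 <- wilson_ci(x1, n1, conf); w2 <- wilson_ci(x2, n2, conf)
    lo <- d - sqrt((p1 - w1["lower"])^2 + (w2["upper"] - p2)^2)
    hi <- d + sqrt((w1["upper"] - p1)^2 + (p2 - w2["lower"])^2)
  } else {
    z <- qnorm(1 - (1 - conf) / 2)
    se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
    lo <- d - z * se; hi <- d + z * se
  }
  structure(list(diff_pp = 100 * d, ci_pp = 100 * c(unname(lo), unname(hi)),
                 p1 = p1, p2 = p2, method = method),
            class = "rate_difference")
}

#' @export
print.rate_difference <- function(x, ...) {
  cat(sprintf("%.1f percentage points (95%%CI %.1f to %.1f)\n",
              x$diff_pp, x$ci_pp[1], x$ci_pp[2]))
  invisible(x)
}

#' Unadjusted odds ratio of a 2x2 table with Woolf interval
#'
#' `OR = (a d) / (b c)` with a log-scale (Woolf) confidence interval.
#' When any cell is zero, 0.5 is added to every cell (Haldane–Anscombe
#' continuity correction). Two zero cells in the same margin leave the OR
#' undefined and raise an error.
#'
#' @param a,b Outcome-positive / outcome-negative counts, exposed group.
#' @param c,d Outcome-positive / outcome-negative counts, reference group.
#' @param conf Confidence level.
#' @return A list of class `odds_ratio`: `or`, `ci`, `corrected`.
#' @export
odds_ratio_2x2 <- function(a, b, c, d, conf = 0.95) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if ((a == 0 && b == 0) || (c == 0 && d == 0) ||
      (a == 0 && c == 0) || (b == 0 && d == 0)) {
    stop("odds ratio undefined: two zero cells share a margin", call. = FALSE)
  }
  corrected <- any(counts == 0)
  if (corrected) counts <- counts + 0.5
  or <- (counts["a"] * counts["d"]) / (counts["b"] * counts["c"])
  se <- sqrt(sum(1 / counts))
  z <- qnorm(1 - (1 - conf) / 2)
  ci <- exp(log(or) + c(-1, 1) * z * se)
  structure(list(or = unname(or), ci = unname(ci), corrected = corrected),
            class = "odds_ratio")
}

#' Bonferroni-adjusted significance level
#'
#' `alpha / n_tests`; e.g. eleven outcome comparisons at a family level
#' of 0.05 are each tested at 0.0045.
#'
#' @param alpha Family-wise significance level.
#' @param n_tests Number of tests (>= 1).
#' @return The adjusted per-test level (unrounded; round only for
#'   display).
#' @export
bonferroni_alpha <- function(alpha = 0.05, n_tests = 11) {
  if (n_tests < 1) stop("n_tests must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  alpha / n_tests
}

#' Power of the two-sided two-proportion test
#'
#' Normal approximation with unpooled variance:
#' \deqn{power = \Phi\left(\frac{|p_1-p_2|\sqrt{n}}{\sqrt{p_1 q_1 + p_2 q_2}} -
#'   z_{1-\alpha/2}\right)}
#' per group of size `n`. In inverse mode (`power` given, `n_per_group`
#' missing) returns the smallest per-group `n` achieving the requested
#' power.
#'
#' @param p1,p2 The two outcome proportions (in `(0, 1)`).
#' @param alpha Two-sided significance level.
#' @param n_per_group Group size (forward mode).
#' @param power Target power (inverse mode).
#' @return Forward mode: the power. Inverse mode: the required per-group
#'   `n` (integer).
#' @export
power_two_proportions <- function(p1, p2, alpha = 0.05, n_per_group = NULL,
                                  power = NULL) {
  if (any(c(p1, p2) <= 0) || any(c(p1, p2) >= 1)) {
    stop("p1 and p2 must be probabilities in (0, 1)", call. = FALSE)
  }
  z <- qnorm(1 - alpha / 2)
  sd0 <- sqrt(p1 * (1 - p1) + p2 * (1 - p2))
  delta <- abs(p1 - p2)
  if (!is.null(n_per_group)) {
    if (n_per_group < 2) stop("n_per_group must be >= 2", call. = FALSE)
    shift <- delta * sqrt(n_per_group) / sd0
    # both rejection tails; the far tail is negligible except under H0
    return(pnorm(shift - z) + pnorm(-shift - z))
  }
  if (is.null(power)) stop("give n_per_group or power", call. = FALSE)
  if (power <= alpha || power >= 1) stop("power must be in (alpha, 1)", call. = FALSE)
  if (delta == 0) stop("p1 must differ from p2 in inverse mode", call. = FALSE)
  zb <- qnorm(power)
  ceiling(((z + zb) * sd0 / delta)^2)
}
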