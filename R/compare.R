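# The eleven-outcome comparison report of the prospective study design:
# one primary (ADR) and ten secondary outcomes, each tested at the
# Bonferroni-adjusted level.

.outcome_spec <- list(
  list(name = "Adenoma detection rate", column = "adenoma", kind = "binary"),
  list(name = "Diminutive adenoma (<=5 mm)", column = "aden_diminutive", kind = "binary"),
  list(name = "Small adenoma (>5 to <10 mm)", column = "aden_small", kind = "binary"),
  list(name = "Large adenoma (>=10 mm)", column = "aden_large", kind = "binary"),
  list(name = "Advanced adenoma", column = "advanced", kind = "binary"),
  list(name = "Polyp detection rate", column = "polyp", kind = "binary"),
  list(name = "Diminutive polyp (<=5 mm)", column = "polyp_diminutive", kind = "binary"),
  list(name = "Small polyp (>5 to <10 mm)", column = "polyp_small", kind = "binary"),
  list(name = "Large polyp (>=10 mm)", column = "polyp_large", kind = "binary"),
  list(name = "Number of adenomas", column = "adenoma_count", kind = "count"),
  list(name = "Number of polyps", column = "polyp_count", kind = "count")
)

#' Compare qualified and unqualified groups across the study outcomes
#'
#' Produces the full outcome comparison of a two-group cohort: for each of
#' the 11 outcomes (adenoma detection overall and by size class, advanced
#' adenomas, polyp detection overall and by size class, mean adenoma and
#' polyp counts) it reports group rates or means, the absolute difference
#' with a Newcombe score CI (rates) or Wald CI (means), an adjusted ratio
#' from the mixed models of [fit_glmm_logit()] / [fit_glmm_poisson()]
#' (or an unadjusted 2x2 odds ratio / ratio of means), and a significance
#' flag at the Bonferroni-adjusted level `alpha / 11`.
#'
#' @param cohort Patient-level data frame carrying the outcome columns
#'   (`adenoma`, `aden_diminutive`, ..., `polyp_count`), plus either a
#'   0/1 `group` column or a `ccmea` column with `threshold` given, and —
#'   for adjusted ratios — `sex`, `indication` and `center`.
#' @param threshold Qualified-colonoscopy CCMEA threshold used to derive
#'   the group when no `group` column is present (ties qualify).
#' @param ratios `"adjusted"` (mixed models), `"unadjusted"` (2x2 odds
#'   ratio; ratio of means for counts), or `"none"` (rates and
#'   differences only).
#' @param alpha Family-wise significance level before Bonferroni
#'   correction over the 11 tests.
#' @return A data frame of class `outcome_report`, one row per outcome:
#'   `outcome`, `kind`, `q_summary`, `u_summary` (count (percent) or
#'   mean (SD)), `value_q`, `value_u`, `difference`, `diff_lo`,
#'   `diff_hi`, `ratio_type`, `ratio`, `ratio_lo`, `ratio_hi`,
#'   `p_value`, `significant`. The adjusted alpha is attached as
#'   `attr(x, "alpha_adjusted")`.
#' @export
compare_groups <- function(cohort, threshold = 2000,
                           ratios = c("adjusted", "unadjusted", "none"),
                           alpha = 0.05) {
  ratios <- match.arg(ratios)
  stopifnot(is.data.frame(cohort))
  if (is.null(cohort$group)) {
    if (is.null(cohort$ccmea)) {
      stop("cohort needs a group column or a ccmea column with threshold",
           call. = FALSE)
    }
    cohort$group <- as.integer(cohort$ccmea >= threshold)
  }
  nq <- sum(cohort$group == 1); nu <- sum(cohort$group == 0)
  if (nq == 0 || nu == 0) {
    stop("both groups must contain at least one patient", call. = FALSE)
  }
  a_adj <- bonferroni_alpha(alpha, length(.outcome_spec))
  q <- cohort[cohort$group == 1, , drop = FALSE]
  u <- cohort[cohort$group == 0, , drop = FALSE]

  rows <- lapply(.outcome_spec, function(os) {
    col <- os$column
    if (is.null(cohort[[col]])) {
      stop("cohort lacks outcome column: ", col, call. = FALSE)
    }
    ratio <- c(NA_real_, NA_real_, NA_real_); p <- NA_real_
    rtype <- "none"
    if (os$kind == "binary") {
      xq <- sum(q[[col]] > 0); xu <- sum(u[[col]] > 0)
      rd <- rate_difference(xq, nq, xu, nu)
      val_q <- 100 * xq / nq; val_u <- 100 * xu / nu
      sum_q <- sprintf("%d (%.1f)", xq, val_q)
      sum_u <- sprintf("%d (%.1f)", xu, val_u)
      diff <- rd$diff_pp; dlo <- rd$ci_pp[1]; dhi <- rd$ci_pp[2]
      if (ratios == "adjusted") {
        est <- fit_glmm_logit(cohort, col)
        ratio <- c(est$ratio, est$ci); p <- est$p_value; rtype <- "aOR"
      } else if (ratios == "unadjusted") {
        or <- odds_ratio_2x2(xq, nq - xq, xu, nu - xu)
        ratio <- c(or$or, or$ci); rtype <- "OR"
        p <- suppressWarnings(
          stats::prop.test(c(xq, xu), c(nq, nu))$p.value)
      }
    } else {
      mq <- mean(q[[col]]); mu_ <- mean(u[[col]])
      sdq <- stats::sd(q[[col]]); sdu <- stats::sd(u[[col]])
      val_q <- mq; val_u <- mu_
      sum_q <- sprintf("%.1f (%.1f)", mq, sdq)
      sum_u <- sprintf("%.1f (%.1f)", mu_, sdu)
      diff <- mq - mu_
      z <- qnorm(0.975)
      se <- sqrt(sdq^2 / nq + sdu^2 / nu)
      dlo <- diff - z * se; dhi <- diff + z * se
      if (ratios == "adjusted") {
        est <- fit_glmm_poisson(cohort, col)
        ratio <- c(est$ratio, est$ci); p <- est$p_value; rtype <- "aIRR"
      } else if (ratios == "unadjusted") {
        rtype <- "IRR"
        ratio <- c(mq / mu_, NA_real_, NA_real_)
        p <- stats::poisson.test(c(sum(q[[col]]), sum(u[[col]])),
                                 c(nq, nu))$p.value
      }
    }
    data.frame(outcome = os$name, kind = os$kind,
               q_summary = sum_q, u_summary = sum_u,
               value_q = val_q, value_u = val_u,
               difference = diff, diff_lo = dlo, diff_hi = dhi,
               ratio_type = rtype, ratio = ratio[1],
               ratio_lo = ratio[2], ratio_hi = ratio[3],
               p_value = p,
               significant = if (is.na(p)) NA else p < a_adj,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha_adjusted") <- a_adj
  attr(out, "n_groups") <- c(qualified = nq, unqualified = nu)
  class(out) <- c("outcome_report", "data.frame")
  out
}

#' @export
print.outcome_report <- function(x, digits = 2, ...) {
  ng <- attr(x, "n_groups")
  cat(sprintf("Outcome comparison: qualified n = %d, unqualified n = %d\n",
              ng[1], ng[2]))
  cat(sprintf("Bonferroni-adjusted significance level: %.4f\n\n",
              attr(x, "alpha_adjusted")))
  show <- data.frame(
    outcome = x$outcome, qualified = x$q_summary, unqualified = x$u_summary,
    difference = sprintf("%.1f (%.1f to %.1f)", x$difference, x$diff_lo,
                         x$diff_hi),
    ratio = ifelse(is.na(x$ratio), "-",
                   sprintf("%s %.1f (%.1f-%.1f)", x$ratio_type, x$ratio,
                           x$ratio_lo, x$ratio_hi)),
    p = ifelse(is.na(x$p_value), "-", format(x$p_value, digits = 2)),
    stringsAsFactors = FALSE
  )
  print(show, row.names = FALSE, right = FALSE)
  invisible(x)
}
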