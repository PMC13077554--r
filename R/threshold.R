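#' Bin a cohort by CCMEA
#'
#' Groups patients into half-open CCMEA intervals `[k*width, (k+1)*width)`
#' starting at 0 and computes the per-bin adenoma detection rate. Trailing
#' empty bins are dropped; interior empty bins are kept (with `NA` ADR) so
#' the bins partition the observed range.
#'
#' @param cohort Data frame with numeric `ccmea` and 0/1 `adenoma`
#'   columns (e.g. from [generate_cohort()]).
#' @param width Bin width in CCMEA units (> 0); the conventional grouping
#'   uses intervals of 1000.
#' @return A data frame of class `ccmea_bins`: `bin_lower`, `bin_upper`,
#'   `midpoint`, `n_patients`, `n_adenoma_positive`, `adr`.
#' @export
bin_by_ccmea <- function(cohort, width = 1000) {
  if (width <= 0) stop("width must be > 0", call. = FALSE)
  if (is.null(cohort$ccmea) || is.null(cohort$adenoma)) {
    stop("cohort must have ccmea and adenoma columns", call. = FALSE)
  }
  n <- nrow(cohort)
  if (is.null(n) || n == 0L) stop("cohort is empty", call. = FALSE)
  k <- floor(cohort$ccmea / width)
  if (any(k < 0)) stop("ccmea values must be non-negative", call. = FALSE)
  kmax <- max(k)
  lower <- (0:kmax) * width
  n_pat <- vapply(0:kmax, function(i) sum(k == i), integer(1))
  n_pos <- vapply(0:kmax, function(i) sum(cohort$adenoma[k == i]), numeric(1))
  bins <- data.frame(
    bin_lower = lower, bin_upper = lower + width,
    midpoint = lower + width / 2,
    n_patients = n_pat, n_adenoma_positive = as.integer(n_pos),
    adr = ifelse(n_pat > 0, n_pos / n_pat, NA_real_)
  )
  class(bins) <- c("ccmea_bins", "data.frame")
  bins
}

#' Fit the ADR-vs-CCMEA dose-response curve
#'
#' Fits a monotone saturating logistic
#' \deqn{ADR(c) = L / (1 + e^{-k (c - c_0)})}
#' to the bin midpoints, weighted by bin size. ADR is a bounded increasing
#' dose-response in cumulative exposure, and the three-parameter logistic
#' is the minimal such family. When the nonlinear fit fails to converge
#' the fit falls back to weighted isotonic regression (flagged in the
#' result); bins with identical ADR give a flagged constant curve.
#'
#' @param bins A `ccmea_bins` data frame with at least 3 non-empty bins.
#' @return A list of class `adr_curve`: `method` (`"logistic"`,
#'   `"isotonic"` or `"constant"`), `params` (`L`, `k`, `c0` for the
#'   logistic), `predict` (function of CCMEA), `residuals` (per-bin),
#'   `converged`, `degenerate`.
#' @export
fit_adr_curve <- function(bins) {
  stopifnot(inherits(bins, "data.frame"))
  use <- bins[bins$n_patients > 0, ]
  if (nrow(use) < 3) stop("need at least 3 non-empty bins", call. = FALSE)
  x <- use$midpoint; y <- use$adr; wts <- use$n_patients

  if (max(y) - min(y) < 1e-12) {
    const <- y[1]
    f <- function(c) rep(const, length(c))
    return(structure(list(method = "constant", params = c(L = const),
                          predict = f, residuals = y - f(x),
                          converged = TRUE, degenerate = TRUE),
                     class = "adr_curve"))
  }

  start <- list(
    L = min(1, max(y) * 1.05 + 1e-3),
    k = 4 / max(diff(range(x)), 1),
    c0 = x[which.min(abs(y - (min(y) + max(y)) / 2))]
  )
  fit <- tryCatch(
    minpack.lm::nlsLM(
      adr ~ L / (1 + exp(-k * (midpoint - c0))),
      data = data.frame(midpoint = x, adr = y),
      weights = wts, start = start,
      lower = c(L = 1e-6, k = 1e-9, c0 = -Inf),
      upper = c(L = 1, k = Inf, c0 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (!is.null(fit)) {
    p <- coef(fit)
    f <- function(c) p[["L"]] / (1 + exp(-p[["k"]] * (c - p[["c0"]])))
    return(structure(list(method = "logistic", params = p, predict = f,
                          residuals = y - f(x), converged = TRUE,
                          degenerate = FALSE),
                     class = "adr_curve"))
  }
  # isotonic fallback: monotone step/interpolated curve, flagged
  ord <- order(x)
  iso <- isoreg(x[ord], y[ord])
  xi <- x[ord]; yi <- iso$yf
  f <- function(c) {
    approx(xi, yi, xout = c, rule = 2, ties = "ordered")$y
  }
  structure(list(method = "isotonic", params = NULL, predict = f,
                 residuals = y[ord] - yi, converged = FALSE,
                 degenerate = FALSE),
            class = "adr_curve")
}

#' Select the qualified-colonoscopy CCMEA threshold
#'
#' Returns the smallest multiple of the bin width such that the fitted
#' ADR curve stays above the target at that point and everywhere beyond
#' it (evaluated on candidate bin edges across the observed range). The
#' criterion is applied to the fitted curve by default because raw bin
#' ADRs may be non-monotone from sampling noise; `use_fitted = FALSE`
#' applies it to raw bin ADRs instead.
#'
#' @param curve An `adr_curve` from [fit_adr_curve()].
#' @param bins The `ccmea_bins` the curve was fitted to.
#' @param adr_target Target ADR (default 0.25, the conventional screening
#'   benchmark).
#' @param width Threshold granularity in CCMEA units (bin width).
#' @param use_fitted Apply the criterion to the fitted curve (default) or
#'   to raw bin ADRs.
#' @return A list of class `threshold_result`: `threshold` (CCMEA units,
#'   or `NA` with `reached = FALSE` when no candidate qualifies),
#'   `adr_target`, `curve`, `diagnostics` (per-bin fit residuals and
#'   fitted values).
#' @export
select_threshold <- function(curve, bins, adr_target = 0.25, width = 1000,
                             use_fitted = TRUE) {
  stopifnot(inherits(curve, "adr_curve"))
  edges <- bins$bin_lower
  fitted_at <- curve$predict(edges)
  ok <- if (use_fitted) {
    # monotone-from-here condition on the candidate edges
    rev(cumprod(rev(fitted_at > adr_target))) > 0
  } else {
    raw <- bins$adr
    rev(cumprod(rev(ifelse(is.na(raw), TRUE, raw > adr_target)))) > 0
  }
  idx <- which(ok)
  threshold <- if (length(idx) == 0L) NA_real_ else edges[min(idx)]
  structure(
    list(threshold = threshold, reached = length(idx) > 0L,
         adr_target = adr_target, width = width, curve = curve,
         diagnostics = data.frame(
           bin_lower = bins$bin_lower, n_patients = bins$n_patients,
           adr = bins$adr, fitted = fitted_at
         )),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  if (x$reached) {
    cat(sprintf(
      "Qualified-colonoscopy threshold: CCMEA >= %g (fitted ADR above %.0f%% target; %s curve)\n",
      x$threshold, 100 * x$adr_target, x$curve$method))
  } else {
    cat(sprintf(
      "No qualifying threshold: fitted ADR never exceeds the %.0f%% target\n",
      100 * x$adr_target))
  }
  invisible(x)
}

#' Calibrate the CCMEA threshold from a cohort table
#'
#' Convenience wrapper: [bin_by_ccmea()], [fit_adr_curve()],
#' [select_threshold()] in one call.
#'
#' @inheritParams bin_by_ccmea
#' @inheritParams select_threshold
#' @return A `threshold_result`.
#' @export
calibrate_threshold <- function(cohort, width = 1000, adr_target = 0.25,
                                use_fitted = TRUE) {
  bins <- bin_by_ccmea(cohort, width)
  curve <- fit_adr_curve(bins)
  select_threshold(curve, bins, adr_target = adr_target, width = width,
                   use_fitted = use_fitted)
}
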