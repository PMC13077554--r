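make_screened <- function(reasons) {
  n <- 551
  reason_vec <- rep(NA_character_, n)
  idx <- 1
  for (r in names(reasons)) {
    k <- reasons[[r]]
    if (k > 0) reason_vec[idx:(idx + k - 1)] <- r
    idx <- idx + k
  }
  data.frame(patient_id = seq_len(n), exclusion_reason = reason_vec,
             stringsAsFactors = FALSE)
}

study_exclusions <- c("suspected IBD" = 6, "inadequate bowel preparation" = 15,
                      "failed cecal intubation" = 7, "no biopsies" = 8,
                      "cancerous obstruction" = 5)

test_that("exclusion accounting reproduces the enrolment flowchart", {
  res <- apply_exclusions(make_screened(study_exclusions))
  expect_equal(res$n_screened, 551)
  expect_equal(res$n_excluded, 41)
  expect_equal(res$n_analyzed, 510)
  expect_equal(sum(res$accounting$n), 41)
  expect_setequal(res$accounting$reason, names(study_exclusions))
})

test_that("exclusion edge cases behave", {
  none <- data.frame(patient_id = 1:10, exclusion_reason = NA_character_)
  res <- apply_exclusions(none)
  expect_equal(nrow(res$analysis_set), 10)
  all_out <- data.frame(patient_id = 1:4, exclusion_reason = rep("x", 4))
  res2 <- apply_exclusions(all_out)
  expect_equal(nrow(res2$analysis_set), 0)
  expect_equal(res2$accounting$n, 4)
  bad <- data.frame(patient_id = 1, exclusion_reason = "x", included = TRUE)
  expect_error(apply_exclusions(bad), "contradicts")
})

test_that("detection rates reproduce printed group percentages", {
  expect_equal(detection_rate(145, n = 270)$percent, 53.7)
  expect_equal(detection_rate(34, n = 240)$percent, 14.2)
  expect_equal(detection_rate(0, n = 50)$percent, 0)
  df <- data.frame(adenoma = c(1, 0, 1, 1))
  expect_equal(detection_rate(df, "adenoma")$rate, 0.75)
  expect_equal(detection_rate(df, function(d) d$adenoma > 0)$positives, 3)
  expect_error(detection_rate(0, n = 0), "denominator")
})

test_that("rate differences match the published point estimates", {
  adr <- rate_difference(145, 270, 34, 240)
  expect_equal(round(adr$diff_pp, 1), 39.5)
  pdr <- rate_difference(242, 270, 96, 240)
  expect_equal(round(pdr$diff_pp, 1), 49.6)
  same <- rate_difference(30, 100, 30, 100)
  expect_equal(same$diff_pp, 0)
  # CI brackets the point estimate, for both interval methods
  for (m in c("newcombe", "wald")) {
    rd <- rate_difference(145, 270, 34, 240, method = m)
    expect_lt(rd$ci_pp[1], rd$diff_pp)
    expect_gt(rd$ci_pp[2], rd$diff_pp)
  }
  # Newcombe interval is asymmetric around the estimate in general
  rd <- rate_difference(242, 270, 96, 240)
  expect_false(isTRUE(all.equal(rd$diff_pp - rd$ci_pp[1],
                                rd$ci_pp[2] - rd$diff_pp)))
})

test_that("2x2 odds ratios follow the cross-product with Woolf intervals", {
  expect_equal(odds_ratio_2x2(10, 10, 10, 10)$or, 1)
  # qualified 145/270, unqualified 34/240: OR = (145*206)/(125*34)
  or <- odds_ratio_2x2(145, 270 - 145, 34, 240 - 34)
  expect_equal(or$or, (145 * 206) / (125 * 34), tolerance = 1e-12)
  expect_equal(round(or$or, 2), 7.03)
  # continuity correction keeps rare-event tables finite
  rare <- odds_ratio_2x2(14, 256, 1, 239)
  expect_true(is.finite(rare$or) && all(is.finite(rare$ci)))
  zero <- odds_ratio_2x2(5, 5, 0, 10)
  expect_true(zero$corrected)
  expect_true(is.finite(zero$or))
  expect_error(odds_ratio_2x2(0, 10, 0, 10), "zero cells")
  expect_error(odds_ratio_2x2(-1, 1, 1, 1), "non-negative")
})

test_that("Bonferroni adjustment divides the family-wise level", {
  expect_equal(round(bonferroni_alpha(0.05, 11), 4), 0.0045)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.10, 4), 0.025)
  expect_error(bonferroni_alpha(0.05, 0), "n_tests")
  expect_error(bonferroni_alpha(0, 5), "alpha")
})

test_that("two-proportion power matches the normal approximation", {
  # at the null the two-sided rejection probability equals alpha
  expect_equal(power_two_proportions(0.3, 0.3, 0.05, n_per_group = 100), 0.05,
               tolerance = 1e-10)
  p <- power_two_proportions(0.33, 0.23, 0.05, n_per_group = 247)
  expect_gt(p, 0.68); expect_lt(p, 0.76)
  # monotone in n
  ns <- c(50, 100, 200, 400, 800)
  pw <- vapply(ns, function(n) {
    power_two_proportions(0.33, 0.23, 0.05, n_per_group = n)
  }, numeric(1))
  expect_true(all(diff(pw) > 0))
  # inverse mode is consistent with forward mode
  n_req <- power_two_proportions(0.33, 0.23, 0.05, power = 0.74)
  expect_gte(power_two_proportions(0.33, 0.23, 0.05, n_per_group = n_req), 0.74)
  expect_lt(power_two_proportions(0.33, 0.23, 0.05, n_per_group = n_req - 5),
            0.74)
  expect_error(power_two_proportions(1.2, 0.3, 0.05, 100), "probabilities")
  expect_error(power_two_proportions(0.3, 0.2, 0.05), "n_per_group or power")
})

test_that("power approximation agrees with Monte-Carlo simulation", {
  n <- 247; p1 <- 0.33; p2 <- 0.23
  approx_power <- power_two_proportions(p1, p2, 0.05, n_per_group = n)
  sim <- ccmea:::with_seed(123, {
    reject <- logical(4000)
    for (i in seq_along(reject)) {
      x1 <- rbinom(1, n, p1); x2 <- rbinom(1, n, p2)
      reject[i] <- suppressWarnings(
        stats::prop.test(c(x1, x2), c(n, n))$p.value) < 0.05
    }
    mean(reject)
  })
  expect_equal(approx_power, sim, tolerance = 0.05)
})
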