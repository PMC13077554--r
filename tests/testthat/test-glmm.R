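test_that("null group effects are recovered as ratios near 1", {
  # a single 95% CI misses the truth 5% of the time by construction, so
  # require coverage in most of a small replicate set
  cover_or <- cover_irr <- logical(5)
  for (r in 1:5) {
    g <- generate_grouped_cohort(n = 2000, log_or = 0, log_irr = 0,
                                 seed = 700 + r)
    est <- fit_glmm_logit(g, "outcome")
    cover_or[r] <- est$ci[1] < 1 && est$ci[2] > 1
    irr <- fit_glmm_poisson(g, "count")
    cover_irr[r] <- irr$ci[1] < 1 && irr$ci[2] > 1
    expect_equal(irr$ratio, 1, tolerance = 0.15)
  }
  expect_gte(sum(cover_or), 4)
  expect_gte(sum(cover_irr), 4)
})

test_that("a strong group effect is estimated with a covering CI", {
  g <- generate_grouped_cohort(n = 510, log_or = log(8), log_irr = log(4),
                               seed = 42)
  est <- fit_glmm_logit(g, "outcome")
  expect_identical(est$ratio_type, "aOR")
  expect_lt(est$ci[1], 8); expect_gt(est$ci[2], 8)
  expect_lt(est$p_value, 0.001)
  irr <- fit_glmm_poisson(g, "count")
  expect_lt(irr$ci[1], 4); expect_gt(irr$ci[2], 4)
})

test_that("zero center variance yields a near-zero random-intercept SD", {
  g <- generate_grouped_cohort(n = 3000, center_sd = 0, seed = 9)
  est <- fit_glmm_logit(g, "outcome")
  if (!est$fallback) expect_lt(est$re_sd, 0.1)
})

test_that("degenerate inputs are flagged, never silently estimated", {
  g <- generate_grouped_cohort(n = 300, seed = 11)
  g$count[g$group == 1] <- 0L  # boundary: no events in the exposed group
  irr <- fit_glmm_poisson(g, "count")
  expect_true(irr$fallback || irr$ratio < 1e-4 || length(irr$notes) > 0)
  expect_error(fit_glmm_logit(g[g$center == "center1", ], "outcome"),
               "2 levels")
  expect_error(fit_glmm_logit(g, "nonexistent"), "missing column")
})

test_that("the outcome report has the full 11-outcome structure", {
  coh <- generate_cohort(cohort_gen_spec(n_patients = 800, seed = 13))
  rep <- compare_groups(coh, threshold = 2000, ratios = "unadjusted")
  expect_s3_class(rep, "outcome_report")
  expect_equal(nrow(rep), 11)
  expect_equal(sum(rep$kind == "binary"), 9)
  expect_equal(sum(rep$kind == "count"), 2)
  expect_equal(attr(rep, "alpha_adjusted"), 0.05 / 11)
  expect_true(all(is.finite(rep$difference)))
  # qualified group detects more across the board in the calibrated cohort
  expect_true(all(rep$difference > 0))
})

test_that("identical groups give zero differences and unit ratios", {
  coh <- generate_cohort(cohort_gen_spec(n_patients = 400, seed = 19))
  twin <- rbind(coh, coh)
  twin$group <- rep(c(1L, 0L), each = nrow(coh))
  rep <- compare_groups(twin, ratios = "unadjusted")
  expect_true(all(abs(rep$difference) < 1e-9))
  expect_true(all(abs(rep$ratio[rep$ratio_type == "OR"] - 1) < 1e-9))
  one_group <- coh; one_group$group <- 1L
  expect_error(compare_groups(one_group), "both groups")
})

test_that("rates reconstructed from printed counts reproduce the table", {
  # patient-level indicator columns built from the published counts
  expand <- function(pos, n) c(rep(1L, pos), rep(0L, n - pos))
  nq <- 270; nu <- 240
  coh <- data.frame(
    group = rep(c(1L, 0L), c(nq, nu)),
    adenoma = c(expand(145, nq), expand(34, nu)),
    aden_diminutive = c(expand(114, nq), expand(24, nu)),
    aden_small = c(expand(55, nq), expand(9, nu)),
    aden_large = c(expand(14, nq), expand(1, nu)),
    advanced = c(expand(16, nq), expand(2, nu)),
    polyp = c(expand(242, nq), expand(96, nu)),
    polyp_diminutive = c(expand(222, nq), expand(83, nu)),
    polyp_small = c(expand(77, nq), expand(21, nu)),
    polyp_large = c(expand(19, nq), expand(3, nu)),
    adenoma_count = 0, polyp_count = 0
  )
  rep <- compare_groups(coh, ratios = "none")
  bin <- rep[rep$kind == "binary", ]
  rhu <- ccmea:::round_half_up
  expect_equal(rhu(bin$value_q, 1),
               c(53.7, 42.2, 20.4, 5.2, 5.9, 89.6, 82.2, 28.5, 7.0))
  expect_equal(rhu(bin$value_u, 1),
               c(14.2, 10.0, 3.8, 0.4, 0.8, 40.0, 34.6, 8.8, 1.3))
  expect_equal(rhu(bin$difference, 1),
               c(39.5, 32.2, 16.6, 4.8, 5.1, 49.6, 47.6, 19.8, 5.8))
})
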