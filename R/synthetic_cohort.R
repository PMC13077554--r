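#' Specification for a synthetic multi-center colonoscopy cohort
#'
#' Describes the generative model for a per-patient cohort table linking
#' the cumulative mucosal exposure score (CCMEA) to lesion outcomes across
#' healthcare centers. Adenoma presence follows a logistic model on the
#' logit scale,
#' \deqn{logit P(adenoma) = \beta_0 + \beta_c (CCMEA - c_{1/2}) +
#'       \beta_{sex} [male] + \beta_{ind}[indication] + u_{center},}
#' with a Gaussian center random intercept \eqn{u_{center}}. Lesion counts
#' are built so that `polyp_count >= adenoma_count >= adenoma indicator`
#' holds by construction: a positive patient carries `1 + Poisson` extra
#' adenomas, and polyps add an independent Poisson count of non-adenomatous
#' lesions, both with log-rates increasing in CCMEA.
#'
#' Default parameters are calibrated so that the marginal ADR curve crosses
#' 25% just below CCMEA = 2000 (inside the `[1000, 2000)` bin) and the
#' qualified / unqualified group rates are of the order seen in multi-center
#' screening practice (ADR roughly 54% vs 14%, mean polyps roughly 5.8 vs
#' 1.3 at a threshold of 2000).
#'
#' @param n_patients Number of patients.
#' @param n_centers Number of healthcare centers (>= 1).
#' @param center_sd SD of the center random intercept on the logit scale
#'   (also applied to log lesion rates).
#' @param beta0 Intercept on the logit scale at `ccmea = half_point` for a
#'   female health-examination patient with zero center effect.
#' @param beta_ccmea Log-odds slope per CCMEA unit.
#' @param half_point CCMEA value at which the linear predictor equals
#'   `beta0` (the calibration anchor of the curve).
#' @param beta_sex Log-odds for male vs female.
#' @param beta_indication Named log-odds for indication levels
#'   `diagnostic` and `surveillance` relative to `health examination`.
#' @param p_male Marginal probability of male sex.
#' @param p_indication Marginal probabilities of the three indications
#'   (health examination, diagnostic, surveillance); must sum to 1.
#' @param ccmea_shape,ccmea_scale Gamma parameters of the per-patient CCMEA
#'   distribution (positive, right-skewed, spanning several 1000-wide bins).
#' @param adeno_count_coef,polyp_count_coef Length-2 vectors `c(g0, g1)`:
#'   mean extra-lesion rates `max(0, g0 + g1 * ccmea)` for additional
#'   adenomas in adenoma-positive patients and for non-adenomatous polyps
#'   (linear in CCMEA so the right tail of the CCMEA distribution does not
#'   produce runaway counts).
#' @param polyp_disp Negative-binomial size (dispersion) of the
#'   non-adenomatous polyp count; real polyp counts are strongly
#'   overdispersed (SD well above the mean), which a pure Poisson cannot
#'   emulate. `Inf` gives Poisson.
#' @param size_meanlog,size_sdlog Log-normal parameters of per-lesion size
#'   in millimetres.
#' @param p_hgd,p_villous Per-adenoma probabilities of high-grade dysplasia
#'   and villous histology (components of the advanced-adenoma definition).
#' @param seed Integer seed; a fixed seed reproduces the cohort exactly.
#'
#' @return An object of class `cohort_gen_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_gen_spec <- function(n_patients = 510, n_centers = 3,
                            center_sd = 0.3,
                            beta0 = qlogis(0.25) - 0.355,
                            beta_ccmea = 9e-4,
                            half_point = 1700,
                            beta_sex = 0.4,
                            beta_indication = c(diagnostic = 0.15,
                                                surveillance = 0.45),
                            p_male = 0.47,
                            p_indication = c(0.218, 0.620, 0.162),
                            ccmea_shape = 2.0, ccmea_scale = 1150,
                            adeno_count_coef = c(0.24, 1.78e-4),
                            polyp_count_coef = c(-0.58, 1.57e-3),
                            polyp_disp = 0.35,
                            size_meanlog = 1.1, size_sdlog = 0.55,
                            p_hgd = 0.02, p_villous = 0.02,
                            seed = 1L) {
  if (n_centers < 1) stop("n_centers must be >= 1", call. = FALSE)
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  if (center_sd < 0) stop("center_sd must be >= 0", call. = FALSE)
  if (abs(sum(p_indication) - 1) > 1e-8) {
    stop("p_indication must sum to 1", call. = FALSE)
  }
  structure(
    list(n_patients = as.integer(n_patients),
         n_centers = as.integer(n_centers), center_sd = center_sd,
         beta0 = beta0, beta_ccmea = beta_ccmea, half_point = half_point,
         beta_sex = beta_sex, beta_indication = beta_indication,
         p_male = p_male, p_indication = p_indication,
         ccmea_shape = ccmea_shape, ccmea_scale = ccmea_scale,
         adeno_count_coef = adeno_count_coef,
         polyp_count_coef = polyp_count_coef, polyp_disp = polyp_disp,
         size_meanlog = size_meanlog, size_sdlog = size_sdlog,
         p_hgd = p_hgd, p_villous = p_villous, seed = seed),
    class = "cohort_gen_spec"
  )
}

lesion_size_class <- function(size_mm) {
  ifelse(size_mm >= 10, "large", ifelse(size_mm > 5, "small", "diminutive"))
}

#' Generate a synthetic multi-center cohort table
#'
#' Draws a per-patient cohort from a [cohort_gen_spec()]: covariates,
#' per-center CCMEA, Bernoulli adenoma status on the specified logistic
#' curve, adenoma and polyp counts, and per-lesion sizes/histology from
#' which the patient-level outcome indicators of the study report are
#' derived (detection by lesion size class, advanced adenoma).
#'
#' @param spec A [cohort_gen_spec()].
#' @return A data frame of class `ccmea_cohort`, one row per patient, with
#'   columns `patient_id`, `center`, `sex`, `age`, `bmi`, `indication`,
#'   `boston_score`, `ccmea`, `adenoma` (0/1 indicator), `adenoma_count`,
#'   `polyp_count`, `polyp` (0/1), size-class indicators
#'   `aden_diminutive`, `aden_small`, `aden_large`, `advanced`,
#'   `polyp_diminutive`, `polyp_small`, `polyp_large`, and the latent
#'   `p_adenoma`. The per-lesion table is attached as
#'   `attr(x, "lesions")`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_gen_spec"))
  with_seed(spec$seed, {
    n <- spec$n_patients
    centers <- factor(paste0("center", sample.int(spec$n_centers, n, replace = TRUE)),
                      levels = paste0("center", seq_len(spec$n_centers)))
    u <- rnorm(spec$n_centers, 0, spec$center_sd)
    u_pat <- u[as.integer(centers)]
    sex <- factor(ifelse(rbinom(n, 1, spec$p_male) == 1, "male", "female"),
                  levels = c("female", "male"))
    indication <- factor(
      sample(c("health examination", "diagnostic", "surveillance"), n,
             replace = TRUE, prob = spec$p_indication),
      levels = c("health examination", "diagnostic", "surveillance")
    )
    age <- round(rnorm(n, 58.5, 11))
    bmi <- round(rnorm(n, 23.7, 3.6), 1)
    boston <- pmin(9, pmax(6, round(rnorm(n, 7.9, 1.1))))
    ccmea <- rgamma(n, shape = spec$ccmea_shape, scale = spec$ccmea_scale)

    eta <- spec$beta0 + spec$beta_ccmea * (ccmea - spec$half_point) +
      spec$beta_sex * (sex == "male") +
      ifelse(indication == "diagnostic", spec$beta_indication[["diagnostic"]],
             ifelse(indication == "surveillance",
                    spec$beta_indication[["surveillance"]], 0)) +
      u_pat
    p <- plogis(eta)
    adenoma <- rbinom(n, 1, p)

    lam_a <- pmax(0, spec$adeno_count_coef[1] + spec$adeno_count_coef[2] * ccmea) *
      exp(u_pat)
    adenoma_count <- adenoma * (1L + rpois(n, lam_a))
    lam_p <- pmax(0, spec$polyp_count_coef[1] + spec$polyp_count_coef[2] * ccmea) *
      exp(u_pat)
    extra <- if (is.finite(spec$polyp_disp)) {
      rnbinom(n, size = spec$polyp_disp, mu = lam_p)
    } else {
      rpois(n, lam_p)
    }
    polyp_count <- adenoma_count + extra

    # per-lesion sizes and histology
    pid <- rep.int(seq_len(n), polyp_count)
    n_les <- length(pid)
    is_adenoma <- unlist(lapply(seq_len(n), function(i) {
      c(rep(TRUE, adenoma_count[i]), rep(FALSE, polyp_count[i] - adenoma_count[i]))
    }), use.names = FALSE)
    size <- rlnorm(n_les, spec$size_meanlog, spec$size_sdlog)
    hgd <- is_adenoma & rbinom(n_les, 1, spec$p_hgd) == 1
    villous <- is_adenoma & rbinom(n_les, 1, spec$p_villous) == 1
    lesions <- data.frame(
      patient_id = pid, adenoma = is_adenoma, size_mm = size,
      size_class = lesion_size_class(size),
      high_grade = hgd, villous = villous,
      advanced = is_adenoma & (size >= 10 | hgd | villous)
    )

    any_by_patient <- function(flag) {
      out <- logical(n)
      if (any(flag)) out[unique(pid[flag])] <- TRUE
      as.integer(out)
    }
    cohort <- data.frame(
      patient_id = seq_len(n), center = centers, sex = sex, age = age,
      bmi = bmi, indication = indication, boston_score = boston,
      ccmea = ccmea, adenoma = adenoma, adenoma_count = adenoma_count,
      polyp_count = polyp_count,
      polyp = as.integer(polyp_count > 0),
      aden_diminutive = any_by_patient(lesions$adenoma & lesions$size_class == "diminutive"),
      aden_small = any_by_patient(lesions$adenoma & lesions$size_class == "small"),
      aden_large = any_by_patient(lesions$adenoma & lesions$size_class == "large"),
      advanced = any_by_patient(lesions$advanced),
      polyp_diminutive = any_by_patient(lesions$size_class == "diminutive"),
      polyp_small = any_by_patient(lesions$size_class == "small"),
      polyp_large = any_by_patient(lesions$size_class == "large"),
      p_adenoma = p
    )
    attr(cohort, "lesions") <- lesions
    attr(cohort, "spec") <- spec
    class(cohort) <- c("ccmea_cohort", "data.frame")
    cohort
  })
}

#' Generate a cohort with an explicit two-group effect
#'
#' Simulation harness for mixed-model parameter recovery: patients are
#' assigned to an exposure group (emulating qualified vs unqualified
#' colonoscopy) with a specified group log-odds ratio on a binary outcome
#' and a specified group log incidence-rate ratio on a count outcome,
#' plus a shared Gaussian center random intercept. Sex and indication are
#' drawn as in [generate_cohort()] but carry zero true effect, so adjusted
#' estimates should recover the group coefficients alone.
#'
#' @param n Number of patients.
#' @param n_centers Number of centers.
#' @param center_sd SD of the center random intercept.
#' @param log_or True group log-odds ratio for the binary outcome.
#' @param log_irr True group log incidence-rate ratio for the count outcome.
#' @param p0 Baseline outcome probability in the reference group.
#' @param rate0 Baseline mean count in the reference group.
#' @param p_group Probability of assignment to the exposed group.
#' @param seed Integer seed.
#' @return A data frame with columns `center`, `sex`, `indication`,
#'   `group` (0/1), `outcome` (0/1) and `count`.
#' @export
generate_grouped_cohort <- function(n = 510, n_centers = 3, center_sd = 0.3,
                                    log_or = log(8), log_irr = log(4),
                                    p0 = 0.14, rate0 = 1.3,
                                    p_group = 0.5, seed = 1L) {
  if (n_centers < 1) stop("n_centers must be >= 1", call. = FALSE)
  with_seed(seed, {
    centers <- factor(paste0("center", sample.int(n_centers, n, replace = TRUE)),
                      levels = paste0("center", seq_len(n_centers)))
    u <- rnorm(n_centers, 0, center_sd)
    u_pat <- u[as.integer(centers)]
    sex <- factor(ifelse(rbinom(n, 1, 0.47) == 1, "male", "female"),
                  levels = c("female", "male"))
    indication <- factor(
      sample(c("health examination", "diagnostic", "surveillance"), n,
             replace = TRUE, prob = c(0.218, 0.620, 0.162)),
      levels = c("health examination", "diagnostic", "surveillance")
    )
    group <- rbinom(n, 1, p_group)
    outcome <- rbinom(n, 1, plogis(qlogis(p0) + log_or * group + u_pat))
    count <- rpois(n, exp(log(rate0) + log_irr * group + u_pat))
    data.frame(center = centers, sex = sex, indication = indication,
               group = group, outcome = outcome, count = count)
  })
}
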