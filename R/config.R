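#' Fixed-effect and variance parameters of the SDT linear predictors
#'
#' Container for the coefficients of the two linear models of the hierarchical
#' equal-variance SDT model: one for truth discernment (d') and one for
#' response bias (c). Predictors are the standardized cognitive-reflection
#' score (`crt`), political concordance (`concord`), their interaction,
#' the standardized numeracy score (`num`), standardized age, and education
#' dummies relative to the reference level. Crossed random intercepts by
#' participant and by statement have half-Normal-scaled standard deviations.
#'
#' Derived quantities follow the usual SDT reading: overall belief is `-c`,
#' and partisan bias is minus the concordance coefficient of the c equation.
#'
#' @param d_intercept,c_intercept population intercepts of d' and c.
#' @param d_crt,c_crt effect of the standardized CRT score.
#' @param d_concord,c_concord effect of standardized political concordance.
#' @param d_concord_crt,c_concord_crt concordance-by-CRT interaction.
#' @param d_num,c_num effect of the standardized numeracy score.
#' @param d_age,c_age effect of standardized age.
#' @param d_edu,c_edu numeric vectors of education effects (non-reference
#'   levels, in level order).
#' @param sd_d_id,sd_c_id,sd_d_statement,sd_c_statement random-intercept
#'   standard deviations (must be non-negative).
#'
#' @return An object of class `sdt_coefficients` (a named list).
#' @export
#' @examples
#' sdt_coefficients(d_intercept = 1, c_concord = -0.66)
sdt_coefficients <- function(d_intercept = 1, d_crt = 0.1, d_concord = 0.08,
                             d_concord_crt = 0, d_num = 0, d_age = 0,
                             d_edu = c(0, 0, 0),
                             c_intercept = 0.2, c_crt = 0.1, c_concord = -0.66,
                             c_concord_crt = -0.1, c_num = 0, c_age = 0,
                             c_edu = c(0, 0, 0),
                             sd_d_id = 0.5, sd_c_id = 0.5,
                             sd_d_statement = 0.4, sd_c_statement = 0.4) {
  out <- list(
    d_intercept = d_intercept, d_crt = d_crt, d_concord = d_concord,
    d_concord_crt = d_concord_crt, d_num = d_num, d_age = d_age, d_edu = d_edu,
    c_intercept = c_intercept, c_crt = c_crt, c_concord = c_concord,
    c_concord_crt = c_concord_crt, c_num = c_num, c_age = c_age, c_edu = c_edu,
    sd_d_id = sd_d_id, sd_c_id = sd_c_id,
    sd_d_statement = sd_d_statement, sd_c_statement = sd_c_statement
  )
  sds <- c(sd_d_id, sd_c_id, sd_d_statement, sd_c_statement)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("random-intercept standard deviations must be finite and >= 0",
         call. = FALSE)
  }
  num <- unlist(out[setdiff(names(out), c("d_edu", "c_edu"))])
  if (any(!is.finite(num)) || any(!is.finite(d_edu)) || any(!is.finite(c_edu))) {
    stop("all SDT coefficients must be finite", call. = FALSE)
  }
  structure(out, class = "sdt_coefficients")
}

#' Parameters of the zero-one-inflated beta rating model
#'
#' The ZOIB mixture puts probability `alpha` on an exact 0/1 rating (1 with
#' probability `gamma` given a binary rating) and otherwise draws from a
#' Beta distribution reparameterized by mean `mu` and precision `phi`
#' (shapes `phi * mu` and `phi * (1 - mu)`). Used both to generate synthetic
#' slider ratings and as generating truth in recovery simulations. `mu` is
#' statement-specific at generation time (derived from target valences); the
#' value here is the population default used when none is supplied.
#'
#' @param mu mean of the beta branch, in (0, 1).
#' @param phi precision of the beta branch, > 0.
#' @param alpha probability of an exact 0/1 rating, in `[0, 1]`.
#' @param gamma probability that a binary rating is 1, in `[0, 1]`.
#' @param sd_mu_id,sd_phi_id,sd_alpha_id,sd_gamma_id by-participant
#'   random-intercept SDs on the logit (`mu`, `alpha`, `gamma`) or log
#'   (`phi`) scale.
#'
#' @return An object of class `zoib_parameters` (a named list).
#' @export
#' @examples
#' zoib_parameters(alpha = 0.1, gamma = 0.5, phi = 8)
zoib_parameters <- function(mu = 0.5, phi = 8, alpha = 0.1, gamma = 0.5,
                            sd_mu_id = 0.4, sd_phi_id = 0.3,
                            sd_alpha_id = 0.5, sd_gamma_id = 0.5) {
  check_zoib_par(mu, phi, alpha, gamma)
  sds <- c(sd_mu_id, sd_phi_id, sd_alpha_id, sd_gamma_id)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("ZOIB random-intercept SDs must be finite and >= 0", call. = FALSE)
  }
  structure(list(mu = mu, phi = phi, alpha = alpha, gamma = gamma,
                 sd_mu_id = sd_mu_id, sd_phi_id = sd_phi_id,
                 sd_alpha_id = sd_alpha_id, sd_gamma_id = sd_gamma_id),
            class = "zoib_parameters")
}

check_zoib_par <- function(mu, phi, alpha, gamma) {
  if (any(!is.finite(mu)) || any(mu <= 0) || any(mu >= 1)) {
    stop("mu must lie strictly in (0, 1)", call. = FALSE)
  }
  if (any(!is.finite(phi)) || any(phi <= 0)) {
    stop("phi must be > 0", call. = FALSE)
  }
  if (any(!is.finite(alpha)) || any(alpha < 0) || any(alpha > 1)) {
    stop("alpha must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(gamma)) || any(gamma < 0) || any(gamma > 1)) {
    stop("gamma must lie in [0, 1]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Configuration of a synthetic study
#'
#' Bundles everything the generator needs to produce a complete study with
#' known ground truth: sample sizes, the generating SDT and ZOIB parameters,
#' demographic and response-time distributions, and rates of deliberate
#' data-quality violations. Identical config + seed yields an identical study.
#'
#' Demographic defaults mirror the kind of online adult sample the task was
#' designed for: age from a truncated normal (mean 58, SD 12.2, floor 18),
#' four education levels with "high-school complete" as the modelling
#' reference, and a polarised main-app sample (pro-Left/pro-Right only) next
#' to a calibration sample that also contains non-polarised ("other") raters.
#' Response times are log-normal; the defaults put most detection responses
#' inside the (750 ms, 10 s) analysis window and most test-item responses
#' inside (1 s, 60 s).
#'
#' @param n_participants number of main-app participants.
#' @param n_calibration number of calibration-app raters.
#' @param n_statements number of statements (default 30).
#' @param prop_true fraction of statements that are actually true.
#' @param coefficients an [sdt_coefficients()] object (generating truth for
#'   the detection task).
#' @param zoib a [zoib_parameters()] object (generating truth for ratings).
#' @param valence_range half-open range of target statement valences; targets
#'   are an evenly spaced grid over `[-valence_range, valence_range]`.
#' @param age_mean,age_sd,age_min truncated-normal age model (years).
#' @param edu_levels education labels; `edu_ref` is the reference level.
#' @param edu_ref reference education level.
#' @param edu_probs sampling probabilities for `edu_levels`.
#' @param pol_probs_main named probabilities over political profiles for the
#'   main app (no "other" by default).
#' @param pol_probs_calibration ditto for the calibration app (includes
#'   "other").
#' @param crt_difficulty,num_difficulty per-item probabilities of a correct
#'   response (length gives the item count, default 3).
#' @param rt_detection,rt_calibration,rt_item `c(meanlog, sdlog)` of the
#'   log-normal RT model, in log-milliseconds.
#' @param violation_rates named list of fractions: `fast_trial` (detection and
#'   calibration trials forced under 750 ms), `insincere`, `nonpolarised`,
#'   `foreign` (participants given failing flags).
#' @param seed integer master seed for the study.
#'
#' @return An object of class `study_config`.
#' @export
#' @examples
#' cfg <- study_config(n_participants = 50, n_calibration = 40, seed = 1)
#' study <- simulate_study(cfg)
study_config <- function(n_participants = 300,
                         n_calibration = n_participants,
                         n_statements = 30,
                         prop_true = 0.5,
                         coefficients = sdt_coefficients(),
                         zoib = zoib_parameters(),
                         valence_range = 0.8,
                         age_mean = 58, age_sd = 12.2, age_min = 18,
                         edu_levels = c("primary", "high-school complete",
                                        "tertiary", "university"),
                         edu_ref = "high-school complete",
                         edu_probs = c(0.15, 0.35, 0.25, 0.25),
                         pol_probs_main = c("pro-Left" = 0.5,
                                            "pro-Right" = 0.5),
                         pol_probs_calibration = c("pro-Left" = 0.44,
                                                   "pro-Right" = 0.34,
                                                   "other" = 0.22),
                         crt_difficulty = c(0.35, 0.45, 0.55),
                         num_difficulty = c(0.5, 0.6, 0.7),
                         rt_detection = c(meanlog = log(3000), sdlog = 0.45),
                         rt_calibration = c(meanlog = log(3000), sdlog = 0.45),
                         rt_item = c(meanlog = log(9000), sdlog = 0.5),
                         violation_rates = list(fast_trial = 0, insincere = 0,
                                                nonpolarised = 0, foreign = 0),
                         seed = 1L) {
  if (n_participants < 0 || n_calibration < 0 || n_statements < 0) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (prop_true < 0 || prop_true > 1) {
    stop("prop_true must lie in [0, 1]", call. = FALSE)
  }
  if (!inherits(coefficients, "sdt_coefficients")) {
    stop("`coefficients` must be an sdt_coefficients() object", call. = FALSE)
  }
  if (!inherits(zoib, "zoib_parameters")) {
    stop("`zoib` must be a zoib_parameters() object", call. = FALSE)
  }
  if (valence_range <= 0 || valence_range > 1) {
    stop("valence_range must lie in (0, 1]", call. = FALSE)
  }
  if (!edu_ref %in% edu_levels) {
    stop("edu_ref must be one of edu_levels", call. = FALSE)
  }
  if (length(edu_probs) != length(edu_levels)) {
    stop("edu_probs must match edu_levels in length", call. = FALSE)
  }
  if (length(coefficients$d_edu) != length(edu_levels) - 1L ||
      length(coefficients$c_edu) != length(edu_levels) - 1L) {
    stop("education effect vectors must have length(edu_levels) - 1 entries",
         call. = FALSE)
  }
  if (age_sd <= 0 || age_min <= 0) {
    stop("age distribution parameters must be positive", call. = FALSE)
  }
  rates <- unlist(violation_rates)
  if (any(rates < 0) || any(rates > 1)) {
    stop("violation rates must lie in [0, 1]", call. = FALSE)
  }
  for (rt in list(rt_detection, rt_calibration, rt_item)) {
    if (length(rt) != 2 || any(!is.finite(rt)) || rt[[2]] <= 0) {
      stop("RT models must be c(meanlog, sdlog) with sdlog > 0", call. = FALSE)
    }
  }
  structure(list(
    n_participants = as.integer(n_participants),
    n_calibration = as.integer(n_calibration),
    n_statements = as.integer(n_statements),
    prop_true = prop_true,
    coefficients = coefficients, zoib = zoib,
    valence_range = valence_range,
    age_mean = age_mean, age_sd = age_sd, age_min = age_min,
    edu_levels = edu_levels, edu_ref = edu_ref, edu_probs = edu_probs,
    pol_probs_main = pol_probs_main,
    pol_probs_calibration = pol_probs_calibration,
    crt_difficulty = crt_difficulty, num_difficulty = num_difficulty,
    rt_detection = rt_detection, rt_calibration = rt_calibration,
    rt_item = rt_item,
    violation_rates = violation_rates,
    seed = as.integer(seed)
  ), class = "study_config")
}

# Deterministic sub-seed for a named substream of a master seed.
# Keeps values in [0, 2^31): R integers are 32-bit.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 1009) %% 2147483647)
}
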