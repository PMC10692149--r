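#' Probability of a "true" response under equal-variance SDT
#'
#' The statement-veracity judgement is a Bernoulli draw with probability
#' `pnorm(dprime * is_true - c)`: the probit link maps the decision variable
#' (signal separation d' switched on for actually-true statements, minus the
#' response criterion c) to a probability.
#'
#' @param dprime truth discernment d'.
#' @param is_true ground-truth veracity (0/1).
#' @param c response criterion (positive = sceptical; overall belief is `-c`).
#' @return Probability of responding "true", in (0, 1) for finite inputs.
#' @export
#' @examples
#' response_probability(0, 0, 0)       # 0.5
#' response_probability(1.5, 1, 0)     # pnorm(1.5)
response_probability <- function(dprime, is_true, c) {
  if (any(!is_true %in% c(0, 1))) {
    stop("is_true must be 0 or 1", call. = FALSE)
  }
  stats::pnorm(dprime * is_true - c)
}

# truncated normal (lower bound only), simple rejection-free draw
rtnorm_lower <- function(n, mean, sd, lower) {
  p_lo <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n, p_lo, 1)
  stats::qnorm(pmin(u, 1 - 1e-12), mean, sd)
}

sample_levels <- function(n, probs) {
  if (n == 0) return(character(0))
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# z-score returning 0s when the sd is degenerate (tiny samples)
safe_z <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

make_participants <- function(n, config, id_prefix, pol_probs, with_items) {
  k_crt <- length(config$crt_difficulty)
  k_num <- length(config$num_difficulty)
  tb <- tibble::tibble(
    participant_id = sprintf("%s%04d", id_prefix, seq_len(n)),
    age = round(rtnorm_lower(n, config$age_mean, config$age_sd,
                             config$age_min)),
    sex = sample_levels(n, c(female = 0.49, male = 0.49, other = 0.02)),
    edu = sample(config$edu_levels, n, replace = TRUE,
                 prob = config$edu_probs),
    pol = sample_levels(n, pol_probs),
    nationality_ok = rep(TRUE, n),
    sincere = rep(TRUE, n)
  )
  if (with_items) {
    for (j in seq_len(k_crt)) {
      tb[[paste0("crt_correct_", j)]] <-
        stats::rbinom(n, 1L, config$crt_difficulty[j])
      tb[[paste0("crt_rt_", j)]] <-
        stats::rlnorm(n, config$rt_item[[1]], config$rt_item[[2]])
    }
    for (j in seq_len(k_num)) {
      tb[[paste0("num_correct_", j)]] <-
        stats::rbinom(n, 1L, config$num_difficulty[j])
      tb[[paste0("num_rt_", j)]] <-
        stats::rlnorm(n, config$rt_item[[1]], config$rt_item[[2]])
    }
  }
  tb
}

#' Generate a complete synthetic study
#'
#' Produces statements, main-app participants, calibration raters, detection
#' trials and calibration ratings from the generating parameters in a
#' [study_config()], and retains all latent ground truth (statement valences,
#' random intercepts, standardization constants) for recovery testing.
#'
#' Every main-app participant judges every statement once (within-subjects,
#' presentation order shuffled per participant); every calibration rater
#' rates every statement on both the pro-Left and pro-Right slider. The
#' detection response is a Bernoulli draw with probability
#' [response_probability()] at the participant/statement linear predictors;
#' ratings are ZOIB draws whose statement-level means are set so that the
#' balanced-marginal expected congruence difference equals the target
#' valence. If any violation rate in the config is positive,
#' [inject_quality_violations()] is applied before returning.
#'
#' @param config a [study_config()].
#' @return An object of class `sdt_study`: a list with tibbles `statements`,
#'   `participants`, `calibration_participants`, `detection_trials`,
#'   `calibration_trials`, plus `truth` (generating parameters and latent
#'   effects) and, when violations were injected, `injection_log`.
#' @export
#' @examples
#' study <- simulate_study(study_config(n_participants = 20,
#'                                      n_calibration = 15, seed = 42))
#' nrow(study$detection_trials)  # 20 x 30
simulate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  ns <- config$n_statements
  np <- config$n_participants
  nc <- config$n_calibration
  cf <- config$coefficients
  zp <- config$zoib

  # --- statements ------------------------------------------------------
  set.seed(derive_seed(config$seed, "statements"))
  n_true <- round(ns * config$prop_true)
  is_true <- sample(c(rep(1L, n_true), rep(0L, ns - n_true)))
  valence <- if (ns > 1) {
    sample(seq(-config$valence_range, config$valence_range, length.out = ns))
  } else {
    rep(0, ns)
  }
  statements <- tibble::tibble(
    statement_id = sprintf("s%03d", seq_len(ns)),
    is_true = is_true,
    true_valence = valence,
    d_intercept = stats::rnorm(ns, 0, cf$sd_d_statement),
    c_intercept = stats::rnorm(ns, 0, cf$sd_c_statement)
  )

  # statement-level beta means targeting the valences
  target_R <- 0.5 + valence / 2
  target_L <- 0.5 - valence / 2
  if (zp$alpha < 1) {
    mu_R <- (target_R - zp$alpha * zp$gamma) / (1 - zp$alpha)
    mu_L <- (target_L - zp$alpha * zp$gamma) / (1 - zp$alpha)
    if (ns > 0 && (any(mu_R <= 0 | mu_R >= 1) || any(mu_L <= 0 | mu_L >= 1))) {
      stop("target valences are unreachable under the ZOIB alpha/gamma; ",
           "reduce valence_range or alpha", call. = FALSE)
    }
  } else {
    mu_R <- mu_L <- rep(0.5, ns)
  }

  # --- participants ----------------------------------------------------
  set.seed(derive_seed(config$seed, "participants_main"))
  participants <- make_participants(np, config, "p", config$pol_probs_main,
                                    with_items = TRUE)
  main_effects <- tibble::tibble(
    participant_id = participants$participant_id,
    d_intercept = stats::rnorm(np, 0, cf$sd_d_id),
    c_intercept = stats::rnorm(np, 0, cf$sd_c_id)
  )

  set.seed(derive_seed(config$seed, "participants_calibration"))
  cal_participants <- make_participants(nc, config, "c",
                                        config$pol_probs_calibration,
                                        with_items = FALSE)
  cal_effects <- tibble::tibble(
    participant_id = cal_participants$participant_id,
    mu_id_L = stats::rnorm(nc, 0, zp$sd_mu_id),
    mu_id_R = stats::rnorm(nc, 0, zp$sd_mu_id),
    alpha_id_L = stats::rnorm(nc, 0, zp$sd_alpha_id),
    alpha_id_R = stats::rnorm(nc, 0, zp$sd_alpha_id),
    gamma_id_L = stats::rnorm(nc, 0, zp$sd_gamma_id),
    gamma_id_R = stats::rnorm(nc, 0, zp$sd_gamma_id),
    phi_id_L = stats::rnorm(nc, 0, zp$sd_phi_id),
    phi_id_R = stats::rnorm(nc, 0, zp$sd_phi_id)
  )

  # --- detection trials ------------------------------------------------
  set.seed(derive_seed(config$seed, "detection"))
  k_crt <- length(config$crt_difficulty)
  k_num <- length(config$num_difficulty)
  crt_score <- if (np > 0) {
    rowSums(as.matrix(participants[paste0("crt_correct_", seq_len(k_crt))]))
  } else numeric(0)
  num_score <- if (np > 0) {
    rowSums(as.matrix(participants[paste0("num_correct_", seq_len(k_num))]))
  } else numeric(0)
  scal <- list(crt = c(mean = mean(crt_score), sd = stats::sd(crt_score)),
               num = c(mean = mean(num_score), sd = stats::sd(num_score)),
               age = c(mean = mean(participants$age),
                       sd = stats::sd(participants$age)))

  grid <- tidyr::expand_grid(
    participant_id = participants$participant_id,
    statement_id = statements$statement_id
  )
  if (np > 0 && ns > 0) {
    pidx <- match(grid$participant_id, participants$participant_id)
    sidx <- match(grid$statement_id, statements$statement_id)
    concord_raw <- ifelse(participants$pol[pidx] == "pro-Right", 1, -1) *
      statements$true_valence[sidx]
    pred <- tibble::tibble(
      is_true = statements$is_true[sidx],
      crt_z = safe_z(crt_score)[pidx],
      num_z = safe_z(num_score)[pidx],
      age_z = safe_z(participants$age)[pidx],
      pol_concord_z = safe_z(concord_raw),
      edu = participants$edu[pidx],
      d_offset = main_effects$d_intercept[pidx] +
        statements$d_intercept[sidx],
      c_offset = main_effects$c_intercept[pidx] + statements$c_intercept[sidx]
    )
    lp <- linear_predictors(pred, cf, edu_levels = config$edu_levels,
                            edu_ref = config$edu_ref)
    p_true <- response_probability(lp$dprime, pred$is_true, lp$c)
    detection_trials <- grid |>
      dplyr::mutate(
        say_true = stats::rbinom(dplyr::n(), 1L, p_true),
        rt_ms = stats::rlnorm(dplyr::n(), config$rt_detection[[1]],
                              config$rt_detection[[2]])
      ) |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::slice_sample(prop = 1) |>
      dplyr::mutate(position = dplyr::row_number()) |>
      dplyr::ungroup()
  } else {
    detection_trials <- tibble::tibble(
      participant_id = character(0), statement_id = character(0),
      say_true = integer(0), rt_ms = numeric(0), position = integer(0)
    )
  }

  # --- calibration trials ----------------------------------------------
  set.seed(derive_seed(config$seed, "calibration"))
  if (nc > 0 && ns > 0) {
    cgrid <- tidyr::expand_grid(
      participant_id = cal_participants$participant_id,
      statement_id = statements$statement_id
    )
    pidx <- match(cgrid$participant_id, cal_participants$participant_id)
    sidx <- match(cgrid$statement_id, statements$statement_id)
    draw_dv <- function(mu_stmt, mu_id, alpha_id, gamma_id, phi_id) {
      mu <- stats::plogis(stats::qlogis(mu_stmt[sidx]) + mu_id[pidx])
      al <- stats::plogis(stats::qlogis(zp$alpha) + alpha_id[pidx])
      ga <- stats::plogis(stats::qlogis(zp$gamma) + gamma_id[pidx])
      ph <- exp(log(zp$phi) + phi_id[pidx])
      rzoib(nrow(cgrid), mu, ph, al, ga)
    }
    calibration_trials <- cgrid |>
      dplyr::mutate(
        cong_left = draw_dv(mu_L, cal_effects$mu_id_L, cal_effects$alpha_id_L,
                            cal_effects$gamma_id_L, cal_effects$phi_id_L),
        cong_right = draw_dv(mu_R, cal_effects$mu_id_R,
                             cal_effects$alpha_id_R, cal_effects$gamma_id_R,
                             cal_effects$phi_id_R),
        rt_ms = stats::rlnorm(dplyr::n(), config$rt_calibration[[1]],
                              config$rt_calibration[[2]])
      ) |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::slice_sample(prop = 1) |>
      dplyr::mutate(position = dplyr::row_number()) |>
      dplyr::ungroup()
  } else {
    calibration_trials <- tibble::tibble(
      participant_id = character(0), statement_id = character(0),
      cong_left = numeric(0), cong_right = numeric(0), rt_ms = numeric(0),
      position = integer(0)
    )
  }

  study <- structure(list(
    statements = statements,
    participants = participants,
    calibration_participants = cal_participants,
    detection_trials = detection_trials,
    calibration_trials = calibration_trials,
    truth = list(config = config,
                 main_effects = main_effects,
                 calibration_effects = cal_effects,
                 mu_L = mu_L, mu_R = mu_R,
                 scaling = scal)
  ), class = "sdt_study")

  if (any(unlist(config$violation_rates) > 0)) {
    study <- inject_quality_violations(study, config$violation_rates,
                                       seed = derive_seed(config$seed,
                                                          "violations"))
  }
  study
}

#' @export
print.sdt_study <- function(x, ...) {
  cat("<sdt_study>\n")
  cat("  statements:            ", nrow(x$statements), "\n")
  cat("  main participants:     ", nrow(x$participants), "\n")
  cat("  calibration raters:    ", nrow(x$calibration_participants), "\n")
  cat("  detection trials:      ", nrow(x$detection_trials), "\n")
  cat("  calibration ratings:   ", nrow(x$calibration_trials), "\n")
  invisible(x)
}

#' Simulate detection-task responses at given predictors
#'
#' Draws binary "true"/"false" judgements and response times for a table of
#' trial-level predictors, under a fixed set of generating coefficients. This
#' is the single-trial generative core of the detection task exposed
#' directly, used for Monte-Carlo checks against [response_probability()].
#'
#' @param data tibble with column `is_true` and any of `crt_z`, `num_z`,
#'   `age_z`, `pol_concord_z`, `edu`, `d_offset`, `c_offset` (missing
#'   predictors are treated as 0 / reference).
#' @param coefficients an [sdt_coefficients()].
#' @param seed optional integer seed.
#' @param rt `c(meanlog, sdlog)` of the log-normal RT model (ms).
#' @param edu_levels,edu_ref education coding (defaults: no education terms).
#' @return `data` with columns `dprime`, `c`, `p_true`, `say_true`, `rt_ms`.
#' @export
simulate_detection_trials <- function(data, coefficients, seed = NULL,
                                      rt = c(meanlog = log(3000),
                                             sdlog = 0.45),
                                      edu_levels = NULL, edu_ref = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lp <- linear_predictors(data, coefficients, edu_levels = edu_levels,
                          edu_ref = edu_ref)
  p <- response_probability(lp$dprime, data$is_true, lp$c)
  dplyr::mutate(data,
    dprime = lp$dprime, c = lp$c, p_true = p,
    say_true = stats::rbinom(dplyr::n(), 1L, p),
    rt_ms = stats::rlnorm(dplyr::n(), rt[[1]], rt[[2]])
  )
}

#' Inject data-quality violations into a synthetic study
#'
#' Marks random fractions of trials and participants with the kinds of
#' quality problems the registered inclusion criteria are designed to catch:
#' impulsively fast trials (RT forced below the 750 ms floor), insincere
#' participants, non-polarised main-app participants, and participants
#' failing the nationality question.
#'
#' @param study an `sdt_study`.
#' @param violation_rates named list with fractions `fast_trial`,
#'   `insincere`, `nonpolarised`, `foreign` (all in `[0, 1]`; missing
#'   entries default to 0).
#' @param seed optional integer seed.
#' @return The modified study, with an `injection_log` tibble recording what
#'   was changed. All rates 0 returns the study unchanged.
#' @export
inject_quality_violations <- function(study, violation_rates, seed = NULL) {
  stopifnot(inherits(study, "sdt_study"))
  rates <- utils::modifyList(
    list(fast_trial = 0, insincere = 0, nonpolarised = 0, foreign = 0),
    as.list(violation_rates)
  )
  if (any(unlist(rates) < 0) || any(unlist(rates) > 1)) {
    stop("violation rates must lie in [0, 1]", call. = FALSE)
  }
  if (all(unlist(rates) == 0)) {
    study$injection_log <- tibble::tibble(action = character(0),
                                          table = character(0),
                                          n = integer(0))
    return(study)
  }
  if (!is.null(seed)) set.seed(seed)
  log <- list()
  mark_rows <- function(n_total, rate) {
    sample(n_total, size = floor(rate * n_total))
  }
  if (rates$fast_trial > 0) {
    for (tab in c("detection_trials", "calibration_trials")) {
      idx <- mark_rows(nrow(study[[tab]]), rates$fast_trial)
      study[[tab]]$rt_ms[idx] <- stats::runif(length(idx), 200, 740)
      log[[length(log) + 1]] <- tibble::tibble(action = "fast_trial",
                                               table = tab,
                                               n = length(idx))
    }
  }
  flag_participants <- function(study, rate, action, fn) {
    for (tab in c("participants", "calibration_participants")) {
      idx <- mark_rows(nrow(study[[tab]]), rate)
      if (action == "nonpolarised" && tab == "calibration_participants") next
      study[[tab]] <- fn(study[[tab]], idx)
      log[[length(log) + 1]] <<- tibble::tibble(action = action, table = tab,
                                                n = length(idx))
    }
    study
  }
  if (rates$insincere > 0) {
    study <- flag_participants(study, rates$insincere, "insincere",
                               function(tb, i) { tb$sincere[i] <- FALSE; tb })
  }
  if (rates$nonpolarised > 0) {
    study <- flag_participants(study, rates$nonpolarised, "nonpolarised",
                               function(tb, i) { tb$pol[i] <- "other"; tb })
  }
  if (rates$foreign > 0) {
    study <- flag_participants(study, rates$foreign, "foreign",
                               function(tb, i) {
                                 tb$nationality_ok[i] <- FALSE; tb
                               })
  }
  study$injection_log <- dplyr::bind_rows(log)
  study
}
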