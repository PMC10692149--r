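# map between generating-coefficient fields and posterior parameter names
coef_name_map <- function() {
  c(d_Intercept = "d_intercept", d_crt_score = "d_crt",
    d_pol_concord = "d_concord", `d_pol_concord:crt_score` = "d_concord_crt",
    d_num_score = "d_num", d_age = "d_age",
    c_Intercept = "c_intercept", c_crt_score = "c_crt",
    c_pol_concord = "c_concord", `c_pol_concord:crt_score` = "c_concord_crt",
    c_num_score = "c_num", c_age = "c_age",
    sd_d_id = "sd_d_id", sd_c_id = "sd_c_id",
    sd_d_statement = "sd_d_statement", sd_c_statement = "sd_c_statement")
}

simulate_and_fit <- function(coefficients, n_participants, seed, controls,
                             control, config_args = list()) {
  args <- utils::modifyList(
    list(n_participants = n_participants, n_calibration = 0L,
         coefficients = coefficients, seed = seed),
    config_args
  )
  study <- simulate_study(do.call(study_config, args))
  # desk-scale recovery uses the generator's true valences as the
  # calibration product, isolating the detection-model stage
  valence <- tibble::tibble(statement_id = study$statements$statement_id,
                            valence = study$statements$true_valence)
  inc <- apply_participant_inclusion(study, "main")
  pt <- build_predictor_table(study, valence, included = inc$included)
  control$seed <- derive_seed(seed, "fit")
  fit_sdt(pt, controls = controls, control = control)
}

#' Parameter-recovery simulation for the SDT model
#'
#' Generates replicate synthetic studies from fixed, known coefficients,
#' pushes each through preprocessing and the full Bayesian fit, and compares
#' the posterior to the generating truth: per-parameter bias and whether the
#' truth falls inside the 95% quantile interval. A successful recovery
#' (coverage near nominal, small bias) validates the modelling strategy
#' before it is let loose on real data.
#'
#' @param coefficients generating [sdt_coefficients()].
#' @param n_participants participants per replicate study.
#' @param replicates number of replicate studies.
#' @param seed master seed; replicate seeds are derived from it.
#' @param parameters posterior parameter names to track (default: the
#'   registered coefficients plus both intercepts).
#' @param controls fit with age/education controls?
#' @param control an [sdt_control()]; the default is a reduced desk-scale
#'   sampler (2 chains x 600 retained draws).
#' @param config_args named list of [study_config()] overrides.
#' @return An object of class `recovery_report`: `results` (one row per
#'   replicate x parameter: true value, posterior median, bias, `in_ci`),
#'   `summary` (per-parameter coverage and mean bias over converged
#'   replicates), `excluded` (replicates failing convergence diagnostics).
#' @export
run_parameter_recovery <- function(coefficients = sdt_coefficients(),
                                   n_participants = 200,
                                   replicates = 10,
                                   seed = 1L,
                                   parameters = c("d_Intercept",
                                                  "c_Intercept",
                                                  "d_crt_score",
                                                  "c_crt_score",
                                                  "c_pol_concord",
                                                  "c_pol_concord:crt_score"),
                                   controls = TRUE,
                                   control = sdt_control(chains = 2,
                                                         iter = 600,
                                                         warmup = 300),
                                   config_args = list()) {
  stopifnot(replicates >= 1)
  nm <- coef_name_map()
  bad <- setdiff(parameters, names(nm))
  if (length(bad)) {
    stop("unknown parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  truth <- vapply(parameters, function(p) coefficients[[nm[[p]]]],
                  numeric(1))
  results <- purrr::map_dfr(seq_len(replicates), function(r) {
    fit <- suppressWarnings(
      simulate_and_fit(coefficients, n_participants,
                       derive_seed(seed, paste0("rep", r)),
                       controls, control, config_args))
    # replicate-level gate: diagnostics of the parameters being recovered
    # (the global flag over every nuisance parameter is recorded alongside)
    rh <- fit$diagnostics$rhat[match(parameters,
                                     fit$diagnostics$parameter)]
    ok <- !any(rh > 1.1, na.rm = TRUE)
    purrr::map_dfr(parameters, function(p) {
      s <- summarize_coefficient(fit$draws[[p]])
      tibble::tibble(replicate = r, parameter = p,
                     true = truth[[p]], median = s$median,
                     bias = s$median - truth[[p]],
                     ci_low = s$ci_low, ci_high = s$ci_high,
                     in_ci = truth[[p]] >= s$ci_low &
                       truth[[p]] <= s$ci_high,
                     converged = ok,
                     converged_all = fit$converged)
    })
  })
  excluded <- unique(results$replicate[!results$converged])
  if (length(excluded)) {
    warning(length(excluded),
            " replicate(s) failed convergence diagnostics and are excluded",
            " from the aggregates", call. = FALSE)
  }
  ok <- dplyr::filter(results, .data$converged)
  summary <- ok |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(coverage = mean(.data$in_ci),
                     mean_bias = mean(.data$bias),
                     n_replicates = dplyr::n(), .groups = "drop")
  structure(list(results = results, summary = summary,
                 excluded = excluded, n_participants = n_participants,
                 replicates = replicates, seed = seed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>", x$replicates, "replicates at n =",
      x$n_participants, "\n")
  print(x$summary)
  invisible(x)
}

#' Bayes-factor design analysis over a sample-size grid
#'
#' The registered sample-size rule: simulate data under the hypothesized
#' effects, fit the model, compute the Savage-Dickey `BF10` for each of the
#' four registered coefficients, and grow N until every `BF10` clears the
#' threshold (10 by default).
#'
#' @param coefficients generating [sdt_coefficients()] (the hypothesized
#'   effects).
#' @param sample_sizes integer grid of participant counts.
#' @param replicates replicate studies per grid point.
#' @param bf_threshold evidence threshold.
#' @param seed master seed.
#' @param parameters coefficients to test (default: the four registered
#'   ones).
#' @param controls,control,config_args as in [run_parameter_recovery()].
#' @return An object of class `power_report`: `results` (n, replicate,
#'   parameter, bf10), `summary` (per n x parameter: median BF and the
#'   fraction of replicates clearing the threshold), and `smallest_n` (the
#'   smallest grid N whose median BF clears the threshold for every tested
#'   coefficient; `NA` if none does).
#' @export
run_power_analysis <- function(coefficients = sdt_coefficients(),
                               sample_sizes = c(100, 200, 400),
                               replicates = 3,
                               bf_threshold = 10,
                               seed = 1L,
                               parameters = hypothesis_map()$parameter,
                               controls = TRUE,
                               control = sdt_control(chains = 2,
                                                     iter = 600,
                                                     warmup = 300),
                               config_args = list()) {
  stopifnot(length(sample_sizes) >= 1, replicates >= 1)
  results <- purrr::map_dfr(sample_sizes, function(n) {
    purrr::map_dfr(seq_len(replicates), function(r) {
      fit <- suppressWarnings(
        simulate_and_fit(coefficients, n,
                         derive_seed(seed, paste0("n", n, "rep", r)),
                         controls, control, config_args))
      prior_sd <- fit$priors$sd_fixed
      rh <- fit$diagnostics$rhat[match(parameters,
                                       fit$diagnostics$parameter)]
      ok <- !any(rh > 1.1, na.rm = TRUE)
      purrr::map_dfr(parameters, function(p) {
        tibble::tibble(
          n = n, replicate = r, parameter = p,
          bf10 = as.numeric(savage_dickey_bf10(
            fit$draws[[p]], function(x) stats::dnorm(x, 0, prior_sd))),
          converged = ok,
          converged_all = fit$converged
        )
      })
    })
  })
  summary <- results |>
    dplyr::filter(.data$converged) |>
    dplyr::group_by(.data$n, .data$parameter) |>
    dplyr::summarise(median_bf10 = stats::median(.data$bf10),
                     frac_exceeding = mean(.data$bf10 >= bf_threshold),
                     .groups = "drop")
  per_n <- summary |>
    dplyr::group_by(.data$n) |>
    dplyr::summarise(all_pass = all(.data$median_bf10 >= bf_threshold),
                     .groups = "drop")
  smallest_n <- if (any(per_n$all_pass)) min(per_n$n[per_n$all_pass]) else
    NA_integer_
  structure(list(results = results, summary = summary,
                 smallest_n = smallest_n, bf_threshold = bf_threshold,
                 seed = seed),
            class = "power_report")
}

#' @export
print.power_report <- function(x, ...) {
  cat("<power_report> BF threshold", x$bf_threshold, "| smallest passing N:",
      x$smallest_n, "\n")
  print(x$summary)
  invisible(x)
}
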