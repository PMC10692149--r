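#' Response-time filter for trial tables
#'
#' Keeps trials whose response time is strictly above `lower_ms` and, when an
#' upper bound is given, strictly below `upper_ms`. Detection and
#' calibration-rating trials use a 750 ms floor with no trial-level ceiling;
#' cognitive-test items use the (1 s, 60 s) window.
#'
#' @param trials tibble with an `rt_ms` column.
#' @param lower_ms lower bound in ms (strict).
#' @param upper_ms optional upper bound in ms (strict); `NULL` for none.
#' @return List with `kept` (filtered tibble) and `removed` (count).
#' @export
#' @examples
#' tr <- tibble::tibble(rt_ms = c(500, 800, 12000))
#' filter_trials(tr, 750)$removed         # 1
#' filter_trials(tr, 750, 10000)$removed  # 2
filter_trials <- function(trials, lower_ms = 750, upper_ms = NULL) {
  if (lower_ms <= 0 || (!is.null(upper_ms) && upper_ms <= lower_ms)) {
    stop("bounds must be positive with lower < upper", call. = FALSE)
  }
  keep <- trials$rt_ms > lower_ms
  if (!is.null(upper_ms)) keep <- keep & trials$rt_ms < upper_ms
  keep[is.na(keep)] <- FALSE
  list(kept = trials[keep, , drop = FALSE], removed = sum(!keep))
}

#' Score a timed cognitive test
#'
#' The score is the number of correct responses among items answered inside
#' the response-time window; items outside the window are discarded and
#' contribute nothing.
#'
#' @param item_correct 0/1 correctness flags.
#' @param item_rt_ms per-item response times (ms), aligned with
#'   `item_correct`.
#' @param window `c(lower, upper)` in ms, both strict.
#' @return Integer score.
#' @export
#' @examples
#' score_test(c(1, 1, 1), c(5000, 500, 70000))  # middle and last discarded
score_test <- function(item_correct, item_rt_ms,
                       window = c(1000, 60000)) {
  stopifnot(length(item_correct) == length(item_rt_ms))
  valid <- item_rt_ms > window[1] & item_rt_ms < window[2]
  valid[is.na(valid)] <- FALSE
  sum(item_correct[valid] == 1, na.rm = TRUE)
}

#' Standardize a numeric variable
#'
#' Centers and scales with the sample standard deviation, returning the
#' constants needed for the inverse mapping.
#'
#' @param values numeric vector with at least two distinct values.
#' @return List with `z`, `mean`, `sd`.
#' @export
#' @examples
#' standardize(c(1, 2, 3))$z  # -1 0 1
standardize <- function(values) {
  m <- mean(values)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop("cannot standardize a constant variable", call. = FALSE)
  }
  list(z = (values - m) / s, mean = m, sd = s)
}

#' Political concordance of a statement for a participant
#'
#' Concordance is the statement's political valence seen from the
#' participant's side: the valence itself for pro-Right participants and
#' minus the valence for pro-Left participants. It is undefined for
#' non-polarised profiles, which are excluded from the main model.
#'
#' @param valence statement political valence in `[-1, 1]`.
#' @param pol political profile, `"pro-Left"` or `"pro-Right"` (vectorized).
#' @return Numeric concordance values.
#' @export
#' @examples
#' political_concordance(0.4, "pro-Right")  #  0.4
#' political_concordance(0.4, "pro-Left")   # -0.4
political_concordance <- function(valence, pol) {
  if (any(!pol %in% c("pro-Left", "pro-Right"))) {
    stop("political concordance is undefined for non-polarised profiles",
         call. = FALSE)
  }
  ifelse(pol == "pro-Right", 1, -1) * valence
}

item_matrix <- function(participants, prefix, what) {
  cols <- grep(sprintf("^%s_%s_\\d+$", prefix, what),
               names(participants), value = TRUE)
  as.matrix(participants[cols])
}

#' Apply the registered participant-inclusion criteria
#'
#' Evaluates, per participant, every inclusion criterion of the given app and
#' returns the identifiers passing all of them together with a full
#' per-criterion log.
#'
#' Main-app criteria: passing nationality; sincerity; a polarised political
#' profile; detection-trial RT strictly inside (750 ms, 10 s) on at least 75%
#' of the presented trials; CRT item RT strictly inside (1 s, 60 s) on at
#' least 2 of the 3 items; likewise for the numeracy items. Calibration-app
#' criteria: nationality, sincerity, and rating RT above 750 ms on at least
#' 75% of rating trials (no polarisation requirement). The 75% threshold is
#' inclusive (exactly 75% passes).
#'
#' @param study an `sdt_study` (or a list with compatible tables).
#' @param app_kind `"main"` or `"calibration"`.
#' @param rt_bounds detection/rating RT window, ms (upper bound only used for
#'   the main app).
#' @param item_bounds cognitive-test item RT window, ms.
#' @param min_rt_fraction minimum fraction of in-window trials.
#' @param min_valid_items minimum number of in-window test items.
#' @return List with `included` (character ids) and `log` (one row per
#'   participant with per-criterion pass flags and counts).
#' @export
apply_participant_inclusion <- function(study,
                                        app_kind = c("main", "calibration"),
                                        rt_bounds = c(750, 10000),
                                        item_bounds = c(1000, 60000),
                                        min_rt_fraction = 0.75,
                                        min_valid_items = 2L) {
  app_kind <- match.arg(app_kind)
  if (app_kind == "main") {
    participants <- study$participants
    trials <- study$detection_trials
  } else {
    participants <- study$calibration_participants
    trials <- study$calibration_trials
  }
  n_stmt <- nrow(study$statements)

  ok_window <- if (app_kind == "main") {
    trials$rt_ms > rt_bounds[1] & trials$rt_ms < rt_bounds[2]
  } else {
    trials$rt_ms > rt_bounds[1]
  }
  per_p <- tibble::tibble(participant_id = trials$participant_id,
                          ok = ok_window) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(n_trials = dplyr::n(), n_ok = sum(.data$ok),
                     .groups = "drop")

  log <- participants |>
    dplyr::select("participant_id", "nationality_ok", "sincere",
                  dplyr::any_of("pol")) |>
    dplyr::left_join(per_p, by = "participant_id") |>
    dplyr::mutate(
      n_trials = dplyr::coalesce(.data$n_trials, 0L),
      n_ok = dplyr::coalesce(.data$n_ok, 0L),
      # fraction over trials presented; participants with no trials fail
      pass_nationality = .data$nationality_ok,
      pass_sincerity = .data$sincere,
      pass_rt = .data$n_trials > 0 &
        .data$n_ok / pmax(.data$n_trials, n_stmt, 1) >= min_rt_fraction
    )

  if (app_kind == "main") {
    crt_ok <- rowSums(item_matrix(participants, "crt", "rt") > item_bounds[1] &
                        item_matrix(participants, "crt", "rt") < item_bounds[2])
    num_ok <- rowSums(item_matrix(participants, "num", "rt") > item_bounds[1] &
                        item_matrix(participants, "num", "rt") < item_bounds[2])
    log <- log |>
      dplyr::mutate(
        pass_polarised = .data$pol %in% c("pro-Left", "pro-Right"),
        n_crt_valid = crt_ok[match(.data$participant_id,
                                   participants$participant_id)],
        n_num_valid = num_ok[match(.data$participant_id,
                                   participants$participant_id)],
        pass_crt_items = .data$n_crt_valid >= min_valid_items,
        pass_num_items = .data$n_num_valid >= min_valid_items,
        included = .data$pass_nationality & .data$pass_sincerity &
          .data$pass_polarised & .data$pass_rt & .data$pass_crt_items &
          .data$pass_num_items
      )
  } else {
    log <- dplyr::mutate(log, included = .data$pass_nationality &
                           .data$pass_sincerity & .data$pass_rt)
  }
  list(included = log$participant_id[log$included], log = log)
}

#' Build the trial-level predictor table for the SDT model
#'
#' Joins RT-filtered detection trials of included participants with the
#' standardized participant covariates and trial-level political
#' concordance. CRT, numeracy and age are standardized over the retained
#' participants; concordance over the retained trials. The standardization
#' constants are attached as the `"scaling"` attribute for inverse mapping.
#'
#' @param study an `sdt_study`.
#' @param valence tibble with `statement_id` and `valence` (e.g. from
#'   [valence_table()], or the generator's ground truth).
#' @param included character vector of included participant ids (default:
#'   computed by [apply_participant_inclusion()]).
#' @param rt_bounds trial RT filter bounds, ms (lower strict; no upper bound
#'   at the trial level).
#' @param item_bounds item RT window for test scoring, ms.
#' @return Tibble with one row per retained trial: ids, `is_true`,
#'   `say_true`, `crt_z`, `num_z`, `age_z`, `pol_concord_z`, `edu` (factor
#'   with the reference level first).
#' @export
build_predictor_table <- function(study, valence, included = NULL,
                                  rt_bounds = c(750, NA),
                                  item_bounds = c(1000, 60000)) {
  stopifnot(all(c("statement_id", "valence") %in% names(valence)))
  if (is.null(included)) {
    included <- apply_participant_inclusion(study, "main")$included
  }
  participants <- study$participants |>
    dplyr::filter(.data$participant_id %in% included)
  if (nrow(participants) < 2) {
    stop("fewer than two included participants; cannot standardize",
         call. = FALSE)
  }
  crt_c <- item_matrix(participants, "crt", "correct")
  crt_rt <- item_matrix(participants, "crt", "rt")
  num_c <- item_matrix(participants, "num", "correct")
  num_rt <- item_matrix(participants, "num", "rt")
  crt_score <- vapply(seq_len(nrow(participants)), function(i) {
    score_test(crt_c[i, ], crt_rt[i, ], item_bounds)
  }, numeric(1))
  num_score <- vapply(seq_len(nrow(participants)), function(i) {
    score_test(num_c[i, ], num_rt[i, ], item_bounds)
  }, numeric(1))
  crt_s <- standardize(crt_score)
  num_s <- standardize(num_score)
  age_s <- standardize(participants$age)

  config <- study$truth$config
  edu_levels <- if (!is.null(config)) config$edu_levels else
    sort(unique(participants$edu))
  edu_ref <- if (!is.null(config)) config$edu_ref else edu_levels[1]

  trials <- filter_trials(study$detection_trials, rt_bounds[1],
                          if (is.na(rt_bounds[2])) NULL else rt_bounds[2])$kept
  tab <- trials |>
    dplyr::filter(.data$participant_id %in% included) |>
    dplyr::inner_join(dplyr::select(study$statements, "statement_id",
                                    "is_true"),
                      by = "statement_id") |>
    dplyr::inner_join(valence, by = "statement_id") |>
    dplyr::inner_join(
      tibble::tibble(participant_id = participants$participant_id,
                     crt_z = crt_s$z, num_z = num_s$z, age_z = age_s$z,
                     pol = participants$pol, edu = participants$edu),
      by = "participant_id"
    ) |>
    dplyr::mutate(pol_concord = political_concordance(.data$valence,
                                                      .data$pol))
  conc_s <- standardize(tab$pol_concord)
  tab <- tab |>
    dplyr::mutate(
      pol_concord_z = conc_s$z,
      edu = factor(.data$edu,
                   levels = c(edu_ref, setdiff(edu_levels, edu_ref)))
    ) |>
    dplyr::select("participant_id", "statement_id", "is_true", "say_true",
                  "crt_z", "num_z", "age_z", "pol_concord_z", "edu")
  attr(tab, "scaling") <- list(
    crt = c(mean = crt_s$mean, sd = crt_s$sd),
    num = c(mean = num_s$mean, sd = num_s$sd),
    age = c(mean = age_s$mean, sd = age_s$sd),
    pol_concord = c(mean = conc_s$mean, sd = conc_s$sd)
  )
  tab
}
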