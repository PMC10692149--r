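study_table_specs <- function() {
  list(
    statements = c("statement_id", "is_true"),
    participants_main = c("participant_id", "age", "edu", "pol",
                          "nationality_ok", "sincere"),
    participants_calibration = c("participant_id", "age", "edu", "pol",
                                 "nationality_ok", "sincere"),
    detection_trials = c("participant_id", "statement_id", "say_true",
                         "rt_ms"),
    calibration_trials = c("participant_id", "statement_id", "cong_left",
                           "cong_right", "rt_ms")
  )
}

codebook_descriptions <- function() {
  c(statement_id = "statement identifier",
    is_true = "fact-checked ground-truth veracity (1 true, 0 false)",
    participant_id = "participant identifier",
    age = "age in years",
    sex = "self-reported sex",
    edu = "highest education level",
    pol = "political profile (pro-Left / pro-Right / other)",
    nationality_ok = "passed the nationality question",
    sincere = "answered yes to the sincerity and commitment question",
    say_true = "binary veracity judgement (1 = 'true')",
    rt_ms = "response time in milliseconds",
    position = "presentation position within the participant's session",
    cong_left = "pro-Left congruence slider rating in [0, 1]",
    cong_right = "pro-Right congruence slider rating in [0, 1]")
}

#' Write the study tables as CSV with codebooks
#'
#' One CSV per table plus a `codebook_<table>.csv` describing its columns,
#' and (for synthetic studies) the generating ground truth as JSON.
#' Latent truth columns of the statement table (valence, random intercepts)
#' go to the JSON, not the CSVs, so the exported tables look like collected
#' data.
#'
#' @param study an `sdt_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_tables <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  desc <- codebook_descriptions()
  item_desc <- function(nm) {
    dplyr::case_when(
      grepl("^crt_correct_", nm) ~ "CRT item correctness (1 correct)",
      grepl("^crt_rt_", nm) ~ "CRT item response time in milliseconds",
      grepl("^num_correct_", nm) ~ "numeracy item correctness (1 correct)",
      grepl("^num_rt_", nm) ~ "numeracy item response time in milliseconds",
      TRUE ~ unname(desc[nm])
    )
  }
  tabs <- list(
    statements = dplyr::select(study$statements, "statement_id", "is_true"),
    participants_main = study$participants,
    participants_calibration = study$calibration_participants,
    detection_trials = study$detection_trials,
    calibration_trials = study$calibration_trials
  )
  for (nm in names(tabs)) {
    readr::write_csv(tabs[[nm]], file.path(dir, paste0(nm, ".csv")))
    readr::write_csv(
      tibble::tibble(column = names(tabs[[nm]]),
                     description = item_desc(names(tabs[[nm]]))),
      file.path(dir, paste0("codebook_", nm, ".csv"))
    )
  }
  if (!is.null(study$truth)) {
    truth <- study$truth
    cfg <- truth$config
    cfg$coefficients <- unclass(cfg$coefficients)
    cfg$zoib <- unclass(cfg$zoib)
    jsonlite::write_json(
      list(config = unclass(cfg),
           statements = study$statements,
           main_effects = truth$main_effects,
           calibration_effects = truth$calibration_effects,
           scaling = truth$scaling),
      file.path(dir, "truth.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}

#' Read study tables from CSV
#'
#' Loads the five study tables, optionally renaming columns through a schema
#' mapping so externally deposited layouts can be adapted without code
#' changes. Unknown columns are preserved; a missing required column is an
#' error naming the column.
#'
#' @param dir directory containing the CSVs (as written by
#'   [write_study_tables()]), or a named list of file paths keyed by table
#'   name.
#' @param schema optional named list (per table) of `external = "canonical"`
#'   rename pairs, e.g.
#'   `list(detection_trials = c(resp = "say_true"))` maps column `resp` to
#'   `say_true`.
#' @return An `sdt_study` (with no generating truth attached).
#' @export
read_study_tables <- function(dir, schema = NULL) {
  specs <- study_table_specs()
  paths <- if (is.list(dir)) dir else
    stats::setNames(file.path(dir, paste0(names(specs), ".csv")),
                    names(specs))
  tabs <- lapply(names(specs), function(nm) {
    tb <- readr::read_csv(paths[[nm]], show_col_types = FALSE,
                          progress = FALSE)
    map <- schema[[nm]]
    if (!is.null(map)) {
      for (ext in names(map)) {
        if (ext %in% names(tb)) names(tb)[names(tb) == ext] <- map[[ext]]
      }
    }
    miss <- setdiff(specs[[nm]], names(tb))
    if (length(miss)) {
      stop("table '", nm, "' is missing required column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    tb
  })
  names(tabs) <- names(specs)
  structure(list(statements = tabs$statements,
                 participants = tabs$participants_main,
                 calibration_participants = tabs$participants_calibration,
                 detection_trials = tabs$detection_trials,
                 calibration_trials = tabs$calibration_trials,
                 truth = NULL),
            class = "sdt_study")
}

#' Run the full analysis pipeline
#'
#' Chains the registered workflow on one study: calibration-app inclusion
#' and RT filtering, the ZOIB calibration fit, the statement valence table,
#' political concordance, main-app inclusion and filtering, the hierarchical
#' SDT fit (with controls and, optionally, the no-controls sensitivity
#' variant), and the four directional hypothesis tests. Every stage logs
#' counts; every artifact records the configuration hash and seeds.
#'
#' @param study an `sdt_study` (simulated or read from CSV).
#' @param out_dir optional directory for artifacts (valence CSV,
#'   coefficient summaries, verdict JSON, draws CSV).
#' @param no_controls also fit the variant without age/education controls?
#' @param sdt_ctrl an [sdt_control()].
#' @param zoib_ctrl a [zoib_control()].
#' @param valence optional precomputed valence table (`statement_id`,
#'   `valence`); skips the calibration stage when given.
#' @param quiet suppress stage messages.
#' @return A list of class `sdt_pipeline`: exclusion logs, the calibration
#'   fit and valence table, the SDT fit(s), hypothesis tables, and the
#'   config hash.
#' @export
run_pipeline <- function(study, out_dir = NULL, no_controls = FALSE,
                         sdt_ctrl = sdt_control(),
                         zoib_ctrl = zoib_control(),
                         valence = NULL, quiet = FALSE) {
  stopifnot(inherits(study, "sdt_study"))
  say <- function(...) if (!quiet) message(...)
  cfg_hash <- rlang::hash(list(
    n_detection = nrow(study$detection_trials),
    n_calibration = nrow(study$calibration_trials),
    sdt_ctrl = unclass(sdt_ctrl), zoib_ctrl = unclass(zoib_ctrl),
    no_controls = no_controls
  ))

  calibration_fit <- NULL
  cal_inc <- NULL
  if (is.null(valence)) {
    cal_inc <- apply_participant_inclusion(study, "calibration")
    say("calibration: ", length(cal_inc$included), " of ",
        nrow(study$calibration_participants), " raters included")
    ft <- filter_trials(
      dplyr::filter(study$calibration_trials,
                    .data$participant_id %in% cal_inc$included), 750)
    say("calibration: ", ft$removed, " fast rating trials removed")
    cfg <- study$truth$config
    calibration_fit <- fit_calibration(
      ft$kept,
      study$calibration_participants,
      edu_levels = if (!is.null(cfg)) cfg$edu_levels else NULL,
      edu_ref = if (!is.null(cfg)) cfg$edu_ref else NULL,
      control = zoib_ctrl
    )
    valence <- valence_table(calibration_fit)
    say("calibration: valence table for ", nrow(valence), " statements")
  }

  main_inc <- apply_participant_inclusion(study, "main")
  say("main: ", length(main_inc$included), " of ",
      nrow(study$participants), " participants included")
  predictor_table <- build_predictor_table(study, valence,
                                           included = main_inc$included)
  say("main: ", nrow(predictor_table), " trials retained")

  fit <- fit_sdt(predictor_table, controls = TRUE, control = sdt_ctrl)
  hypotheses <- test_hypotheses(fit)
  fit_nc <- NULL
  hypotheses_nc <- NULL
  if (no_controls) {
    nc_ctrl <- sdt_ctrl
    nc_ctrl$seed <- derive_seed(sdt_ctrl$seed, "no_controls")
    fit_nc <- fit_sdt(predictor_table, controls = FALSE, control = nc_ctrl)
    hypotheses_nc <- test_hypotheses(fit_nc)
  }

  out <- structure(list(
    valence = valence, calibration_fit = calibration_fit,
    calibration_inclusion = cal_inc, main_inclusion = main_inc,
    predictor_table = predictor_table,
    sdt_fit = fit, hypotheses = hypotheses,
    sdt_fit_no_controls = fit_nc, hypotheses_no_controls = hypotheses_nc,
    config_hash = cfg_hash,
    seeds = c(sdt = sdt_ctrl$seed, zoib = zoib_ctrl$seed)
  ), class = "sdt_pipeline")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    export_valence_table(valence, file.path(out_dir, "valence.csv"))
    readr::write_csv(tidy(fit), file.path(out_dir,
                                          "coefficient_summary.csv"))
    readr::write_csv(fit$draws, file.path(out_dir, "sdt_draws.csv"))
    if (!is.null(fit_nc)) {
      readr::write_csv(tidy(fit_nc),
                       file.path(out_dir,
                                 "coefficient_summary_no_controls.csv"))
    }
    verdicts <- stats::setNames(
      lapply(seq_len(nrow(hypotheses)), function(i) {
        as.list(hypotheses[i, setdiff(names(hypotheses), "hypothesis")])
      }),
      hypotheses$hypothesis
    )
    jsonlite::write_json(
      list(config_hash = cfg_hash, seeds = as.list(out$seeds),
           verdicts = verdicts),
      file.path(out_dir, "verdicts.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.sdt_pipeline <- function(x, ...) {
  cat("<sdt_pipeline> config", x$config_hash, "\n")
  print(x$hypotheses)
  invisible(x)
}
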