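test_that("ZOIB density handles point masses and the beta branch", {
  expect_equal(dzoib(1, 0.4, 10, 0.2, 0.5, log = TRUE), log(0.1))
  expect_equal(dzoib(0, 0.4, 10, 0.2, 0.5, log = TRUE), log(0.1))
  # independent beta-density oracle
  expect_equal(dzoib(0.3, 0.4, 10, 0, 0.5, log = TRUE),
               stats::dbeta(0.3, 4, 6, log = TRUE))
  expect_equal(dzoib(0.3, 0.4, 10, 0.25, 0.5),
               0.75 * stats::dbeta(0.3, 4, 6))
  expect_error(dzoib(1.2, 0.4, 10, 0.2, 0.5), "\\[0, 1\\]")
  expect_error(dzoib(0.5, 1.4, 10, 0.2, 0.5), "mu")
  expect_error(dzoib(0.5, 0.4, -1, 0.2, 0.5), "phi")
})

test_that("ZOIB density integrates to one across a parameter grid", {
  grid <- expand.grid(mu = c(0.3, 0.7), phi = c(5, 20),
                      alpha = c(0, 0.3), gamma = c(0.2, 0.8))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cont <- stats::integrate(function(x) {
      dzoib(x, g$mu, g$phi, g$alpha, g$gamma)
    }, 0, 1, rel.tol = 1e-8)$value
    masses <- g$alpha * (1 - g$gamma) + g$alpha * g$gamma
    expect_equal(cont + masses, 1, tolerance = 1e-6)
  }
})

test_that("political valence is the congruence difference, bounded", {
  expect_equal(political_valence(0.8, 0.2), 0.6)
  expect_equal(political_valence(0.5, 0.5), 0)
  expect_equal(political_valence(1, 0), 1)
  expect_equal(political_valence(0, 1), -1)
  expect_error(political_valence(1.2, 0), "\\[0, 1\\]")
})

test_that("expected congruence marginalizes a degenerate posterior exactly", {
  fake_fit <- function(draws) {
    structure(list(draws = draws,
                   statement_ids = c("s1", "s2"),
                   pol_levels = c("other", "pro-Left", "pro-Right"),
                   edu_levels = c("hs", "uni"),
                   category_freqs = list(pol = c(other = 1, `pro-Left` = 0,
                                                 `pro-Right` = 0),
                                         edu = c(hs = 0.5, uni = 0.5))),
              class = "zoib_fit")
  }
  # intercept-only, alpha = 0, logit(mu) = 0 -> expectation 1/2
  d0 <- tibble::tibble(L_Intercept = c(0, 0), R_Intercept = c(0, 0),
                       L_alpha0 = c(-40, -40), R_alpha0 = c(-40, -40),
                       L_gamma0 = c(0, 0), R_gamma0 = c(0, 0))
  cong <- expected_statement_congruence(fake_fit(d0))
  expect_equal(cong$congL, c(0.5, 0.5))
  expect_equal(cong$congR, c(0.5, 0.5))
  # alpha = 1, gamma = 0.8 -> expectation 0.8 whatever mu
  d1 <- tibble::tibble(L_Intercept = c(2, 2), R_Intercept = c(-1, -1),
                       L_alpha0 = c(40, 40), R_alpha0 = c(40, 40),
                       L_gamma0 = stats::qlogis(c(0.8, 0.8)),
                       R_gamma0 = stats::qlogis(c(0.8, 0.8)))
  cong1 <- expected_statement_congruence(fake_fit(d1))
  expect_equal(cong1$congL, c(0.8, 0.8), tolerance = 1e-10)
  expect_equal(cong1$congR, c(0.8, 0.8), tolerance = 1e-10)
  expect_error(expected_statement_congruence(fake_fit(d0), "nope"),
               "unknown statement")
})

test_that("valence export is a strict statement-by-valence table", {
  vt <- tibble::tibble(statement_id = sprintf("s%03d", 1:30),
                       valence = seq(-0.8, 0.8, length.out = 30))
  path <- withr::local_tempfile(fileext = ".csv")
  export_valence_table(vt, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 30)
  expect_equal(names(back), c("statement_id", "valence"))
  expect_equal(back$valence, vt$valence)
  dup <- vt
  dup$statement_id[2] <- dup$statement_id[1]
  expect_error(export_valence_table(dup, path), "duplicate")
  expect_error(export_valence_table(vt[1:29, ], path, n_statements = 30),
               "complete row")
})

test_that("calibration fit recovers statement ordering and extremes", {
  cfg <- study_config(n_participants = 0, n_calibration = 50,
                      n_statements = 12, seed = 37)
  st <- simulate_study(cfg)
  fit <- suppressWarnings(fit_calibration(
    st$calibration_trials, st$calibration_participants,
    edu_levels = cfg$edu_levels, edu_ref = cfg$edu_ref,
    control = zoib_control(chains = 2, iter = 500, adapt = 400, seed = 11)))
  vt <- valence_table(fit)
  truth <- true_valence_table(st)
  cmp <- dplyr::inner_join(vt, truth, by = "statement_id",
                           suffix = c("_est", "_true"))
  expect_equal(nrow(cmp), 12)
  expect_gt(stats::cor(cmp$valence_est, cmp$valence_true,
                       method = "spearman"), 0.9)
  expect_gt(stats::cor(cmp$valence_est, cmp$valence_true), 0.95)
  expect_true(all(abs(vt$valence) <= 1))
  # point-mass intercepts sit near the generating alpha and gamma
  expect_lt(abs(mean(stats::plogis(fit$draws$L_alpha0)) - 0.1), 0.05)
  expect_lt(abs(mean(stats::plogis(fit$draws$L_gamma0)) - 0.5), 0.1)
})

test_that("symmetric ratings give expected congruence near one half", {
  cfg <- study_config(n_participants = 0, n_calibration = 40,
                      n_statements = 8, valence_range = 0.01, seed = 41)
  st <- simulate_study(cfg)
  fit <- suppressWarnings(fit_calibration(
    st$calibration_trials, st$calibration_participants,
    edu_levels = cfg$edu_levels, edu_ref = cfg$edu_ref,
    control = zoib_control(chains = 2, iter = 400, adapt = 300, seed = 2)))
  cong <- expected_statement_congruence(fit)
  expect_true(all(abs(cong$congL - 0.5) < 0.06))
  expect_true(all(abs(cong$congR - 0.5) < 0.06))
  expect_true(all(abs(valence_table(fit)$valence) < 0.08))
})

test_that("calibration fits are reproducible under a fixed seed", {
  cfg <- study_config(n_participants = 0, n_calibration = 12,
                      n_statements = 6, seed = 43)
  st <- simulate_study(cfg)
  ctrl <- zoib_control(chains = 2, iter = 150, adapt = 150, seed = 9)
  f1 <- suppressWarnings(fit_calibration(st$calibration_trials,
                                         st$calibration_participants,
                                         control = ctrl))
  f2 <- suppressWarnings(fit_calibration(st$calibration_trials,
                                         st$calibration_participants,
                                         control = ctrl))
  expect_identical(f1$draws, f2$draws)
})
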