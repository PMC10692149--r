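test_that("response_probability matches the probit closed form", {
  expect_equal(response_probability(0, 0, 0), 0.5)
  expect_equal(response_probability(1.5, 1, 0), 0.9332, tolerance = 1e-4)
  expect_equal(response_probability(1.0, 0, -0.5), 0.6915, tolerance = 1e-4)
  # vectorized and strictly inside (0, 1) for finite inputs
  p <- response_probability(c(-3, 0, 3), c(1, 0, 1), c(2, -2, 0))
  expect_true(all(p > 0 & p < 1))
  expect_error(response_probability(1, 2, 0), "is_true")
})

test_that("identical config and seed give byte-identical studies", {
  cfg <- study_config(n_participants = 15, n_calibration = 10, seed = 42)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$statements, s2$statements)
  expect_identical(s1$participants, s2$participants)
  expect_identical(s1$detection_trials, s2$detection_trials)
  expect_identical(s1$calibration_trials, s2$calibration_trials)
  s3 <- simulate_study(study_config(n_participants = 15,
                                    n_calibration = 10, seed = 43))
  expect_false(identical(s1$detection_trials, s3$detection_trials))
})

test_that("zero participants still yields the statement table", {
  st <- simulate_study(study_config(n_participants = 0, n_calibration = 0,
                                    seed = 1))
  expect_equal(nrow(st$statements), 30)
  expect_equal(nrow(st$detection_trials), 0)
  expect_equal(nrow(st$calibration_trials), 0)
  expect_true(all(c("participant_id", "statement_id", "say_true", "rt_ms")
                  %in% names(st$detection_trials)))
})

test_that("study structure honours the within-subjects design", {
  cfg <- study_config(n_participants = 12, n_calibration = 8,
                      n_statements = 10, seed = 5)
  st <- simulate_study(cfg)
  counts <- table(st$detection_trials$participant_id)
  expect_true(all(counts == 10))
  expect_equal(nrow(st$calibration_trials), 8 * 10)
  expect_true(all(st$statements$is_true %in% c(0, 1)))
  expect_equal(sum(st$statements$is_true), 5)
  expect_true(all(abs(st$statements$true_valence) <= 1))
  expect_true(all(st$calibration_trials$cong_left >= 0 &
                    st$calibration_trials$cong_left <= 1))
})

test_that("simulated responses are Bernoulli draws at the probit rate", {
  n <- 1e5
  data <- tibble::tibble(is_true = rep(c(0L, 1L), each = n / 2))
  cf <- homogeneous_coefficients(d = 1.2, c = 0.4)
  tr <- simulate_detection_trials(data, cf, seed = 99)
  for (v in c(0, 1)) {
    p <- response_probability(1.2, v, 0.4)
    emp <- mean(tr$say_true[tr$is_true == v])
    se <- sqrt(p * (1 - p) / (n / 2))
    expect_lt(abs(emp - p), 3 * se)
  }
  # saturating probit: a wildly liberal criterion forces "true"
  sat <- simulate_detection_trials(
    tibble::tibble(is_true = rep(0L, 500), c_offset = -10), cf, seed = 1)
  expect_true(all(sat$say_true == 1))
  # determinism
  t1 <- simulate_detection_trials(data[1:50, ], cf, seed = 7)
  t2 <- simulate_detection_trials(data[1:50, ], cf, seed = 7)
  expect_identical(t1, t2)
})

test_that("label-swap symmetry: flipped truth and responses negate c", {
  st <- simulate_study(study_config(
    n_participants = 400, n_calibration = 0,
    coefficients = homogeneous_coefficients(d = 1, c = 0.3), seed = 21))
  tr <- dplyr::inner_join(st$detection_trials,
                          st$statements[c("statement_id", "is_true")],
                          by = "statement_id")
  orig <- cell_estimates(tr$say_true, tr$is_true)
  flip <- cell_estimates(1L - tr$say_true, 1L - tr$is_true)
  expect_equal(orig[["dprime"]], flip[["dprime"]], tolerance = 0.06)
  expect_equal(orig[["c_mid"]], -flip[["c_mid"]], tolerance = 0.06)
})

test_that("quality-violation injection is controlled and logged", {
  cfg <- study_config(n_participants = 20, n_calibration = 10, seed = 8)
  st <- simulate_study(cfg)
  same <- inject_quality_violations(st, list(fast_trial = 0))
  expect_identical(same$detection_trials, st$detection_trials)
  expect_equal(nrow(same$injection_log), 0)

  bad <- inject_quality_violations(
    st, list(fast_trial = 0.3, insincere = 0.2, nonpolarised = 0.1,
             foreign = 0.1), seed = 3)
  expect_true(nrow(bad$injection_log) > 0)
  expect_equal(sum(bad$detection_trials$rt_ms < 750),
               floor(0.3 * nrow(st$detection_trials)), tolerance = 0.1)
  # insincere participants are excluded downstream
  insincere <- bad$participants$participant_id[!bad$participants$sincere]
  inc <- apply_participant_inclusion(bad, "main")
  expect_length(intersect(insincere, inc$included), 0)
  expect_true(all(!inc$log$pass_sincerity[
    inc$log$participant_id %in% insincere]))
})

test_that("a participant with 30% fast trials fails the 75% rule", {
  st <- simulate_study(study_config(n_participants = 5, n_calibration = 0,
                                    seed = 13))
  pid <- st$participants$participant_id[1]
  rows <- which(st$detection_trials$participant_id == pid)
  st$detection_trials$rt_ms[rows[1:9]] <- 400  # 21/30 = 70% in-window
  inc <- apply_participant_inclusion(st, "main")
  expect_false(pid %in% inc$included)
  expect_false(inc$log$pass_rt[inc$log$participant_id == pid])
})

test_that("zero-one-inflated ratings match their mixture moments", {
  set.seed(31)
  n <- 1e5
  mu <- 0.4; phi <- 10; alpha <- 0.2; gamma <- 0.6
  y <- rzoib(n, mu, phi, alpha, gamma)
  m <- zoib_mean(mu, alpha, gamma)
  expect_lt(abs(mean(y) - m), 3 * stats::sd(y) / sqrt(n))
  frac_binary <- mean(y == 0 | y == 1)
  expect_lt(abs(frac_binary - alpha), 3 * sqrt(alpha * (1 - alpha) / n))
  ones <- mean(y[y == 0 | y == 1])
  n_bin <- sum(y == 0 | y == 1)
  expect_lt(abs(ones - gamma), 3 * sqrt(gamma * (1 - gamma) / n_bin))
  # degenerate branches
  expect_true(all(rzoib(100, 0.5, 5, 1, 1) == 1))
  y0 <- rzoib(1000, 0.5, 5, 0, 0.5)
  expect_true(all(y0 > 0 & y0 < 1))
})
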