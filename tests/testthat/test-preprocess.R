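test_that("trial RT filter applies strict bounds", {
  tr <- tibble::tibble(rt_ms = c(500, 750, 751, 5000, 10000, 12000))
  out <- filter_trials(tr, 750)
  expect_equal(out$removed, 2)          # 500 and the 750 boundary
  expect_true(all(out$kept$rt_ms > 750))
  out2 <- filter_trials(tr, 750, 10000)
  expect_equal(out2$removed, 4)         # also 10000 (boundary) and 12000
  empty <- filter_trials(tr[0, ], 750)
  expect_equal(nrow(empty$kept), 0)
  expect_equal(empty$removed, 0)
  expect_error(filter_trials(tr, 1000, 800), "lower < upper")
})

test_that("test scoring discards items outside the RT window", {
  expect_equal(score_test(c(1, 1, 1), c(5e3, 6e3, 7e3)), 3)
  expect_equal(score_test(c(1, 1, 1), c(500, 6e3, 7e3)), 2)   # 0.5 s item
  expect_equal(score_test(c(1, 1, 1), c(5e3, 6e3, 9e4)), 2)   # 90 s item
  expect_equal(score_test(c(1, 0, 1), c(500, 6e3, 7e3)), 1)
  # two valid items, both correct (participant retained per the >=2 rule)
  expect_equal(score_test(c(1, 1, 0), c(5e3, 6e3, 100)), 2)
  expect_equal(score_test(integer(0), numeric(0)), 0)
})

test_that("standardization is exact and invertible", {
  s <- standardize(c(1, 2, 3))
  expect_equal(s$z, c(-1, 0, 1))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  x <- rnorm(50, 10, 3)
  s2 <- standardize(x)
  expect_equal(mean(s2$z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(s2$z), 1, tolerance = 1e-12)
  expect_equal(s2$z * s2$sd + s2$mean, x)
  expect_error(standardize(rep(5, 10)), "constant")
})

test_that("political concordance flips sign for pro-Left profiles", {
  expect_equal(political_concordance(0.4, "pro-Right"), 0.4)
  expect_equal(political_concordance(0.4, "pro-Left"), -0.4)
  expect_equal(political_concordance(0, "pro-Left"), 0)
  expect_error(political_concordance(0.4, "other"), "non-polarised")
  # antisymmetry for arbitrary valences
  v <- runif(20, -1, 1)
  expect_equal(political_concordance(v, rep("pro-Left", 20)),
               -political_concordance(v, rep("pro-Right", 20)))
})

test_that("inclusion criteria follow the registered rules", {
  st <- simulate_study(study_config(n_participants = 10, n_calibration = 6,
                                    seed = 17))
  # sincerity
  st$participants$sincere[1] <- FALSE
  inc <- apply_participant_inclusion(st, "main")
  p1 <- st$participants$participant_id[1]
  expect_false(p1 %in% inc$included)
  expect_false(inc$log$pass_sincerity[inc$log$participant_id == p1])

  # exactly 23 of 30 detection trials in-window (76.7%) passes
  p2 <- st$participants$participant_id[2]
  rows <- which(st$detection_trials$participant_id == p2)
  st$detection_trials$rt_ms[rows] <- 2000
  st$detection_trials$rt_ms[rows[1:7]] <- 100
  inc <- apply_participant_inclusion(st, "main")
  expect_true(inc$log$pass_rt[inc$log$participant_id == p2])
  # one more fast trial (22/30 = 73.3%) fails
  st$detection_trials$rt_ms[rows[8]] <- 100
  inc <- apply_participant_inclusion(st, "main")
  expect_false(inc$log$pass_rt[inc$log$participant_id == p2])

  # calibration app has no polarisation requirement
  st$calibration_participants$pol[1] <- "other"
  cinc <- apply_participant_inclusion(st, "calibration")
  expect_true(st$calibration_participants$participant_id[1] %in%
                cinc$included)
  # but the main app does
  st$participants$pol[3] <- "other"
  minc <- apply_participant_inclusion(st, "main")
  expect_false(st$participants$participant_id[3] %in% minc$included)

  expect_error(apply_participant_inclusion(st, "detection"), "arg")
})

test_that("inclusion and filtering are idempotent and monotone", {
  st <- simulate_study(study_config(
    n_participants = 25, n_calibration = 0, seed = 19,
    violation_rates = list(fast_trial = 0.1, insincere = 0.1)))
  inc1 <- apply_participant_inclusion(st, "main")
  # idempotence: restricting to the included set changes nothing
  st2 <- st
  st2$participants <- dplyr::filter(st$participants,
                                    .data$participant_id %in% inc1$included)
  st2$detection_trials <- dplyr::filter(
    st$detection_trials, .data$participant_id %in% inc1$included)
  inc2 <- apply_participant_inclusion(st2, "main")
  expect_setequal(inc2$included, inc1$included)

  f1 <- filter_trials(st$detection_trials, 750)
  f2 <- filter_trials(f1$kept, 750)
  expect_identical(f2$kept, f1$kept)
  expect_equal(f2$removed, 0)

  # monotone: adding violations never adds included participants
  worse <- inject_quality_violations(st, list(insincere = 0.3), seed = 2)
  inc3 <- apply_participant_inclusion(worse, "main")
  expect_true(all(inc3$included %in% inc1$included))
})

test_that("predictor table standardizes over the retained populations", {
  st <- simulate_study(study_config(n_participants = 40, n_calibration = 0,
                                    seed = 23))
  pt <- build_predictor_table(st, true_valence_table(st))
  for (v in c("crt_z", "num_z", "age_z")) {
    per_part <- pt |>
      dplyr::distinct(.data$participant_id, .data[[v]])
    expect_equal(mean(per_part[[v]]), 0, tolerance = 1e-10)
    expect_equal(stats::sd(per_part[[v]]), 1, tolerance = 1e-10)
  }
  expect_equal(mean(pt$pol_concord_z), 0, tolerance = 1e-10)
  expect_equal(stats::sd(pt$pol_concord_z), 1, tolerance = 1e-10)
  # no RT-filtered trial survives
  joined <- dplyr::semi_join(st$detection_trials, pt,
                             by = c("participant_id", "statement_id"))
  expect_true(all(joined$rt_ms > 750))
  sc <- attr(pt, "scaling")
  expect_named(sc, c("crt", "num", "age", "pol_concord"))
  expect_equal(levels(pt$edu)[1], "high-school complete")
})
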