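test_that("linear predictors expand exactly as the two model equations", {
  zero <- sdt_coefficients(d_intercept = 0, c_intercept = 0, d_crt = 0,
                           d_concord = 0, d_concord_crt = 0,
                           c_crt = 0, c_concord = 0, c_concord_crt = 0)
  lp <- linear_predictors(tibble::tibble(crt_z = 1, pol_concord_z = 1), zero)
  expect_equal(lp$dprime, 0)
  expect_equal(lp$c, 0)

  io <- sdt_coefficients(d_intercept = 1, c_intercept = -0.3,
                         d_crt = 0, d_concord = 0, d_concord_crt = 0,
                         c_crt = 0, c_concord = 0, c_concord_crt = 0)
  lp2 <- linear_predictors(tibble::tibble(crt_z = c(2, -1)), io)
  expect_equal(lp2$dprime, c(1, 1))
  expect_equal(lp2$c, c(-0.3, -0.3))

  # manual dot-product oracle with the interaction term
  cf <- sdt_coefficients(d_intercept = 0.5, d_crt = 0.2, d_concord = -0.1,
                         d_concord_crt = 0.3, d_num = 0.05, d_age = -0.02,
                         d_edu = c(0.1, 0.2, 0.3),
                         c_intercept = -0.4, c_crt = 0.15, c_concord = -0.6,
                         c_concord_crt = -0.25, c_num = 0.07, c_age = 0.01,
                         c_edu = c(-0.1, -0.2, -0.3))
  row <- tibble::tibble(crt_z = 1, pol_concord_z = -1, num_z = 0.5,
                        age_z = 2, edu = "tertiary")
  levs <- c("primary", "high-school complete", "tertiary", "university")
  lp3 <- linear_predictors(row, cf, edu_levels = levs,
                           edu_ref = "high-school complete")
  # non-reference order: primary, tertiary, university -> tertiary is [2]
  expect_equal(lp3$dprime,
               0.5 + 0.2 * 1 + (-0.1) * (-1) + 0.3 * (-1) * 1 +
                 0.05 * 0.5 + (-0.02) * 2 + 0.2)
  expect_equal(lp3$c,
               -0.4 + 0.15 * 1 + (-0.6) * (-1) + (-0.25) * (-1) * 1 +
                 0.07 * 0.5 + 0.01 * 2 + (-0.2))
})

test_that("log-likelihood equals an independently coded Bernoulli sum", {
  set.seed(61)
  fx <- tibble::tibble(
    is_true = rep(c(0L, 1L), 10),
    say_true = rbinom(20, 1, 0.5),
    crt_z = rnorm(20), pol_concord_z = rnorm(20),
    num_z = rnorm(20), age_z = rnorm(20),
    d_offset = rnorm(20, 0, 0.3), c_offset = rnorm(20, 0, 0.3)
  )
  cf <- sdt_coefficients(d_intercept = 0.8, c_intercept = 0.2,
                         d_crt = 0.1, d_concord = 0.05, d_concord_crt = 0.02,
                         c_crt = 0.1, c_concord = -0.5, c_concord_crt = -0.1)
  # brute-force oracle: explicit per-trial loop
  ll0 <- 0
  for (i in 1:20) {
    d <- 0.8 + fx$d_offset[i] + 0.1 * fx$crt_z[i] +
      0.05 * fx$pol_concord_z[i] +
      0.02 * fx$pol_concord_z[i] * fx$crt_z[i]
    cc <- 0.2 + fx$c_offset[i] + 0.1 * fx$crt_z[i] -
      0.5 * fx$pol_concord_z[i] -
      0.1 * fx$pol_concord_z[i] * fx$crt_z[i]
    p <- pnorm(d * fx$is_true[i] - cc)
    ll0 <- ll0 + ifelse(fx$say_true[i] == 1, log(p), log(1 - p))
  }
  expect_equal(sdt_loglikelihood(fx, cf), ll0)

  # single trial at pi = 0.5
  one <- tibble::tibble(is_true = 0L, say_true = 1L)
  expect_equal(sdt_loglikelihood(one, homogeneous_coefficients(1, 0)),
               log(0.5))

  # flipping a response agreeing with pi > 0.5 lowers the likelihood
  agree <- tibble::tibble(is_true = 1L, say_true = 1L)
  disagree <- tibble::tibble(is_true = 1L, say_true = 0L)
  cf1 <- homogeneous_coefficients(1.5, 0)
  expect_gt(sdt_loglikelihood(agree, cf1), sdt_loglikelihood(disagree, cf1))

  # order invariance
  shuf <- fx[sample(20), ]
  expect_equal(sdt_loglikelihood(shuf, cf), sdt_loglikelihood(fx, cf))

  # clipping guards saturated probabilities
  sat <- tibble::tibble(is_true = 0L, say_true = 1L, c_offset = 50)
  expect_true(is.finite(sdt_loglikelihood(sat, homogeneous_coefficients())))
})

test_that("fit_sdt validates input and is seed-reproducible", {
  st <- simulate_study(study_config(n_participants = 20, n_calibration = 0,
                                    seed = 71))
  pt <- build_predictor_table(st, true_valence_table(st))
  expect_error(fit_sdt(dplyr::select(pt, -"crt_z")), "crt_z")
  ctrl <- quick_ctrl(seed = 4, iter = 100, warmup = 50)
  f1 <- suppressWarnings(fit_sdt(pt, control = ctrl))
  f2 <- suppressWarnings(fit_sdt(pt, control = ctrl))
  expect_identical(f1$draws, f2$draws)
  expect_equal(nrow(f1$draws), 200)
  expect_true(all(c("d_Intercept", "c_pol_concord:crt_score",
                    "sd_d_statement") %in% names(f1$draws)))
  expect_equal(nrow(f1$diagnostics), ncol(f1$draws) - 2)
  # no-controls variant drops age and education terms
  fnc <- suppressWarnings(fit_sdt(pt, controls = FALSE, control = ctrl))
  expect_false(any(grepl("age|edu", names(fnc$draws))))
  expect_true("c_num_score" %in% names(fnc$draws))
})

test_that("responses carrying no signal give d' near zero", {
  st <- simulate_study(study_config(n_participants = 60, n_calibration = 0,
                                    seed = 73))
  pt <- build_predictor_table(st, true_valence_table(st))
  set.seed(5)
  pt$say_true <- rbinom(nrow(pt), 1, 0.5)   # independent of is_true
  f <- suppressWarnings(fit_sdt(pt, control = quick_ctrl(seed = 6)))
  td <- tidy(f)
  expect_lt(abs(td$median[td$parameter == "d_Intercept"]), 0.15)
})

test_that("the Gibbs sampler agrees with an independent JAGS fit", {
  # small fixture, fixed effects only in common: compare posterior medians
  st <- simulate_study(study_config(n_participants = 50, n_calibration = 0,
                                    n_statements = 16, seed = 79))
  pt <- build_predictor_table(st, true_valence_table(st))
  fit <- suppressWarnings(fit_sdt(pt, controls = FALSE,
                                  control = quick_ctrl(seed = 8, iter = 1000,
                                                       warmup = 400)))
  model <- "
  model {
   for (i in 1:N) {
    y[i] ~ dbern(phi(d[i] * isT[i] - c[i]))
    d[i] <- bd[1] + bd[2]*crt[i] + bd[3]*conc[i] + bd[4]*conc[i]*crt[i] +
            bd[5]*num[i] + d_id[pid[i]] + d_st[sid[i]]
    c[i] <- bc[1] + bc[2]*crt[i] + bc[3]*conc[i] + bc[4]*conc[i]*crt[i] +
            bc[5]*num[i] + c_id[pid[i]] + c_st[sid[i]]
   }
   bd[1] ~ dnorm(0, 0.25); bc[1] ~ dnorm(0, 0.25)
   for (k in 2:5) { bd[k] ~ dnorm(0, 1); bc[k] ~ dnorm(0, 1) }
   for (p in 1:P) { d_id[p] ~ dnorm(0, pow(s1, -2))
                    c_id[p] ~ dnorm(0, pow(s2, -2)) }
   for (s in 1:S) { d_st[s] ~ dnorm(0, pow(s3, -2))
                    c_st[s] ~ dnorm(0, pow(s4, -2)) }
   s1 ~ dnorm(0, 1) T(0,); s2 ~ dnorm(0, 1) T(0,)
   s3 ~ dnorm(0, 1) T(0,); s4 ~ dnorm(0, 1) T(0,)
  }"
  dat <- list(y = pt$say_true, isT = pt$is_true,
              crt = pt$crt_z, conc = pt$pol_concord_z, num = pt$num_z,
              pid = as.integer(factor(pt$participant_id)),
              sid = as.integer(factor(pt$statement_id)),
              N = nrow(pt),
              P = dplyr::n_distinct(pt$participant_id),
              S = dplyr::n_distinct(pt$statement_id))
  jm <- rjags::jags.model(textConnection(model), data = dat, n.chains = 2,
                          n.adapt = 400, quiet = TRUE,
                          inits = list(.RNG.name = "base::Mersenne-Twister",
                                       .RNG.seed = 99))
  samp <- rjags::coda.samples(jm, c("bd", "bc"), n.iter = 1200)
  jags_med <- apply(as.matrix(samp), 2, stats::median)
  ours <- tidy(fit)
  pairs <- rbind(
    c("d_Intercept", "bd[1]"), c("d_crt_score", "bd[2]"),
    c("d_pol_concord", "bd[3]"), c("d_pol_concord:crt_score", "bd[4]"),
    c("c_Intercept", "bc[1]"), c("c_crt_score", "bc[2]"),
    c("c_pol_concord", "bc[3]"), c("c_pol_concord:crt_score", "bc[4]")
  )
  for (i in seq_len(nrow(pairs))) {
    gap <- abs(ours$median[ours$parameter == pairs[i, 1]] -
                 jags_med[[pairs[i, 2]]])
    expect_lt(gap, 0.12, label = paste(pairs[i, 1], "gap"))
  }
})

test_that("posterior predictive reproduces observed response rates", {
  st <- simulate_study(study_config(n_participants = 50, n_calibration = 0,
                                    seed = 83))
  pt <- build_predictor_table(st, true_valence_table(st))
  fit <- suppressWarnings(fit_sdt(pt, control = quick_ctrl(seed = 10)))
  pp <- posterior_predictive(fit, ndraws = 100, seed = 3)
  expect_equal(dim(pp$yrep), c(100, nrow(pt)))
  pred_rate <- mean(pp$yrep)
  obs_rate <- mean(pt$say_true)
  expect_lt(abs(pred_rate - obs_rate), 0.03)
  # fixed seed reproducibility
  pp2 <- posterior_predictive(fit, ndraws = 100, seed = 3)
  expect_identical(pp$yrep, pp2$yrep)
})

test_that("a degenerate posterior predicts like the generative model", {
  # all draws equal -> predictive equals forward simulation at those values
  st <- simulate_study(study_config(
    n_participants = 40, n_calibration = 0,
    coefficients = homogeneous_coefficients(d = 1, c = 0.3), seed = 87))
  pt <- build_predictor_table(st, true_valence_table(st))
  fit <- suppressWarnings(fit_sdt(pt, control = quick_ctrl(seed = 11,
                                                           iter = 200,
                                                           warmup = 100)))
  # collapse the posterior onto a single point
  fit$draws[paste0("d_", fit$design_names)] <- 0
  fit$draws$d_Intercept <- 1
  fit$draws[paste0("c_", fit$design_names)] <- 0
  fit$draws$c_Intercept <- 0.3
  fit$ranef[] <- 0
  pp <- posterior_predictive(fit, ndraws = 150, seed = 13)
  for (v in c(0L, 1L)) {
    p <- response_probability(1, v, 0.3)
    emp <- mean(pp$yrep[, pt$is_true == v])
    n_cell <- sum(pt$is_true == v) * nrow(pp$yrep)
    expect_lt(abs(emp - p), 4 * sqrt(p * (1 - p) / n_cell))
  }
})
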