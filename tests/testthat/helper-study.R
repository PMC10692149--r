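# shared fixtures: all synthetic, built in code at test time

# homogeneous population: fixed d' and c, no covariate or random effects
homogeneous_coefficients <- function(d = 1, c = 0.3) {
  sdt_coefficients(d_intercept = d, c_intercept = c,
                   d_crt = 0, d_concord = 0, d_concord_crt = 0,
                   d_num = 0, d_age = 0, d_edu = c(0, 0, 0),
                   c_crt = 0, c_concord = 0, c_concord_crt = 0,
                   c_num = 0, c_age = 0, c_edu = c(0, 0, 0),
                   sd_d_id = 0, sd_c_id = 0,
                   sd_d_statement = 0, sd_c_statement = 0)
}

true_valence_table <- function(study) {
  tibble::tibble(statement_id = study$statements$statement_id,
                 valence = study$statements$true_valence)
}

# reduced sampler settings for unit-test fits
quick_ctrl <- function(seed = 1L, chains = 2, iter = 500, warmup = 250) {
  sdt_control(chains = chains, iter = iter, warmup = warmup, seed = seed)
}

# closed-form equal-variance SDT cell estimates from hit/false-alarm rates;
# the criterion here is referenced to the ideal-observer midpoint
cell_estimates <- function(say_true, is_true) {
  H <- mean(say_true[is_true == 1])
  F <- mean(say_true[is_true == 0])
  c(dprime = stats::qnorm(H) - stats::qnorm(F),
    c_mid = -(stats::qnorm(H) + stats::qnorm(F)) / 2)
}

# the model measures c from the false-statement distribution; shift by d'/2
# to compare with the midpoint-referenced closed form
fitted_population_sdt <- function(fit) {
  td <- tidy(fit)
  d <- td$median[td$parameter == "d_Intercept"]
  cc <- td$median[td$parameter == "c_Intercept"]
  c(dprime = d, c_mid = cc - d / 2)
}
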