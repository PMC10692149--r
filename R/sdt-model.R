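#' Evaluate the SDT linear predictors for trial rows
#'
#' Computes d' and c for each row exactly as the model's two linear
#' equations: intercept + random-intercept offsets + CRT, concordance,
#' their interaction, numeracy, age and education terms. Missing predictor
#' columns are treated as zero (reference level), so intercept-only
#' evaluations are convenient.
#'
#' @param data tibble; recognised columns are `crt_z`, `pol_concord_z`,
#'   `num_z`, `age_z`, `edu`, and random-intercept sums `d_offset`,
#'   `c_offset`.
#' @param coefficients an [sdt_coefficients()].
#' @param edu_levels,edu_ref education coding; defaults to the factor levels
#'   of `data$edu` with its first level as reference.
#' @return Tibble with columns `dprime` and `c`.
#' @export
#' @examples
#' linear_predictors(tibble::tibble(crt_z = c(-1, 0, 1)),
#'                   sdt_coefficients(d_intercept = 1, d_crt = 0.5))
linear_predictors <- function(data, coefficients, edu_levels = NULL,
                              edu_ref = NULL) {
  cf <- coefficients
  n <- nrow(data)
  col0 <- function(nm) if (nm %in% names(data)) data[[nm]] else rep(0, n)
  edu_d <- edu_c <- rep(0, n)
  if ("edu" %in% names(data)) {
    edu <- data$edu
    if (is.null(edu_levels)) {
      edu_levels <- if (is.factor(edu)) levels(edu) else sort(unique(edu))
    }
    if (is.null(edu_ref)) edu_ref <- edu_levels[1]
    nonref <- setdiff(edu_levels, edu_ref)
    if (length(nonref) > length(cf$d_edu)) {
      stop("more non-reference education levels than coefficients",
           call. = FALSE)
    }
    idx <- match(as.character(edu), nonref)
    edu_d <- ifelse(is.na(idx), 0, cf$d_edu[idx])
    edu_c <- ifelse(is.na(idx), 0, cf$c_edu[idx])
  }
  crt <- col0("crt_z"); conc <- col0("pol_concord_z")
  tibble::tibble(
    dprime = cf$d_intercept + col0("d_offset") + cf$d_crt * crt +
      cf$d_concord * conc + cf$d_concord_crt * conc * crt +
      cf$d_num * col0("num_z") + cf$d_age * col0("age_z") + edu_d,
    c = cf$c_intercept + col0("c_offset") + cf$c_crt * crt +
      cf$c_concord * conc + cf$c_concord_crt * conc * crt +
      cf$c_num * col0("num_z") + cf$c_age * col0("age_z") + edu_c
  )
}

#' Bernoulli log-likelihood of the SDT model
#'
#' Sum over trials of the Bernoulli log-mass at
#' `pnorm(dprime * is_true - c)`. Probabilities are clipped to
#' `[1e-12, 1 - 1e-12]` to guard the log at saturating predictors.
#'
#' @param data tibble with `say_true`, `is_true` and predictor columns as in
#'   [linear_predictors()].
#' @inheritParams linear_predictors
#' @return Scalar log-likelihood.
#' @export
sdt_loglikelihood <- function(data, coefficients, edu_levels = NULL,
                              edu_ref = NULL) {
  lp <- linear_predictors(data, coefficients, edu_levels, edu_ref)
  p <- response_probability(lp$dprime, data$is_true, lp$c)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(stats::dbinom(data$say_true, 1L, p, log = TRUE))
}

#' Sampler settings for the hierarchical SDT fit
#'
#' @param chains number of chains.
#' @param iter retained draws per chain (total draws = `chains * iter`;
#'   the default 4 x 2000 = 8000).
#' @param warmup burn-in iterations per chain, discarded.
#' @param seed integer seed; chain seeds are derived from it.
#' @param max_ranef_draws at most this many joint random-effect draws are
#'   stored (thinned, aligned with the fixed-effect draws) for posterior
#'   prediction.
#' @return A list of class `sdt_control`.
#' @export
sdt_control <- function(chains = 4, iter = 2000, warmup = 500, seed = 1L,
                        max_ranef_draws = 400) {
  stopifnot(chains >= 1, iter >= 2, warmup >= 0)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), seed = as.integer(seed),
                 max_ranef_draws = as.integer(max_ranef_draws)),
            class = "sdt_control")
}

#' Priors for the hierarchical SDT fit
#'
#' Proper priors are required throughout (Savage-Dickey Bayes factors divide
#' by the prior density at zero). Fixed effects on the standardized predictor
#' scale get Normal(0, `sd_fixed`); intercepts Normal(0, `sd_intercept`);
#' random-intercept standard deviations half-Normal(0, `sd_scale`).
#'
#' @param sd_fixed,sd_intercept,sd_scale prior standard deviations.
#' @return A list of class `sdt_priors`.
#' @export
sdt_priors <- function(sd_fixed = 1, sd_intercept = 2, sd_scale = 1) {
  stopifnot(sd_fixed > 0, sd_intercept > 0, sd_scale > 0)
  structure(list(sd_fixed = sd_fixed, sd_intercept = sd_intercept,
                 sd_scale = sd_scale), class = "sdt_priors")
}

# design matrix for one SDT equation; identical structure for d' and c
sdt_design <- function(data, controls = TRUE) {
  n <- nrow(data)
  X <- cbind(Intercept = rep(1, n),
             crt_score = data$crt_z,
             pol_concord = data$pol_concord_z,
             `pol_concord:crt_score` = data$pol_concord_z * data$crt_z,
             num_score = data$num_z)
  if (controls) {
    X <- cbind(X, age = data$age_z)
    edu <- data$edu
    if (!is.factor(edu)) edu <- factor(edu)
    if (nlevels(edu) > 1) {
      D <- stats::model.matrix(~edu)[, -1, drop = FALSE]
      colnames(D) <- paste0("edu:", levels(edu)[-1])
      X <- cbind(X, D)
    }
  }
  X
}

# slice update of a scale s with half-Normal(0, prior_sd) prior given
# effects x ~ N(0, s^2); used for the centered half of the ASIS scale move
slice_scale <- function(sd_cur, x, prior_sd = 1) {
  n <- length(x)
  ssq <- sum(x^2)
  logpost <- function(ls) {
    s <- exp(ls)
    -n * ls - ssq / (2 * s^2) - s^2 / (2 * prior_sd^2) + ls
  }
  ls0 <- log(sd_cur)
  ly <- logpost(ls0) - stats::rexp(1)
  L <- ls0 - stats::runif(1)
  R <- L + 1
  for (i in 1:100) { if (logpost(L) < ly) break; L <- L - 1 }
  for (i in 1:100) { if (logpost(R) < ly) break; R <- R + 1 }
  repeat {
    ls1 <- stats::runif(1, L, R)
    if (logpost(ls1) >= ly) return(exp(ls1))
    if (ls1 < ls0) L <- ls1 else R <- ls1
  }
}

# truncated standard-deviation-1 normal draws: z ~ N(mu, 1), sign fixed by y
rtruncnorm_sign <- function(mu, positive) {
  p0 <- stats::pnorm(-mu)           # P(z - mu < -mu) = P(z < 0)
  u <- stats::runif(length(mu))
  q <- ifelse(positive, p0 + u * (1 - p0), u * p0)
  mu + stats::qnorm(pmin(pmax(q, 1e-15), 1 - 1e-15))
}

# One Gibbs chain for the probit SDT model, by truncated-normal data
# augmentation. Random intercepts use the non-centered (parameter-expanded)
# form: effect = lambda * u with u ~ N(0, 1) and lambda ~ N(0, sd_scale^2)
# unconstrained, so the scale is |lambda| with the intended half-Normal
# prior, every conditional is Gaussian, and the sd ~ 0 funnel is avoided.
run_sdt_chain <- function(y, isT, pid, sid, Xd, Xc, priors, n_iter, warmup,
                          thin_ranef, seed) {
  set.seed(seed)
  N <- length(y); np <- max(pid); ns <- max(sid)
  Kf <- ncol(Xd) + ncol(Xc)
  W <- cbind(Xd * isT, -Xc)
  prior_prec <- c(
    ifelse(colnames(Xd) == "Intercept", priors$sd_intercept^-2,
           priors$sd_fixed^-2),
    ifelse(colnames(Xc) == "Intercept", priors$sd_intercept^-2,
           priors$sd_fixed^-2)
  )
  ch <- chol(crossprod(W) + diag(prior_prec, Kf))
  positive <- y == 1L
  lam_prec <- priors$sd_scale^-2
  nT_p <- as.vector(rowsum(isT, pid))     # isT^2 sums (isT is 0/1)
  n_p <- tabulate(pid, np)
  nT_s <- as.vector(rowsum(isT, sid))
  n_s <- tabulate(sid, ns)
  idx_dp <- which(nT_p > 0)
  idx_ds <- which(nT_s > 0)

  beta <- stats::rnorm(Kf, 0, 0.3)
  ud <- stats::rnorm(np); uc <- stats::rnorm(np)
  vd <- stats::rnorm(ns); vc <- stats::rnorm(ns)
  lam <- stats::rnorm(4, 0, 0.3)  # d_id, c_id, d_statement, c_statement
  eta_fix <- as.vector(W %*% beta)

  keep_ranef <- seq(thin_ranef, n_iter, by = thin_ranef)
  draws <- matrix(NA_real_, n_iter, Kf + 4)
  ranef <- matrix(NA_real_, length(keep_ranef), 2 * (np + ns))
  ri <- 0L

  re_d_id <- function() lam[1] * isT * ud[pid]
  re_c_id <- function() -lam[2] * uc[pid]
  re_d_st <- function() lam[3] * isT * vd[sid]
  re_c_st <- function() -lam[4] * vc[sid]

  for (it in seq_len(warmup + n_iter)) {
    eta_re <- re_d_id() + re_c_id() + re_d_st() + re_c_st()
    z <- rtruncnorm_sign(eta_fix + eta_re, positive)

    r <- z - eta_re
    m <- backsolve(ch, forwardsolve(t(ch), crossprod(W, r)))
    beta <- as.vector(m + backsolve(ch, stats::rnorm(Kf)))
    eta_fix <- as.vector(W %*% beta)
    res <- z - eta_fix

    # participant d' intercepts: contribution lam1 * isT * ud
    r1 <- res - re_c_id() - re_d_st() - re_c_st()
    prec <- lam[1]^2 * nT_p + 1
    ud <- lam[1] * as.vector(rowsum(isT * r1, pid)) / prec +
      stats::rnorm(np) / sqrt(prec)
    g <- isT * ud[pid]
    prec <- sum(g * g) + lam_prec
    lam[1] <- sum(g * r1) / prec + stats::rnorm(1) / sqrt(prec)

    # participant c intercepts: contribution -lam2 * uc
    r1 <- res - re_d_id() - re_d_st() - re_c_st()
    prec <- lam[2]^2 * n_p + 1
    uc <- -lam[2] * as.vector(rowsum(r1, pid)) / prec +
      stats::rnorm(np) / sqrt(prec)
    g <- -uc[pid]
    prec <- sum(g * g) + lam_prec
    lam[2] <- sum(g * r1) / prec + stats::rnorm(1) / sqrt(prec)

    # statement d' intercepts
    r1 <- res - re_d_id() - re_c_id() - re_c_st()
    prec <- lam[3]^2 * nT_s + 1
    vd <- lam[3] * as.vector(rowsum(isT * r1, sid)) / prec +
      stats::rnorm(ns) / sqrt(prec)
    g <- isT * vd[sid]
    prec <- sum(g * g) + lam_prec
    lam[3] <- sum(g * r1) / prec + stats::rnorm(1) / sqrt(prec)

    # statement c intercepts
    r1 <- res - re_d_id() - re_c_id() - re_d_st()
    prec <- lam[4]^2 * n_s + 1
    vc <- -lam[4] * as.vector(rowsum(r1, sid)) / prec +
      stats::rnorm(ns) / sqrt(prec)
    g <- -vc[sid]
    prec <- sum(g * g) + lam_prec
    lam[4] <- sum(g * r1) / prec + stats::rnorm(1) / sqrt(prec)

    # ASIS scale moves: holding the actual effects lam * u fixed (so the
    # likelihood is untouched), redraw the scale from its centered
    # conditional and rescale u. Complements the non-centered updates,
    # which alone leave |lam| mixing slowly once effects are large. Only
    # likelihood-identified effects enter (d' intercepts of units never
    # seen with a true statement are prior-only and would feed the scale
    # back to itself).
    asis <- function(l, u, idx) {
      if (abs(l) < 1e-12 || length(idx) == 0) return(list(l = l, u = u))
      b <- l * u[idx]
      l_new <- sign(l) * slice_scale(abs(l), b, priors$sd_scale)
      u[idx] <- b / l_new
      list(l = l_new, u = u)
    }
    a <- asis(lam[1], ud, idx_dp); lam[1] <- a$l; ud <- a$u
    a <- asis(lam[2], uc, seq_len(np)); lam[2] <- a$l; uc <- a$u
    a <- asis(lam[3], vd, idx_ds); lam[3] <- a$l; vd <- a$u
    a <- asis(lam[4], vc, seq_len(ns)); lam[4] <- a$l; vc <- a$u

    # interweaving (translation) updates: shift mass between each intercept
    # and the mean of its random-effect family; the likelihood is invariant,
    # so the conditional is Gaussian from the priors alone. Kills the slow
    # intercept-vs-effect-mean ridge (30 statements make it severe).
    i_d <- which(colnames(Xd) == "Intercept")
    i_c <- ncol(Xd) + which(colnames(Xc) == "Intercept")
    s2 <- priors$sd_intercept^2
    shift <- function(u, l, i_int) {
      prec <- length(u) + l^2 / s2
      delta <- stats::rnorm(1, (sum(u) - l * beta[i_int] / s2) / prec,
                            1 / sqrt(prec))
      beta[i_int] <<- beta[i_int] + l * delta
      u - delta
    }
    if (length(i_d) == 1) {
      ud <- shift(ud, lam[1], i_d)
      vd <- shift(vd, lam[3], i_d)
    }
    if (length(i_c) == 1) {
      uc <- shift(uc, lam[2], i_c)
      vc <- shift(vc, lam[4], i_c)
    }
    eta_fix <- as.vector(W %*% beta)

    if (it > warmup) {
      k <- it - warmup
      draws[k, ] <- c(beta, abs(lam))
      if (k %% thin_ranef == 0) {
        ri <- ri + 1L
        ranef[ri, ] <- c(lam[1] * ud, lam[2] * uc, lam[3] * vd, lam[4] * vc)
      }
    }
  }
  list(draws = draws, ranef = ranef, ranef_iter = keep_ranef)
}

#' Fit the hierarchical equal-variance SDT model
#'
#' Bayesian fit of the probit Bernoulli model with linear predictors on both
#' d' and c and crossed random intercepts for participants and statements.
#' Sampling uses truncated-normal data augmentation: conditional on latent
#' normal decision variables every regression update is conjugate Gaussian,
#' and the random-intercept scales take slice-sampling steps under their
#' half-Normal priors. Chains are run with distinct derived seeds; split
#' convergence diagnostics (potential scale reduction and effective sample
#' size via coda) are attached and non-convergence is flagged with a
#' warning, never silently ignored.
#'
#' @param data predictor table from [build_predictor_table()] (columns
#'   `participant_id`, `statement_id`, `is_true`, `say_true`, `crt_z`,
#'   `num_z`, `age_z`, `pol_concord_z`, `edu`).
#' @param controls include the age and education control terms? `FALSE`
#'   gives the sensitivity variant without them.
#' @param priors an [sdt_priors()].
#' @param control an [sdt_control()].
#' @return An object of class `sdt_fit` with elements `draws` (tibble,
#'   `.chain`, `.iteration` and one column per parameter), `diagnostics`,
#'   `converged`, `ranef` (thinned random-effect draws), `data`, `priors`,
#'   `control`.
#' @export
fit_sdt <- function(data, controls = TRUE, priors = sdt_priors(),
                    control = sdt_control()) {
  req <- c("participant_id", "statement_id", "is_true", "say_true",
           "crt_z", "num_z", "pol_concord_z")
  if (controls) req <- c(req, "age_z", "edu")
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    stop("predictor table is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(!data$say_true %in% c(0L, 1L))) {
    stop("say_true must be binary", call. = FALSE)
  }
  pid <- as.integer(factor(data$participant_id))
  sid <- as.integer(factor(data$statement_id))
  Xd <- sdt_design(data, controls)
  Xc <- Xd
  par_names <- c(paste0("d_", colnames(Xd)), paste0("c_", colnames(Xc)),
                 "sd_d_id", "sd_c_id", "sd_d_statement", "sd_c_statement")
  thin_ranef <- max(1L, ceiling(control$iter * control$chains /
                                  control$max_ranef_draws))
  fits <- lapply(seq_len(control$chains), function(chain) {
    run_sdt_chain(data$say_true, data$is_true, pid, sid, Xd, Xc, priors,
                  control$iter, control$warmup, thin_ranef,
                  seed = derive_seed(control$seed, paste0("chain", chain)))
  })
  draws <- purrr::map_dfr(seq_along(fits), function(i) {
    d <- tibble::as_tibble(fits[[i]]$draws, .name_repair = "minimal")
    names(d) <- par_names
    dplyr::mutate(d, .chain = i, .iteration = dplyr::row_number(),
                  .before = 1)
  })
  mcl <- coda::mcmc.list(lapply(fits, function(f) coda::mcmc(f$draws)))
  ess <- coda::effectiveSize(mcl)
  rhat <- if (control$chains >= 2) {
    coda::gelman.diag(mcl, autoburnin = FALSE,
                      multivariate = FALSE)$psrf[, 1]
  } else {
    rep(NA_real_, length(par_names))
  }
  diagnostics <- tibble::tibble(parameter = par_names,
                                rhat = unname(rhat), ess = unname(ess))
  converged <- !any(diagnostics$rhat > 1.1, na.rm = TRUE)
  if (!converged) {
    warning("SDT fit did not converge: max Rhat = ",
            round(max(diagnostics$rhat, na.rm = TRUE), 3), call. = FALSE)
  }
  ranef <- do.call(rbind, lapply(fits, `[[`, "ranef"))
  np <- max(pid); ns <- max(sid)
  colnames(ranef) <- c(
    paste0("d_id[", levels(factor(data$participant_id)), "]"),
    paste0("c_id[", levels(factor(data$participant_id)), "]"),
    paste0("d_statement[", levels(factor(data$statement_id)), "]"),
    paste0("c_statement[", levels(factor(data$statement_id)), "]")
  )
  ranef_draw_index <- unlist(lapply(seq_along(fits), function(i) {
    (i - 1) * control$iter + fits[[i]]$ranef_iter
  }))
  structure(list(draws = draws, diagnostics = diagnostics,
                 converged = converged,
                 ranef = ranef, ranef_draw_index = ranef_draw_index,
                 data = data, controls = controls, priors = priors,
                 control = control, design_names = colnames(Xd)),
            class = "sdt_fit")
}

#' @export
print.sdt_fit <- function(x, ...) {
  cat("<sdt_fit> hierarchical probit SDT model\n")
  cat("  trials:", nrow(x$data),
      "| participants:", dplyr::n_distinct(x$data$participant_id),
      "| statements:", dplyr::n_distinct(x$data$statement_id), "\n")
  cat("  draws:", nrow(x$draws), sprintf("(%d chains x %d)",
      x$control$chains, x$control$iter),
      "| controls:", x$controls, "\n")
  cat("  converged:", x$converged, "\n")
  print(tidy(x), n = 12)
  invisible(x)
}

#' Posterior-predictive response sets
#'
#' Simulates replicated binary responses from stored joint posterior draws
#' (fixed effects plus the aligned random-intercept draws), for
#' model-checking plots such as observed vs predicted "true"-rates by
#' concordance bin.
#'
#' @param fit an [fit_sdt()] result.
#' @param data trial table to predict (default: the training data).
#' @param ndraws number of posterior draws to use (at most the stored
#'   random-effect draws).
#' @param seed optional integer seed.
#' @return List with `yrep` (draws x trials matrix) and `draw_index`.
#' @export
posterior_predictive <- function(fit, data = NULL, ndraws = 100,
                                 seed = NULL) {
  stopifnot(inherits(fit, "sdt_fit"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(data)) data <- fit$data
  avail <- seq_along(fit$ranef_draw_index)
  pick <- if (ndraws >= length(avail)) avail else
    sort(sample(avail, ndraws))
  X <- sdt_design(data, fit$controls)
  kd <- length(fit$design_names)
  dmat <- as.matrix(fit$draws[fit$ranef_draw_index[pick],
                              paste0("d_", fit$design_names)])
  cmat <- as.matrix(fit$draws[fit$ranef_draw_index[pick],
                              paste0("c_", fit$design_names)])
  rid <- paste0("d_id[", data$participant_id, "]")
  ril <- paste0("c_id[", data$participant_id, "]")
  rsd <- paste0("d_statement[", data$statement_id, "]")
  rsl <- paste0("c_statement[", data$statement_id, "]")
  known <- colnames(fit$ranef)
  grab <- function(keys, row) {
    idx <- match(keys, known)
    v <- numeric(length(keys))
    ok <- !is.na(idx)
    v[ok] <- fit$ranef[row, idx[ok]]
    v
  }
  yrep <- matrix(NA_integer_, length(pick), nrow(data))
  for (i in seq_along(pick)) {
    row <- pick[i]
    dprime <- as.vector(X %*% dmat[i, ]) + grab(rid, row) + grab(rsd, row)
    cc <- as.vector(X %*% cmat[i, ]) + grab(ril, row) + grab(rsl, row)
    p <- response_probability(dprime, data$is_true, cc)
    yrep[i, ] <- stats::rbinom(ncol(yrep), 1L, p)
  }
  list(yrep = yrep, draw_index = fit$ranef_draw_index[pick])
}
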