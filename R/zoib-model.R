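#' Sampler settings for the ZOIB calibration fit
#'
#' @param chains number of JAGS chains.
#' @param iter retained draws per chain.
#' @param adapt adaptation + burn-in iterations.
#' @param seed integer seed; per-chain RNG seeds are derived from it.
#' @return A list of class `zoib_control`.
#' @export
zoib_control <- function(chains = 2, iter = 1500, adapt = 800, seed = 1L) {
  stopifnot(chains >= 1, iter >= 2, adapt >= 0)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 adapt = as.integer(adapt), seed = as.integer(seed)),
            class = "zoib_control")
}

# one dependent-variable block of the joint ZOIB model; `v` is "L" or "R";
# the likelihood loops are dropped when their data subset is empty (the
# corresponding parameters then keep their priors)
zoib_block <- function(v, has_interior = TRUE, has_binary = TRUE) {
  interior <- "
 for (q in 1:Ni_V) {
  yi_V[q] ~ dbeta(muV[q] * phiV[pidi_V[q]], (1 - muV[q]) * phiV[pidi_V[q]])
  logit(muV[q]) <- u_V[pidi_V[q]] + b_st_V[sidi_V[q]]
 }"
  binary <- "
 for (j in 1:Nb_V) { wb_V[j] ~ dbern(ga_V[pidb_V[j]]) }"
  gsub("V", v, paste0(
    if (has_interior) interior else "",
    "
 for (i in 1:N) { zb_V[i] ~ dbern(al_V[pid[i]]) }",
    if (has_binary) binary else "",
    zoib_block_tail()))
}

zoib_block_tail <- function() {
  "
 for (p in 1:P) {
  # centered hierarchical parameterization: the participant intercept is
  # drawn around its covariate-determined mean (pol, age and edu are
  # participant-level, so their regression on u is conjugate normal --
  # much better Gibbs geometry than trial-level covariate terms)
  u_V[p] ~ dnorm(b0_V + b_pol_V[pol_p[p]] + b_age_V * age_p[p] +
                 b_edu_V[edu_p[p]], tau_u_V)
  logit(al_V[p]) <- a_id_V[p]
  a_id_V[p] ~ dnorm(a0_V, tau_a_V)
  logit(ga_V[p]) <- g_id_V[p]
  g_id_V[p] ~ dnorm(g0_V, tau_g_V)
  log(phiV[p]) <- f_id_V[p]
  f_id_V[p] ~ dnorm(f0_V, tau_f_V)
 }
 b0_V ~ dnorm(0, 0.444)
 b_st_V[1] <- 0
 for (s in 2:S) { b_st_V[s] ~ dnorm(0, 0.444) }
 b_pol_V[1] <- 0
 for (k in 2:K) { b_pol_V[k] ~ dnorm(0, 0.444) }
 b_age_V ~ dnorm(0, 0.444)
 b_edu_V[1] <- 0
 for (m in 2:M) { b_edu_V[m] ~ dnorm(0, 0.444) }
 a0_V ~ dnorm(0, 0.444)
 g0_V ~ dnorm(0, 0.444)
 f0_V ~ dnorm(2, 0.25)
 sd_u_V ~ dnorm(0, 1) T(0,) ; tau_u_V <- pow(sd_u_V, -2)
 sd_a_V ~ dnorm(0, 1) T(0,) ; tau_a_V <- pow(sd_a_V, -2)
 sd_g_V ~ dnorm(0, 1) T(0,) ; tau_g_V <- pow(sd_g_V, -2)
 sd_f_V ~ dnorm(0, 1) T(0,) ; tau_f_V <- pow(sd_f_V, -2)
"
}

zoib_model_string <- function(dat) {
  paste0("model {",
         zoib_block("L", dat$Ni_L > 0, dat$Nb_L > 0),
         zoib_block("R", dat$Ni_R > 0, dat$Nb_R > 0),
         "}")
}

# per-DV data blocks for JAGS; ratings within `tol` of 0/1 are point masses
zoib_dv_data <- function(y, pid, sid, v, tol = 1e-9) {
  y <- pmin(pmax(y, 0), 1)
  at0 <- y <= tol
  at1 <- y >= 1 - tol
  bin <- at0 | at1
  int <- which(!bin)
  binw <- which(bin)
  out <- list(y[int], pid[int], sid[int],
              length(int), as.integer(bin), as.integer(at1[binw]),
              pid[binw], length(binw))
  names(out) <- paste0(c("yi_", "pidi_", "sidi_",
                         "Ni_", "zb_", "wb_", "pidb_", "Nb_"), v)
  out
}

#' Fit the multivariate zero-one-inflated-beta calibration model
#'
#' Joint Bayesian fit of the ZOIB mixed model to the pro-Left and pro-Right
#' slider ratings. Each dependent variable gets its own coefficient set; the
#' two share the participant grouping. The beta-mean linear predictor (logit
#' link) carries statement effects (reference: first statement), political
#' profile (reference: "other"), standardized age and education (reference:
#' `edu_ref`), plus a by-participant intercept; precision, binary-rating
#' probability and the one-given-binary probability are intercept-only with
#' by-participant variability. Fitting uses JAGS via rjags; the ZOIB
#' likelihood factorizes exactly into a beta block over interior ratings and
#' two Bernoulli blocks over the point masses.
#'
#' @param trials calibration rating tibble (`participant_id`,
#'   `statement_id`, `cong_left`, `cong_right`), already RT-filtered.
#' @param participants rater covariate tibble (`participant_id`, `pol`,
#'   `age`, `edu`), typically the included calibration raters.
#' @param edu_levels,edu_ref education coding (defaults: levels present,
#'   reference "high-school complete" when available).
#' @param control a [zoib_control()].
#' @param tol ratings within `tol` of 0 or 1 count as point masses.
#' @return An object of class `zoib_fit`: `draws` (tibble with `.chain`,
#'   `.iteration` and named parameter columns), `diagnostics`, `converged`,
#'   and metadata (`statement_ids`, `pol_levels`, `edu_levels`,
#'   `age_scaling`, observed category frequencies).
#' @export
fit_calibration <- function(trials, participants, edu_levels = NULL,
                            edu_ref = NULL, control = zoib_control(),
                            tol = 1e-9) {
  req <- c("participant_id", "statement_id", "cong_left", "cong_right")
  miss <- setdiff(req, names(trials))
  if (length(miss)) {
    stop("calibration trials missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(trials$cong_left < 0 | trials$cong_left > 1 |
            trials$cong_right < 0 | trials$cong_right > 1)) {
    stop("ratings must lie in [0, 1]", call. = FALSE)
  }
  participants <- dplyr::filter(participants,
                                .data$participant_id %in%
                                  trials$participant_id)
  trials <- dplyr::filter(trials,
                          .data$participant_id %in%
                            participants$participant_id)
  if (nrow(participants) < 2) {
    stop("need at least two raters with trials", call. = FALSE)
  }
  pol_levels <- c("other", "pro-Left", "pro-Right")
  if (any(!participants$pol %in% pol_levels)) {
    stop("unknown political profile level", call. = FALSE)
  }
  if (is.null(edu_levels)) {
    edu_levels <- sort(unique(as.character(participants$edu)))
  }
  if (is.null(edu_ref)) {
    edu_ref <- if ("high-school complete" %in% edu_levels)
      "high-school complete" else edu_levels[1]
  }
  edu_levels <- c(edu_ref, setdiff(edu_levels, edu_ref))
  statement_ids <- sort(unique(trials$statement_id))

  age_s <- standardize(participants$age)
  pid <- as.integer(factor(trials$participant_id,
                           levels = participants$participant_id))
  sid <- match(trials$statement_id, statement_ids)

  dat <- c(
    list(N = nrow(trials), P = nrow(participants),
         S = length(statement_ids), K = length(pol_levels),
         M = length(edu_levels), pid = pid,
         pol_p = match(participants$pol, pol_levels),
         edu_p = match(as.character(participants$edu), edu_levels),
         age_p = age_s$z),
    zoib_dv_data(trials$cong_left, pid, sid, "L", tol),
    zoib_dv_data(trials$cong_right, pid, sid, "R", tol)
  )
  monitor <- as.vector(outer(
    c("b0_", "b_st_", "b_pol_", "b_age_", "b_edu_", "a0_", "g0_", "f0_",
      "sd_u_", "sd_a_", "sd_g_", "sd_f_"),
    c("L", "R"), paste0))
  model_str <- zoib_model_string(dat)
  # drop data entries whose likelihood loop was omitted
  for (v in c("L", "R")) {
    if (dat[[paste0("Ni_", v)]] == 0) {
      dat[paste0(c("yi_", "pidi_", "sidi_", "Ni_"), v)] <- NULL
    }
    if (dat[[paste0("Nb_", v)]] == 0) {
      dat[paste0(c("wb_", "pidb_", "Nb_"), v)] <- NULL
    }
  }
  inits <- lapply(seq_len(control$chains), function(chain) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = derive_seed(control$seed, paste0("zoib", chain)))
  })
  jm <- rjags::jags.model(textConnection(model_str), data = dat,
                          inits = inits, n.chains = control$chains,
                          n.adapt = control$adapt, quiet = TRUE)
  samp <- rjags::coda.samples(jm, monitor, n.iter = control$iter)

  # drop structurally-zero reference entries, keep readable names
  keep <- !grepl("(b_st_[LR]\\[1\\]|b_pol_[LR]\\[1\\]|b_edu_[LR]\\[1\\])",
                 coda::varnames(samp))
  samp <- samp[, keep, drop = FALSE]
  rename <- function(nm) {
    nm <- gsub("^b_st_([LR])\\[(\\d+)\\]$", "\\1_statement.\\2", nm)
    nm <- gsub("^b_pol_([LR])\\[(\\d+)\\]$", "\\1_pol.\\2", nm)
    nm <- gsub("^b_edu_([LR])\\[(\\d+)\\]$", "\\1_edu.\\2", nm)
    nm <- gsub("^b0_([LR])$", "\\1_Intercept", nm)
    nm <- gsub("^b_age_([LR])$", "\\1_age", nm)
    nm <- gsub("^a0_([LR])$", "\\1_alpha0", nm)
    nm <- gsub("^g0_([LR])$", "\\1_gamma0", nm)
    nm <- gsub("^f0_([LR])$", "\\1_logphi0", nm)
    nm <- gsub("^sd_([uagf])_([LR])$", "\\2_sd_\\1", nm)
    for (i in seq_along(statement_ids)) {
      nm <- gsub(paste0("_statement\\.", i, "$"),
                 paste0("_statement:", statement_ids[i]), nm)
    }
    for (i in seq_along(pol_levels)) {
      nm <- gsub(paste0("_pol\\.", i, "$"),
                 paste0("_pol:", pol_levels[i]), nm)
    }
    for (i in seq_along(edu_levels)) {
      nm <- gsub(paste0("_edu\\.", i, "$"),
                 paste0("_edu:", edu_levels[i]), nm)
    }
    nm
  }
  par_names <- rename(coda::varnames(samp))
  draws <- purrr::map_dfr(seq_along(samp), function(i) {
    d <- tibble::as_tibble(as.matrix(samp[[i]]), .name_repair = "minimal")
    names(d) <- par_names
    dplyr::mutate(d, .chain = i, .iteration = dplyr::row_number(),
                  .before = 1)
  })
  ess <- coda::effectiveSize(samp)
  rhat <- if (control$chains >= 2) {
    coda::gelman.diag(samp, autoburnin = FALSE,
                      multivariate = FALSE)$psrf[, 1]
  } else rep(NA_real_, length(par_names))
  diagnostics <- tibble::tibble(parameter = par_names,
                                rhat = unname(rhat), ess = unname(ess))
  converged <- !any(diagnostics$rhat > 1.1, na.rm = TRUE)
  if (!converged) {
    warning("calibration fit did not converge: max Rhat = ",
            round(max(diagnostics$rhat, na.rm = TRUE), 3), call. = FALSE)
  }
  structure(list(
    draws = draws, diagnostics = diagnostics, converged = converged,
    statement_ids = statement_ids, pol_levels = pol_levels,
    edu_levels = edu_levels,
    age_scaling = c(mean = age_s$mean, sd = age_s$sd),
    category_freqs = list(
      pol = prop.table(table(factor(participants$pol, pol_levels))),
      edu = prop.table(table(factor(participants$edu, edu_levels)))
    ),
    control = control
  ), class = "zoib_fit")
}

#' @export
print.zoib_fit <- function(x, ...) {
  cat("<zoib_fit> multivariate zero-one-inflated beta model\n")
  cat("  statements:", length(x$statement_ids),
      "| draws:", nrow(x$draws), "| converged:", x$converged, "\n")
  invisible(x)
}

#' Expected population congruence of each statement
#'
#' For an average participant: random intercepts at zero, age at its mean
#' (z = 0), and the political-profile and education effects averaged over
#' their categories. The expectation of the mixture is
#' `(1 - alpha) * mu + alpha * gamma`, evaluated per posterior draw and then
#' averaged.
#'
#' @param fit a [fit_calibration()] result.
#' @param statement_id optional subset of statement ids.
#' @param marginal `"balanced"` averages category effects with equal weight
#'   (the "average participant" grid); `"observed"` weights them by the
#'   observed rater frequencies.
#' @return Tibble with `statement_id`, `congL`, `congR`.
#' @export
expected_statement_congruence <- function(fit, statement_id = NULL,
                                          marginal = c("balanced",
                                                       "observed")) {
  stopifnot(inherits(fit, "zoib_fit"))
  marginal <- match.arg(marginal)
  ids <- statement_id %||% fit$statement_ids
  unknown <- setdiff(ids, fit$statement_ids)
  if (length(unknown)) {
    stop("unknown statement id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  w_pol <- if (marginal == "balanced") {
    rep(1 / length(fit$pol_levels), length(fit$pol_levels))
  } else as.numeric(fit$category_freqs$pol)
  w_edu <- if (marginal == "balanced") {
    rep(1 / length(fit$edu_levels), length(fit$edu_levels))
  } else as.numeric(fit$category_freqs$edu)

  one_dv <- function(v) {
    d <- fit$draws
    col <- function(nm) if (nm %in% names(d)) d[[nm]] else 0
    pol_eff <- Reduce(`+`, lapply(seq_along(fit$pol_levels), function(k) {
      w_pol[k] * col(paste0(v, "_pol:", fit$pol_levels[k]))
    }))
    edu_eff <- Reduce(`+`, lapply(seq_along(fit$edu_levels), function(m) {
      w_edu[m] * col(paste0(v, "_edu:", fit$edu_levels[m]))
    }))
    alpha <- stats::plogis(col(paste0(v, "_alpha0")))
    gamma <- stats::plogis(col(paste0(v, "_gamma0")))
    vapply(ids, function(s) {
      eta <- col(paste0(v, "_Intercept")) +
        col(paste0(v, "_statement:", s)) + pol_eff + edu_eff
      mean((1 - alpha) * stats::plogis(eta) + alpha * gamma)
    }, numeric(1))
  }
  tibble::tibble(statement_id = ids,
                 congL = unname(one_dv("L")),
                 congR = unname(one_dv("R")))
}

#' Political valence from expected congruences
#'
#' Valence is the expected pro-Right congruence minus the expected pro-Left
#' congruence: positive values mark statements aligned with right-wing
#' voters, negative with left-wing voters, bounded in `[-1, 1]`.
#'
#' @param congR,congL expected congruences in `[0, 1]`.
#' @return Numeric valence values.
#' @export
#' @examples
#' political_valence(0.8, 0.2)  # 0.6
political_valence <- function(congR, congL) {
  if (any(congR < 0 | congR > 1 | congL < 0 | congL > 1, na.rm = TRUE)) {
    stop("congruences must lie in [0, 1]", call. = FALSE)
  }
  congR - congL
}

#' Statement valence table
#'
#' The calibration product consumed by the main analysis: one row per
#' statement, one valence column.
#'
#' @param fit a [fit_calibration()] result (or a tibble with `statement_id`,
#'   `congL`, `congR`).
#' @param marginal passed to [expected_statement_congruence()].
#' @return Tibble with `statement_id` and `valence`.
#' @export
valence_table <- function(fit, marginal = "balanced") {
  cong <- if (inherits(fit, "zoib_fit")) {
    expected_statement_congruence(fit, marginal = marginal)
  } else fit
  stopifnot(all(c("statement_id", "congL", "congR") %in% names(cong)))
  tibble::tibble(statement_id = cong$statement_id,
                 valence = political_valence(cong$congR, cong$congL))
}

#' Export the valence table as CSV
#'
#' Writes exactly one row per statement and two columns (`statement_id`,
#' `valence`); duplicate or missing statements are an error.
#'
#' @param values tibble with `statement_id` and `valence`.
#' @param path output CSV path.
#' @param n_statements expected row count (default: rows given).
#' @return `path`, invisibly.
#' @export
export_valence_table <- function(values, path,
                                 n_statements = nrow(values)) {
  stopifnot(all(c("statement_id", "valence") %in% names(values)))
  if (anyDuplicated(values$statement_id)) {
    stop("duplicate statement id in valence table", call. = FALSE)
  }
  if (nrow(values) != n_statements || anyNA(values$valence)) {
    stop("valence table must have one complete row per statement",
         call. = FALSE)
  }
  readr::write_csv(values[c("statement_id", "valence")], path)
  invisible(path)
}
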