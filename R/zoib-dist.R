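#' Zero-one-inflated beta density
#'
#' Density of the ZOIB mixture used to model bounded slider ratings: with
#' probability `alpha` the rating is exactly binary (1 with probability
#' `gamma`, else 0), otherwise it comes from a Beta distribution with mean
#' `mu` and precision `phi` (shapes `phi * mu`, `phi * (1 - mu)`).
#'
#' The distribution is mixed (two point masses plus a continuous part), so
#' `dzoib()` returns the point-mass probability at 0 and 1 and the Lebesgue
#' density elsewhere; it integrates to one in the sense
#' `P(0) + P(1) + integral over (0,1) = 1`.
#'
#' @param x rating values in `[0, 1]`.
#' @param mu,phi,alpha,gamma ZOIB parameters (recycled against `x`).
#' @param log if `TRUE`, return log-density.
#' @return Numeric vector of (log-)densities.
#' @export
#' @examples
#' dzoib(1, mu = 0.4, phi = 10, alpha = 0.2, gamma = 0.5)  # alpha * gamma
#' dzoib(0.3, mu = 0.4, phi = 10, alpha = 0, gamma = 0.5)  # dbeta(0.3, 4, 6)
dzoib <- function(x, mu, phi, alpha, gamma, log = FALSE) {
  check_zoib_par(mu, phi, alpha, gamma)
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("ratings must lie in [0, 1]", call. = FALSE)
  }
  n <- max(length(x), length(mu), length(phi), length(alpha), length(gamma))
  x <- rep_len(x, n); mu <- rep_len(mu, n); phi <- rep_len(phi, n)
  alpha <- rep_len(alpha, n); gamma <- rep_len(gamma, n)
  ld <- numeric(n)
  at0 <- x == 0
  at1 <- x == 1
  mid <- !at0 & !at1
  ld[at0] <- log(alpha[at0]) + log1p(-gamma[at0])
  ld[at1] <- log(alpha[at1]) + log(gamma[at1])
  ld[mid] <- log1p(-alpha[mid]) +
    stats::dbeta(x[mid], mu[mid] * phi[mid], (1 - mu[mid]) * phi[mid],
                 log = TRUE)
  if (log) ld else exp(ld)
}

#' Draw zero-one-inflated beta ratings
#'
#' @param n number of draws.
#' @param mu,phi,alpha,gamma ZOIB parameters (recycled to length `n`).
#' @return Numeric vector of ratings in `[0, 1]`; expectation is
#'   `(1 - alpha) * mu + alpha * gamma`.
#' @export
#' @examples
#' set.seed(1)
#' mean(rzoib(1e4, mu = 0.4, phi = 10, alpha = 0.2, gamma = 0.5))
rzoib <- function(n, mu, phi, alpha, gamma) {
  check_zoib_par(mu, phi, alpha, gamma)
  mu <- rep_len(mu, n); phi <- rep_len(phi, n)
  alpha <- rep_len(alpha, n); gamma <- rep_len(gamma, n)
  binary <- stats::rbinom(n, 1L, alpha) == 1L
  out <- numeric(n)
  out[binary] <- stats::rbinom(sum(binary), 1L, gamma[binary])
  k <- !binary
  out[k] <- stats::rbeta(sum(k), mu[k] * phi[k], (1 - mu[k]) * phi[k])
  out
}

#' Expectation of the ZOIB mixture
#'
#' @inheritParams rzoib
#' @return `(1 - alpha) * mu + alpha * gamma`.
#' @export
zoib_mean <- function(mu, alpha, gamma) (1 - alpha) * mu + alpha * gamma
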