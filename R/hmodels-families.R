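#' Likelihood families for the hierarchical regression layer
#'
#' Mean-precision beta density and its zero- and zero-one-inflated mixtures,
#' as used for proportion-valued diversity responses. The beta component is
#' parameterized by mean `mu` in (0,1) and precision `phi` > 0 (shape
#' parameters `mu*phi` and `(1-mu)*phi`). The zero-inflated mixture puts mass
#' `zi` on 0; the zero-one-inflated mixture puts mass `zoi` on {0,1}, split
#' by the conditional-one probability `coi`:
#' \deqn{p(0) = zoi(1-coi), \quad p(1) = zoi \cdot coi, \quad
#'       p(y) = (1-zoi)\,\mathrm{Beta}(y; \mu\phi, (1-\mu)\phi).}
#'
#' @param y observation(s); support `[0,1)` for `dzibeta`, `[0,1]` for
#'   `dzoibeta`, `(0,1)` for `dbeta_mu`.
#' @param mu beta mean in (0,1).
#' @param phi beta precision > 0.
#' @param zi probability of an exact zero.
#' @param zoi probability of a boundary value (0 or 1).
#' @param coi conditional probability that a boundary value is 1.
#' @param log return log density.
#' @return density (or log density) values.
#' @name beta-families
NULL

#' @rdname beta-families
#' @export
dbeta_mu <- function(y, mu, phi, log = FALSE) {
  stopifnot(all(mu > 0 & mu < 1), all(phi > 0))
  stats::dbeta(y, mu * phi, (1 - mu) * phi, log = log)
}

#' @rdname beta-families
#' @export
dzibeta <- function(y, mu, phi, zi, log = FALSE) {
  stopifnot(all(zi >= 0 & zi <= 1))
  if (any(y < 0 | y >= 1)) stop("zero-inflated beta support is [0, 1)")
  ll <- ifelse(y == 0, log(zi),
               log(1 - zi) + dbeta_mu(pmax(y, 1e-300), mu, phi, log = TRUE))
  if (log) ll else exp(ll)
}

#' @rdname beta-families
#' @export
dzoibeta <- function(y, mu, phi, zoi, coi, log = FALSE) {
  stopifnot(all(zoi >= 0 & zoi <= 1), all(coi >= 0 & coi <= 1))
  if (any(y < 0 | y > 1)) stop("zero-one-inflated beta support is [0, 1]")
  ll <- ifelse(y == 0, log(zoi) + log(1 - coi),
        ifelse(y == 1, log(zoi) + log(coi),
               log(1 - zoi) +
                 dbeta_mu(pmin(pmax(y, 1e-300), 1 - 1e-16), mu, phi,
                          log = TRUE)))
  if (log) ll else exp(ll)
}

.families <- c("gaussian", "negbinomial_log", "beta_logit", "zi_beta_logit",
               "zoi_beta_logit")

.family_code <- function(family) {
  match(match.arg(family, .families), .families) - 1L
}

.n_aux <- function(family) {
  switch(family, gaussian = 1L, negbinomial_log = 1L, beta_logit = 1L,
         zi_beta_logit = 2L, zoi_beta_logit = 3L)
}

#' Log likelihood of one family at given parameters
#'
#' Evaluates the family's log density observation-wise; the same densities
#' drive the MCMC backend.
#'
#' @param family one of `gaussian`, `negbinomial_log`, `beta_logit`,
#'   `zi_beta_logit`, `zoi_beta_logit`.
#' @param params named list: `mu` (response-scale mean; for
#'   `negbinomial_log` the mean count, for beta families the beta mean),
#'   plus `sigma` (gaussian), `size` (NB dispersion), `phi` (beta precision),
#'   `zi`, `zoi`, `coi` as applicable.
#' @param y observations.
#' @return vector of log densities.
#' @export
loglik <- function(family, params, y) {
  family <- match.arg(family, .families)
  switch(family,
    gaussian = stats::dnorm(y, params$mu, params$sigma, log = TRUE),
    negbinomial_log = {
      if (any(y < 0) || any(y != round(y))) stop("negative binomial needs counts")
      stats::dnbinom(y, mu = params$mu, size = params$size, log = TRUE)
    },
    beta_logit = {
      if (any(y <= 0 | y >= 1)) stop("beta support is (0, 1)")
      dbeta_mu(y, params$mu, params$phi, log = TRUE)
    },
    zi_beta_logit = dzibeta(y, params$mu, params$phi, params$zi, log = TRUE),
    zoi_beta_logit = dzoibeta(y, params$mu, params$phi, params$zoi,
                              params$coi, log = TRUE))
}

.check_support <- function(family, y) {
  ok <- switch(family,
    gaussian = all(is.finite(y)),
    negbinomial_log = all(y >= 0 & y == round(y)),
    beta_logit = all(y > 0 & y < 1),
    zi_beta_logit = all(y >= 0 & y < 1),
    zoi_beta_logit = all(y >= 0 & y <= 1))
  if (!ok)
    stop("response outside the support of family '", family, "'")
  invisible(TRUE)
}
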