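#' Facets success probability
#'
#' Success probability under the facets extension of the LCDM: the rater's
#' severity enters the logit additively, `plogis(kernel - eta)`. A positive
#' severity lowers, a negative severity raises, the probability of success;
#' with `eta = 0` the model reduces exactly to the rater-free LCDM.
#'
#' @inheritParams lcdm_kernel
#' @param eta Rater severity (real).
#' @return Probability in (0, 1).
#' @export
facets_prob <- function(params, eta, alpha, q_row) {
  stopifnot(is.numeric(eta), length(eta) == 1L, is.finite(eta))
  stats::plogis(lcdm_kernel(params, alpha, q_row) - eta)
}

#' HRM rating-stage probabilities
#'
#' Probability table of the observed dichotomous rating k given the latent
#' ideal category xi. The rating stage is a discretized normal kernel: the
#' probability of rating k is proportional to a normal density with mean
#' `xi - phi` and standard deviation `psi`, normalized over k in \{0, 1\}.
#' For two categories this normalization has the closed form
#' \eqn{P(k=1) = \mathrm{logit}^{-1}\{(2(\xi-\phi) - 1) / (2\psi^2)\}}.
#'
#' `phi` is the rater's severity (positive values depress ratings below the
#' ideal category); `psi` is the rater's variability (larger values make the
#' table flatter, i.e. less reliable ratings).
#'
#' @param xi Latent ideal category, 0 or 1.
#' @param phi Rater severity.
#' @param psi Rater variability; must be strictly positive.
#' @return Named numeric vector `c("0" = P(k=0), "1" = P(k=1))`, summing to 1.
#' @examples
#' hrm_rating_prob(1, phi = 0, psi = 0.5)
#' @export
hrm_rating_prob <- function(xi, phi, psi) {
  if (!is.numeric(psi) || length(psi) != 1L || !is.finite(psi) || psi <= 0) {
    stop("psi (rater variability) must be strictly positive.", call. = FALSE)
  }
  stopifnot(xi %in% c(0, 1), is.numeric(phi), length(phi) == 1L)
  p1 <- stats::plogis((2 * (xi - phi) - 1) / (2 * psi^2))
  c("0" = 1 - p1, "1" = p1)
}

#' HRM latent-category probability
#'
#' Probability that the latent ideal category equals 1 given an attribute
#' profile. The mathematics coincide with [lcdm_prob()]; the category is
#' latent here (the measurement model sits behind a rating stage) rather
#' than observed.
#'
#' @inheritParams lcdm_kernel
#' @return Probability in (0, 1).
#' @export
hrm_category_prob <- function(params, alpha, q_row) {
  lcdm_prob(params, alpha, q_row)
}

#' HRM marginal observed-score probability
#'
#' Marginalizes the latent ideal category out of the two HRM stages:
#' \eqn{P(k=1 \mid \alpha, r) = \sum_{\xi} P(k=1 \mid \xi, r)\, P(\xi \mid
#' \alpha)}. Used in likelihood evaluation and posterior predictive checks.
#'
#' @inheritParams lcdm_kernel
#' @inheritParams hrm_rating_prob
#' @return Probability in \[0, 1\].
#' @export
hrm_marginal_prob <- function(params, alpha, q_row, phi, psi) {
  p <- lcdm_prob(params, alpha, q_row)
  r1 <- hrm_rating_prob(1, phi, psi)[["1"]]
  r0 <- hrm_rating_prob(0, phi, psi)[["1"]]
  p * r1 + (1 - p) * r0
}
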