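# Evaluation machinery: recovery metrics across replications, information
# criteria from the marginal likelihood at the EAP estimates, posterior
# predictive checks with a Bayesian chi-square discrepancy, and fair scores.

#' Bias and RMSE of estimates across replications
#'
#' `bias = mean(est - truth)`, `rmse = sqrt(mean((est - truth)^2))`. With a
#' matrix of estimates (replications in rows) and a truth vector, both are
#' computed per parameter (columns matched to `truth` by name when both are
#' named).
#'
#' @param estimates Numeric vector (one parameter across replications) or
#'   matrix (replications x parameters).
#' @param truth Generating value(s).
#' @return Data frame with columns `bias` and `rmse` (one row per
#'   parameter), or a named list for vector input.
#' @export
bias_rmse <- function(estimates, truth) {
  if (is.matrix(estimates)) {
    if (!is.null(colnames(estimates)) && !is.null(names(truth))) {
      truth <- truth[colnames(estimates)]
    }
    stopifnot(length(truth) == ncol(estimates), nrow(estimates) >= 1)
    err <- sweep(estimates, 2, truth)
    return(data.frame(parameter = colnames(estimates),
                      gen = unname(truth),
                      bias = colMeans(err),
                      rmse = sqrt(colMeans(err^2)),
                      row.names = NULL))
  }
  if (!length(estimates)) stop("no estimates supplied.", call. = FALSE)
  stopifnot(length(truth) == 1)
  err <- estimates - truth
  list(bias = mean(err), rmse = sqrt(mean(err^2)))
}

#' Whole-pattern profile recovery rate
#'
#' Percentage of ratees whose full estimated K-vector matches the generating
#' profile exactly.
#'
#' @param estimated,truth Binary matrices of identical dimension (ratees x
#'   attributes).
#' @return Percentage in \[0, 100\].
#' @export
profile_recovery <- function(estimated, truth) {
  estimated <- as.matrix(estimated); truth <- as.matrix(truth)
  if (!all(dim(estimated) == dim(truth))) {
    stop("estimated and generating profiles differ in dimension.",
         call. = FALSE)
  }
  100 * mean(rowSums(estimated != truth) == 0)
}

#' Attribute-wise recovery rate
#'
#' Percentage of (ratee, attribute) cells classified correctly; a laxer
#' companion to [profile_recovery()].
#'
#' @inheritParams profile_recovery
#' @return Percentage in \[0, 100\].
#' @export
attribute_recovery <- function(estimated, truth) {
  estimated <- as.matrix(estimated); truth <- as.matrix(truth)
  if (!all(dim(estimated) == dim(truth))) {
    stop("estimated and generating profiles differ in dimension.",
         call. = FALSE)
  }
  100 * mean(estimated == truth)
}

#' Akaike and Bayesian information criteria from a log-likelihood
#'
#' `AIC = -2*loglik + 2*p`; `BIC = -2*loglik + p*log(n)`.
#'
#' @param loglik Maximized (or plug-in) log-likelihood.
#' @param p Number of free parameters.
#' @param n Number of observations.
#' @return Named list with `aic` and `bic`.
#' @export
information_criteria <- function(loglik, p, n) {
  list(aic = -2 * loglik + 2 * p, bic = -2 * loglik + p * log(n))
}

# kernel matrix (C x J) from a coefficient vector in the fit's design
.kernel_eval <- function(des, coef) {
  ker <- matrix(0, des$C, des$J)
  for (j in seq_len(des$J)) {
    blk <- (des$offsets[j] + 1):des$offsets[j + 1]
    ker[, j] <- des$Z[, blk, drop = FALSE] %*% coef[blk]
  }
  ker
}

.fit_param_draws <- function(fit) do.call(rbind, fit$draws)
.fit_z_draws <- function(fit) do.call(rbind, fit$z_draws)

# per-observation success probability given one parameter draw and class
# assignments; obs are the fit's prepared (i, j, r, x) vectors
.obs_probs <- function(fit, coef, z, phi = NULL, psi = NULL, eta = NULL) {
  des <- fit$design_info; dat <- fit$data
  ker <- .kernel_eval(des, coef)
  cls <- z[dat$i]
  if (fit$model == "hrm") {
    pxi <- stats::plogis(ker[cbind(cls, dat$j)])
    f1 <- stats::plogis((2 * (1 - phi) - 1) / (2 * psi^2))
    f0 <- stats::plogis((2 * (0 - phi) - 1) / (2 * psi^2))
    pxi * f1[dat$r] + (1 - pxi) * f0[dat$r]
  } else {
    e <- if (is.null(eta)) 0 else eta[dat$r]
    stats::plogis(ker[cbind(cls, dat$j)] - e)
  }
}

.fit_rater_draw <- function(fit, drow) {
  if (fit$model == "hrm") {
    if (!is.null(fit$hrm_fixed)) {
      list(phi = fit$hrm_fixed$phi, psi = fit$hrm_fixed$psi)
    } else {
      list(phi = drow[grep("^phi\\[", fit$par_names)],
           psi = drow[grep("^psi\\[", fit$par_names)])
    }
  } else if (fit$model == "facets") {
    list(eta = drow[grep("^eta\\[", fit$par_names)])
  } else list()
}

#' Marginal observed-data log-likelihood at the EAP estimates
#'
#' Ratee class membership is marginalized over the 2^K latent classes with
#' the estimated class weights; item, rater and weight parameters are
#' plugged in at their EAP values. For HRM fits the latent ideal category is
#' additionally marginalized per response.
#'
#' @param fit A `cdm_fit`.
#' @return Log-likelihood (scalar).
#' @export
model_loglik <- function(fit) {
  stopifnot(inherits(fit, "cdm_fit"))
  .marginal_ll(fit, fit$eap)
}

# marginal observed-data log-likelihood at an arbitrary parameter vector in
# the fit's layout (used for the EAP and for per-chain mode comparison)
.marginal_ll <- function(fit, eap) {
  des <- fit$design_info; dat <- fit$data
  coef <- eap[seq_along(des$names)]
  w <- eap[grep("^pi\\[", fit$par_names)]
  w <- w / sum(w)
  ker <- .kernel_eval(des, coef)
  ll <- matrix(0, dat$N, des$C)
  if (fit$model == "hrm") {
    rp <- .fit_rater_draw(fit, eap)
    f1 <- stats::plogis((2 * (1 - rp$phi) - 1) / (2 * rp$psi^2))
    f0 <- stats::plogis((2 * (0 - rp$phi) - 1) / (2 * rp$psi^2))
    A1 <- matrix(1, dat$N, dat$J); A0 <- matrix(1, dat$N, dat$J)
    id <- cbind(dat$i, dat$j)
    g1 <- ifelse(dat$x == 1, f1[dat$r], 1 - f1[dat$r])
    g0 <- ifelse(dat$x == 1, f0[dat$r], 1 - f0[dat$r])
    for (t in seq_along(dat$x)) {
      A1[id[t, 1], id[t, 2]] <- A1[id[t, 1], id[t, 2]] * g1[t]
      A0[id[t, 1], id[t, 2]] <- A0[id[t, 1], id[t, 2]] * g0[t]
    }
    pxi <- stats::plogis(ker)                 # C x J
    for (c in seq_len(des$C)) {
      pc <- matrix(pxi[c, ], dat$N, dat$J, byrow = TRUE)
      ll[, c] <- rowSums(log(pc * A1 + (1 - pc) * A0))
    }
  } else {
    eta <- if (fit$model == "facets")
      eap[grep("^eta\\[", fit$par_names)] else rep(0, dat$R)
    for (c in seq_len(des$C)) {
      lin <- ker[c, dat$j] - eta[dat$r]
      contrib <- ifelse(dat$x == 1, stats::plogis(lin, log.p = TRUE),
                        stats::plogis(-lin, log.p = TRUE))
      ll[, c] <- as.numeric(rowsum(contrib, dat$i))
    }
  }
  lw <- sweep(ll, 2, log(w), `+`)
  mx <- apply(lw, 1, max)
  sum(mx + log(rowSums(exp(lw - mx))))
}

#' Information criteria for a fitted model
#'
#' Plug-in AIC/BIC from [model_loglik()]: the parameter count includes the
#' item coefficients, free rater parameters (severities lose one degree of
#' freedom to the zero-mean constraint; fixed HRM rater parameters count
#' zero), and the 2^K - 1 free class weights; n is the number of observed
#' scores.
#'
#' @param fit A `cdm_fit`.
#' @return List with `loglik`, `p`, `n`, `aic`, `bic`.
#' @export
fit_ic <- function(fit) {
  stopifnot(inherits(fit, "cdm_fit"))
  des <- fit$design_info; dat <- fit$data
  p <- length(des$names) +
    switch(fit$profile_prior,
           saturated = des$C - 1L,
           independent = ncol(des$pat),
           uniform = 0L) +
    switch(fit$model,
           standard = 0L,
           facets = dat$R - 1L,
           hrm = if (is.null(fit$hrm_fixed)) 2L * dat$R else 0L)
  n <- length(dat$x)
  ll <- model_loglik(fit)
  c(list(loglik = ll, p = p, n = n), information_criteria(ll, p, n))
}

#' Posterior predictive p-value of the Bayesian chi-square discrepancy
#'
#' For each retained draw, computes the standardized Pearson discrepancy
#' \eqn{X^2 = \sum (O - E)^2 / (E(1 - E))} over all observed
#' (ratee, item, rater) scores, with E the model probability given that
#' draw's parameters and class assignments, and the same discrepancy for a
#' replicated dataset drawn from the same parameters. The ppp is the
#' fraction of draws whose replicated discrepancy is at least the realized
#' one; values near 0 or 1 indicate misfit. E is clipped to
#' \[1e-6, 1 - 1e-6\].
#'
#' @param fit A `cdm_fit`.
#' @param ndraws Optional cap on the number of retained draws used (evenly
#'   subsampled).
#' @param seed Optional seed for the replicate draws.
#' @return List with `ppp` and the per-draw discrepancies (`realized`,
#'   `replicated`).
#' @export
ppp_chisq <- function(fit, ndraws = NULL, seed = NULL) {
  stopifnot(inherits(fit, "cdm_fit"))
  if (!is.null(seed)) set.seed(seed)
  des <- fit$design_info; dat <- fit$data
  draws <- .fit_param_draws(fit)
  zdr <- .fit_z_draws(fit)
  idx <- seq_len(nrow(draws))
  if (!is.null(ndraws) && ndraws < length(idx)) {
    idx <- unique(round(seq(1, length(idx), length.out = ndraws)))
  }
  x <- dat$x
  realized <- replicated <- numeric(length(idx))
  for (u in seq_along(idx)) {
    d <- idx[u]
    drow <- draws[d, ]
    rp <- .fit_rater_draw(fit, drow)
    E <- .obs_probs(fit, drow[seq_along(des$names)], zdr[d, ],
                    phi = rp$phi, psi = rp$psi, eta = rp$eta)
    E <- pmin(pmax(E, 1e-6), 1 - 1e-6)
    denom <- E * (1 - E)
    realized[u] <- sum((x - E)^2 / denom)
    xrep <- stats::rbinom(length(E), 1L, E)
    replicated[u] <- sum((xrep - E)^2 / denom)
  }
  list(ppp = mean(replicated >= realized), realized = realized,
       replicated = replicated)
}

#' Fair scores: expected totals purged of rater effects
#'
#' The fair score of a profile is the expected test total under the
#' rater-free measurement kernel, \eqn{\sum_j P(X_j = 1 \mid \alpha)};
#' contrasting it with observed (raw) totals separates what a ratee
#' deserves from what their raters gave them.
#'
#' @param profiles Binary profile vector or matrix (ratees x attributes).
#' @param item_params List of [item_params()], one per item.
#' @param qmatrix A `qmatrix`.
#' @return Numeric vector of expected totals, one per profile.
#' @export
fair_scores <- function(profiles, item_params, qmatrix) {
  if (!is.matrix(profiles)) profiles <- matrix(profiles, nrow = 1)
  stopifnot(ncol(profiles) == ncol(qmatrix),
            length(item_params) == nrow(qmatrix))
  ker <- .kernel_matrix(item_params, qmatrix)
  p <- stats::plogis(ker)
  rowSums(p[profile_index(profiles), , drop = FALSE])
}

#' Observed-versus-fair score table
#'
#' Builds the bookkeeping table contrasting observed totals with fair
#' scores: the observed total is each ratee's raw score total averaged over
#' their raters, the fair score is the expected total at the ratee's
#' classified profile under the fitted item parameters, and the difference
#' is observed minus fair. Ratees scored only by severe raters show large
#' negative differences, and the observed and fair rankings can disagree
#' substantially.
#'
#' @param fit A `cdm_fit` (standard or facets; HRM fits use the
#'   latent-category kernel).
#' @return Data frame with one row per ratee: `ratee`, `profile`,
#'   `observed`, `fair`, `difference`.
#' @export
fair_score_report <- function(fit) {
  stopifnot(inherits(fit, "cdm_fit"))
  des <- fit$design_info; dat <- fit$data
  ker <- .kernel_eval(des, fit$eap[seq_along(des$names)])
  p <- stats::plogis(ker)
  prof <- fit$profiles
  cls <- profile_index(prof)
  fair <- rowSums(p[cls, , drop = FALSE])
  nr <- tapply(dat$r, dat$i, function(r) length(unique(r)))
  tot <- tapply(dat$x, dat$i, sum)
  observed <- as.numeric(tot) / as.numeric(nr)
  ratee <- fit$data$levels$ratee
  if (!is.null(fit$real_map)) ratee <- seq_len(nrow(prof))
  data.frame(ratee = ratee,
             profile = apply(prof, 1, paste, collapse = ","),
             observed = observed, fair = fair,
             difference = observed - fair)
}
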