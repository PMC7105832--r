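#' Prior specification for model fitting
#'
#' Defaults follow the estimation conventions of the recovery studies:
#' diffuse normal(0, 4) priors on intercepts, main effects (truncated to be
#' positive, which enforces monotonicity) and interactions, a normal(0, 4)
#' prior on facets severities (a normal(0, 1) severity prior is customary in
#' sparser empirical fits; set `eta_sd = 1` for that), a normal(0, 1) prior
#' on HRM severities, and a log-normal(0, 4) prior on HRM variabilities.
#'
#' @param intercept_sd,main_sd,interaction_sd Prior SDs of the item kernel
#'   coefficients.
#' @param eta_sd Prior SD of facets severities.
#' @param phi_sd Prior SD of HRM severities.
#' @param log_psi_sd Prior SD of log HRM variabilities.
#' @return Object of class `prior_spec`.
#' @export
prior_spec <- function(intercept_sd = 4, main_sd = 4, interaction_sd = 4,
                       eta_sd = 4, phi_sd = 1, log_psi_sd = 4) {
  vals <- c(intercept_sd, main_sd, interaction_sd, eta_sd, phi_sd, log_psi_sd)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all prior scale parameters must be positive.", call. = FALSE)
  }
  structure(list(intercept_sd = intercept_sd, main_sd = main_sd,
                 interaction_sd = interaction_sd, eta_sd = eta_sd,
                 phi_sd = phi_sd, log_psi_sd = log_psi_sd),
            class = "prior_spec")
}

#' MCMC chain schedule
#'
#' The default (10,000 iterations, 5,000 burn-in, keep one draw in ten, two
#' chains) mirrors common practice for these models; the recovery harnesses
#' use a shorter 2,000/1,000/10 schedule.
#'
#' @param iterations Total iterations per chain.
#' @param burnin Burn-in iterations discarded (must be < `iterations`);
#'   proposal step sizes adapt only during burn-in.
#' @param thin Keep one draw in `thin`.
#' @param chains Number of chains (>= 2, so convergence can be assessed).
#' @return Object of class `chain_schedule`.
#' @export
chain_schedule <- function(iterations = 10000, burnin = 5000, thin = 10,
                           chains = 2) {
  stopifnot(iterations >= 2, thin >= 1, chains >= 1)
  if (burnin >= iterations) {
    stop("burn-in must be shorter than the chain.", call. = FALSE)
  }
  if (chains < 2) {
    stop("at least 2 chains are required (convergence diagnostics need them).",
         call. = FALSE)
  }
  structure(list(iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 chains = as.integer(chains)),
            class = "chain_schedule")
}

# Class design over the 2^K profiles: per-item coefficient blocks.
# ptype codes: 0 intercept, 1 positive-constrained, 2 unconstrained effect.
.class_design <- function(qmatrix, cdm, main_effects) {
  pat <- attribute_patterns(ncol(qmatrix))
  C <- nrow(pat); J <- nrow(qmatrix)
  cols <- list(); ptype <- integer(0); nms <- character(0)
  offsets <- integer(J + 1)
  for (j in seq_len(J)) {
    req <- which(qmatrix[j, ] == 1)
    m <- length(req)
    cols[[length(cols) + 1]] <- rep(1, C)
    ptype <- c(ptype, 0L)
    nms <- c(nms, sprintf("lambda0[%d]", j))
    if (cdm == "dina") {
      cols[[length(cols) + 1]] <- apply(pat[, req, drop = FALSE], 1, prod)
      ptype <- c(ptype, 1L)
      nms <- c(nms, sprintf("delta[%d]", j))
    } else if (main_effects == "shared") {
      if (m > 2) {
        stop("shared main-effect kernels support at most two attributes per ",
             "item; use main_effects = \"per_attribute\".", call. = FALSE)
      }
      cols[[length(cols) + 1]] <- rowSums(pat[, req, drop = FALSE])
      ptype <- c(ptype, 1L)
      nms <- c(nms, sprintf("lambda1[%d]", j))
      if (m == 2) {
        cols[[length(cols) + 1]] <- pat[, req[1]] * pat[, req[2]]
        ptype <- c(ptype, 2L)
        nms <- c(nms, sprintf("lambda2[%d]", j))
      }
    } else {
      for (k in req) {
        cols[[length(cols) + 1]] <- pat[, k]
        ptype <- c(ptype, 1L)
        nms <- c(nms, sprintf("lambda1[%d,%d]", j, k))
      }
      if (m >= 2) {
        prs <- utils::combn(req, 2)
        for (s in seq_len(ncol(prs))) {
          cols[[length(cols) + 1]] <- pat[, prs[1, s]] * pat[, prs[2, s]]
          ptype <- c(ptype, 2L)
          nms <- c(nms, sprintf("lambda2[%d,%d.%d]", j, prs[1, s], prs[2, s]))
        }
      }
    }
    offsets[j + 1] <- length(cols)
  }
  K <- ncol(qmatrix)
  # class pairs differing by mastery of exactly one attribute (0-based),
  # used to enforce kernel monotonicity during estimation
  lo <- integer(0); hi <- integer(0)
  for (c0 in 0:(C - 1)) {
    for (k in seq_len(K)) {
      bit <- 2L^(K - k)
      if (bitwAnd(c0, bit) == 0L) { lo <- c(lo, c0); hi <- c(hi, c0 + bit) }
    }
  }
  list(Z = do.call(cbind, cols), offsets = offsets, ptype = ptype,
       names = nms, pat = pat, C = C, J = J,
       mono_pairs = rbind(lo, hi),
       attr_items = lapply(seq_len(ncol(qmatrix)),
                           function(k) which(qmatrix[, k] == 1)))
}

.prepare_ratings <- function(ratings, qmatrix) {
  rt <- if (inherits(ratings, "sim_ratings")) ratings$ratings else ratings
  need <- c("ratee", "item", "rater", "score")
  if (!all(need %in% names(rt))) {
    stop("ratings need columns ratee, item, rater, score.", call. = FALSE)
  }
  if (!all(rt$score %in% c(0, 1))) {
    stop("scores must all be 0 or 1.", call. = FALSE)
  }
  key <- paste(rt$ratee, rt$item, rt$rater)
  if (anyDuplicated(key)) {
    stop("duplicate (ratee, item, rater) triple: ", key[which(duplicated(key))[1]],
         call. = FALSE)
  }
  sort_lv <- function(x) {
    u <- unique(x)
    if (is.numeric(x) || !anyNA(suppressWarnings(as.numeric(u)))) {
      u[order(as.numeric(u))]
    } else sort(as.character(u))
  }
  lv_i <- sort_lv(rt$ratee); lv_j <- sort_lv(rt$item); lv_r <- sort_lv(rt$rater)
  if (length(lv_j) != nrow(qmatrix)) {
    stop(sprintf("ratings reference %d items but the Q-matrix has %d rows.",
                 length(lv_j), nrow(qmatrix)), call. = FALSE)
  }
  list(i = match(rt$ratee, lv_i), j = match(rt$item, lv_j),
       r = match(rt$rater, lv_r), x = as.integer(rt$score),
       N = length(lv_i), J = length(lv_j), R = length(lv_r),
       levels = list(ratee = lv_i, item = lv_j, rater = lv_r))
}

.init_chain <- function(des, dat, priors, model, hrm_fixed) {
  # Data-informed start. Class memberships come from a score heuristic (mark
  # attribute k mastered when the ratee beats the pool average on the items
  # requiring it); item coefficients come from method-of-moments group means
  # under those memberships, de-attenuated through the rating stage for HRM
  # fits. Uniform-random starts can strand a chain in a collapsed mode for
  # extreme-base-rate attributes (visible as a large R-hat), and far-off
  # coefficient starts mix slowly on weak data; both motivated this.
  K <- ncol(des$pat)
  alpha0 <- matrix(0L, dat$N, K)
  for (k in seq_len(K)) {
    jk <- des$attr_items[[k]]
    sel <- dat$j %in% jk
    m_i <- rep(0.5, dat$N)
    agg <- tapply(dat$x[sel], dat$i[sel], mean)
    m_i[as.integer(names(agg))] <- agg
    alpha0[, k] <- as.integer(m_i >= mean(dat$x[sel]))
  }
  phi <- if (is.null(hrm_fixed)) stats::rnorm(dat$R, 0, 0.2) else hrm_fixed$phi
  psi <- if (is.null(hrm_fixed)) exp(stats::rnorm(dat$R, 0, 0.25)) else hrm_fixed$psi
  deatt <- identity
  if (model == "hrm") {
    f1b <- mean(stats::plogis((2 * (1 - phi) - 1) / (2 * psi^2)))
    f0b <- mean(stats::plogis((2 * (0 - phi) - 1) / (2 * psi^2)))
    deatt <- function(m) (m - f0b) / max(f1b - f0b, 0.1)
  }
  clamp <- function(m) pmin(pmax(m, 0.05), 0.95)
  gmean <- function(j, keep) {
    sel <- dat$j == j & keep[dat$i]
    if (!any(sel)) return(NA_real_)
    mean(dat$x[sel])
  }
  coef <- numeric(length(des$ptype))
  jit <- function() exp(stats::rnorm(1, 0, 0.15))
  for (j in seq_len(des$J)) {
    blk <- (des$offsets[j] + 1):des$offsets[j + 1]
    req <- which(vapply(des$attr_items, function(it) j %in% it, TRUE))
    full <- rowSums(alpha0[, req, drop = FALSE]) == length(req)
    none <- rowSums(alpha0[, req, drop = FALSE]) == 0
    m0 <- gmean(j, none); m1 <- gmean(j, full)
    if (is.na(m0)) m0 <- 0.2
    if (is.na(m1)) m1 <- 0.8
    icpt <- stats::qlogis(clamp(deatt(m0))) + stats::rnorm(1, 0, 0.2)
    total <- max(stats::qlogis(clamp(deatt(m1))) - icpt, 0.5)
    for (p in blk) {
      coef[p] <- switch(as.character(des$ptype[p]),
        "0" = icpt,
        "1" = if (length(req) == 1 || des$ptype[max(blk)] != 2)
                total * jit() else 0.35 * total * jit(),
        "2" = 0.3 * total * jit())
    }
  }
  eta <- stats::rnorm(dat$R, 0, 0.25); eta <- eta - mean(eta)
  flip <- matrix(stats::runif(length(alpha0)) < 0.05, nrow(alpha0))
  alpha0[flip] <- 1L - alpha0[flip]
  z <- profile_index(alpha0)
  list(coef = coef, eta = eta, phi = phi, psi = psi, z = z)
}

#' Fit a diagnostic classification model by Metropolis-within-Gibbs
#'
#' Bayesian estimation of three model families on long-format dichotomous
#' ratings: `"standard"` (rater-free LCDM/DINA; with multiple raters the
#' scheme decides whether raters' scores are treated as virtual items with
#' identical parameters or as virtual examinees whose attribute posteriors
#' are averaged), `"facets"` (additive rater severity in the logit, zero-mean
#' identified), and `"hrm"` (signal-detection rating stage over a latent
#' ideal category; the category is marginalized analytically in every full
#' conditional). Latent class membership is sampled from its categorical
#' full conditional under the chosen profile prior (see `profile_prior`);
#' item and rater parameters move by adaptive random-walk Metropolis
#' (adaptation during burn-in only).
#'
#' @param ratings Long-format data frame with columns
#'   `ratee, item, rater, score`, or a `sim_ratings` object.
#' @param qmatrix A `qmatrix`; rows must match the items referenced.
#' @param model `"standard"`, `"facets"`, or `"hrm"`.
#' @param cdm Kernel family: `"saturated"` or `"dina"`.
#' @param main_effects For saturated kernels: `"shared"` (one main-effect
#'   parameter per item applied to each required attribute, the layout of
#'   the recovery studies' generating model) or `"per_attribute"`.
#' @param standard_scheme How a standard fit treats multiple raters.
#' @param priors A [prior_spec()].
#' @param schedule A [chain_schedule()].
#' @param seed Integer seed; every chain and proposal draw descends from it.
#' @param hrm_phi,hrm_psi Optional numeric vectors fixing the HRM rater
#'   parameters (one per rater); when both are given they are held at those
#'   values instead of being estimated.
#' @param profile_prior Estimation-side prior on the latent profiles:
#'   `"independent"` (attribute mastery rates with Beta(1, 1) priors,
#'   attributes independent given the rates; the default, and the
#'   formulation under which the recovery studies reproduce published
#'   behavior), `"saturated"` (a categorical over all 2^K classes with a
#'   uniform Dirichlet prior, assumption-free but more adaptive), or
#'   `"uniform"` (fixed equal weights, i.e. independent Bernoulli(0.5)
#'   attributes).
#' @param param_subiterations Number of item/rater Metropolis sub-cycles per
#'   class-membership draw (the membership draw dominates the sweep cost;
#'   extra cheap parameter cycles improve mixing along flat posterior
#'   ridges).
#' @param update_coef,prior_only Diagnostic hooks: freeze the item
#'   coefficients at their initial values, or drop the likelihood entirely
#'   (prior recovery checks).
#' @param init Optional list of initial values (`coef`, `eta`, `phi`, `psi`,
#'   `z`) used for every chain.
#' @param quiet Suppress progress messages.
#' @return Object of class `cdm_fit`; see [mastery_probs()],
#'   [classify_profiles()], [summary.cdm_fit()].
#' @export
fit_cdm <- function(ratings, qmatrix,
                    model = c("standard", "facets", "hrm"),
                    cdm = c("saturated", "dina"),
                    main_effects = c("per_attribute", "shared"),
                    standard_scheme = c("virtual_items", "virtual_examinees"),
                    priors = prior_spec(), schedule = chain_schedule(),
                    seed = NULL, hrm_phi = NULL, hrm_psi = NULL,
                    profile_prior = c("independent", "saturated", "uniform"),
                    param_subiterations = 3, update_coef = TRUE,
                    prior_only = FALSE, init = NULL, quiet = TRUE) {
  model <- match.arg(model)
  cdm <- match.arg(cdm)
  main_effects <- match.arg(main_effects)
  standard_scheme <- match.arg(standard_scheme)
  profile_prior <- match.arg(profile_prior)
  weight_mode <- c(uniform = 0L, saturated = 1L, independent = 2L)[profile_prior]
  stopifnot(inherits(priors, "prior_spec"), inherits(schedule, "chain_schedule"))
  qmatrix <- as_qmatrix(qmatrix)
  if (!is.null(seed)) set.seed(seed)

  dat <- .prepare_ratings(ratings, qmatrix)
  real_map <- NULL
  if (model == "standard" && standard_scheme == "virtual_examinees") {
    vkey <- paste(dat$i, dat$r)
    vlv <- unique(vkey)
    real_map <- as.integer(vapply(strsplit(vlv, " "), `[[`, "", 1))
    dat$i <- match(vkey, vlv)
    dat$r <- rep(1L, length(dat$r))
    dat$N <- length(vlv)
    dat$R <- 1L
  } else if (model == "standard" && standard_scheme == "virtual_items") {
    # identical parameters across a ratee's raters: scores enter as extra
    # observations of the same item, which the zero-severity sampler gives
    # automatically (eta fixed at 0)
  }
  if (model == "facets") {
    A <- matrix(FALSE, dat$N, dat$R)
    A[cbind(dat$i, dat$r)] <- TRUE
    chk <- design_connected(structure(list(assignment = A), class = "rating_design"))
    if (!isTRUE(chk)) {
      stop("facets fit is unidentified: ", chk, call. = FALSE)
    }
  }

  des <- .class_design(qmatrix, cdm, main_effects)
  P <- length(des$ptype)
  prior_sd <- c(priors$intercept_sd, priors$main_sd,
                priors$interaction_sd)[des$ptype + 1]
  hrm_fixed <- NULL
  if (model == "hrm" && !is.null(hrm_phi) && !is.null(hrm_psi)) {
    stopifnot(length(hrm_phi) %in% c(1L, dat$R), length(hrm_psi) %in% c(1L, dat$R))
    hrm_fixed <- list(phi = rep_len(hrm_phi, dat$R),
                      psi = rep_len(hrm_psi, dat$R))
    if (any(hrm_fixed$psi <= 0)) stop("psi must be positive.", call. = FALSE)
  }

  X <- NULL
  if (model != "hrm") {
    X <- matrix(-1L, dat$N, dat$J * dat$R)
    X[cbind(dat$i, (dat$j - 1L) * dat$R + dat$r)] <- dat$x
  }

  run_chain <- function(sched) {
    ini <- if (is.null(init)) .init_chain(des, dat, priors, model, hrm_fixed)
           else utils::modifyList(.init_chain(des, dat, priors, model, hrm_fixed),
                                  init)
    for (attempt in 1:3) {
      res <- tryCatch({
        if (model == "hrm") {
          hrm_mwg(dat$i - 1L, dat$j - 1L, dat$r - 1L, dat$x,
                  dat$N, dat$J, dat$R,
                  des$Z, des$offsets, des$ptype, prior_sd,
                  priors$phi_sd, priors$log_psi_sd,
                  update_coef, is.null(hrm_fixed), weight_mode, prior_only,
                  as.integer(param_subiterations),
                  sched$iterations, sched$burnin, sched$thin,
                  ini$coef, ini$phi, ini$psi, ini$z, des$pat, des$mono_pairs)
        } else {
          facets_mwg(X, des$Z, des$offsets, des$ptype, dat$R, prior_sd,
                     priors$eta_sd, update_coef, model == "facets",
                     weight_mode, prior_only, as.integer(param_subiterations),
                     sched$iterations, sched$burnin, sched$thin,
                     ini$coef, if (model == "facets") ini$eta else numeric(dat$R),
                     ini$z, des$pat, des$mono_pairs)
        }
      }, error = function(e) e)
      if (!inherits(res, "error") && all(is.finite(res$draws))) return(res)
      if (attempt == 3) {
        stop("sampler failed to initialize with a finite posterior after 3 ",
             "attempts: ",
             if (inherits(res, "error")) conditionMessage(res) else
               "non-finite draws", call. = FALSE)
      }
      ini <- .init_chain(des, dat, priors, model, hrm_fixed)
    }
  }

  par_names <- des$names
  if (model == "facets") par_names <- c(par_names, sprintf("eta[%d]", seq_len(dat$R)))
  if (model == "hrm") par_names <- c(par_names,
                                     sprintf("phi[%d]", seq_len(dat$R)),
                                     sprintf("psi[%d]", seq_len(dat$R)))
  wt_names <- sprintf("pi[%d]", seq_len(des$C))

  # Restricted latent class models can harbor a degenerate "attribute
  # collapse" mode far below the dominant mode in posterior density; a chain
  # stuck there shows up as a large R-hat. Convergence failures therefore
  # trigger a bounded number of full restarts with fresh initial values, and
  # the best-converged attempt is kept (with a warning if still above 1.5).
  best <- NULL
  for (attempt in 1:4) {
    sched_a <- schedule
    if (attempt == 4) {
      # last resort: one attempt with a doubled chain (slow mixing rather
      # than a stuck mode may be the cause)
      sched_a$iterations <- 2L * schedule$iterations
      sched_a$burnin <- 2L * schedule$burnin
    }
    chains <- vector("list", schedule$chains)
    for (ch in seq_len(schedule$chains)) {
      if (!quiet) message(sprintf("attempt %d, chain %d/%d ...", attempt, ch,
                                  schedule$chains))
      chains[[ch]] <- run_chain(sched_a)
    }
    rh <- gelman_rubin(lapply(chains, function(r)
      r$draws[, seq_len(P), drop = FALSE]))
    worst <- max(rh, na.rm = TRUE)
    if (is.null(best) || worst < best$worst) best <- list(chains = chains,
                                                          worst = worst)
    if (worst < 1.5) break
    if (attempt == 4) {
      warning(sprintf(paste0("structural parameters did not reach R-hat < ",
                             "1.5 after restarts and an extended chain ",
                             "(worst %.2f); inspect the chains."),
                      best$worst), call. = FALSE)
    }
  }
  chains <- best$chains

  extract_draws <- function(res) {
    d <- res$draws
    if (model == "standard") {
      d <- d[, c(seq_len(P), P + dat$R + seq_len(des$C)), drop = FALSE]
    } else if (model == "hrm" && !is.null(hrm_fixed)) {
      d <- d[, c(seq_len(P), P + 2 * dat$R + seq_len(des$C)), drop = FALSE]
      # fixed phi/psi columns dropped: they are not parameters here
    }
    colnames(d) <- if (model == "standard" ||
                       (model == "hrm" && !is.null(hrm_fixed)))
      c(des$names, wt_names) else c(par_names, wt_names)
    d
  }
  draw_list <- lapply(chains, extract_draws)
  keep_ch <- seq_along(chains)
  rhat <- gelman_rubin(draw_list)
  all_draws <- do.call(rbind, draw_list[keep_ch])
  eap <- colMeans(all_draws)
  psd <- apply(all_draws, 2, stats::sd)

  cls <- Reduce(`+`, lapply(chains[keep_ch], `[[`, "cls_probs")) /
    length(keep_ch)
  if (!is.null(real_map)) {
    # virtual-examinee averaging: attribute posteriors averaged over each
    # real ratee's virtual copies
    mast_v <- cls %*% des$pat
    n_real <- max(real_map)
    mast <- matrix(0, n_real, ncol(des$pat))
    cls_real <- matrix(0, n_real, des$C)
    cnt <- tabulate(real_map, n_real)
    for (v in seq_len(nrow(mast_v))) {
      mast[real_map[v], ] <- mast[real_map[v], ] + mast_v[v, ]
      cls_real[real_map[v], ] <- cls_real[real_map[v], ] + cls[v, ]
    }
    mast <- mast / cnt
    cls_out <- cls_real / cnt
  } else {
    mast <- cls %*% des$pat
    cls_out <- cls
  }
  colnames(mast) <- colnames(qmatrix)

  fit <- structure(list(
    model = model, cdm = cdm, main_effects = main_effects,
    profile_prior = profile_prior,
    standard_scheme = if (model == "standard") standard_scheme else NULL,
    qmatrix = qmatrix, design_info = des, data = dat, real_map = real_map,
    priors = priors, schedule = schedule, seed = seed,
    hrm_fixed = hrm_fixed,
    par_names = colnames(draw_list[[1]]),
    draws = draw_list,
    z_draws = lapply(chains, `[[`, "z_draws"),
    accept = lapply(chains, `[[`, "accept"),
    eap = eap, sd = psd, rhat = rhat,
    class_probs = cls_out, mastery = mast,
    profiles = (mast >= 0.5) * 1L), class = "cdm_fit")

  if (best$worst >= 1.5 && length(chains) > 1) {
    # disagreeing chains: one may be stuck in a dominated mode whose
    # posterior mass is negligible (log-likelihood hundreds of units below
    # the leader); summarizing over it would corrupt the EAPs, so dominated
    # chains are excluded from the summaries (R-hat still reports all)
    ll_ch <- vapply(draw_list, function(d) .marginal_ll(fit, colMeans(d)), 0)
    keep_ch <- which(ll_ch > max(ll_ch) - 50)
    if (length(keep_ch) < length(chains)) {
      warning(sprintf(paste0("excluding %d chain(s) stuck in a dominated ",
                             "mode (log-likelihood gap %.0f) from posterior ",
                             "summaries."), length(chains) - length(keep_ch),
                      max(ll_ch) - min(ll_ch)), call. = FALSE)
      all_draws <- do.call(rbind, draw_list[keep_ch])
      fit$eap <- colMeans(all_draws)
      fit$sd <- apply(all_draws, 2, stats::sd)
      cls <- Reduce(`+`, lapply(chains[keep_ch], `[[`, "cls_probs")) /
        length(keep_ch)
      if (!is.null(real_map)) {
        mast_v <- cls %*% des$pat
        mast <- matrix(0, max(real_map), ncol(des$pat))
        cls_real <- matrix(0, max(real_map), des$C)
        cnt <- tabulate(real_map, max(real_map))
        for (v in seq_len(nrow(mast_v))) {
          mast[real_map[v], ] <- mast[real_map[v], ] + mast_v[v, ]
          cls_real[real_map[v], ] <- cls_real[real_map[v], ] + cls[v, ]
        }
        fit$mastery <- mast / cnt
        fit$class_probs <- cls_real / cnt
      } else {
        fit$mastery <- cls %*% des$pat
        fit$class_probs <- cls
      }
      colnames(fit$mastery) <- colnames(qmatrix)
      fit$profiles <- (fit$mastery >= 0.5) * 1L
      fit$draws <- draw_list[keep_ch]
      fit$z_draws <- fit$z_draws[keep_ch]
    }
  }

  if (model == "hrm" && is.null(hrm_fixed)) {
    psis <- eap[grep("^psi\\[", names(eap))]
    if (any(psis < 0.2)) {
      warning("posterior rater variability below 0.2 for rater(s) ",
              paste(which(psis < 0.2), collapse = ", "),
              ": the corresponding severities are weakly identified ",
              "(the severity posterior flattens as variability shrinks).",
              call. = FALSE)
    }
  }
  fit
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic two-part variance ratio computed per parameter from two or more
#' chains of equal retained length: with m chains of n draws,
#' \eqn{\hat R = \sqrt{((n-1)/n\, W + B/n) / W}} where W is the mean
#' within-chain variance and B/n the between-chain variance of the chain
#' means. Values below 1.1 are conventionally read as converged; parameters
#' at or above 1.1 are flagged in the result's `"flagged"` attribute.
#' Parameters constant in all chains return 1.
#'
#' @param chains List (length >= 2) of numeric matrices, retained draws by
#'   parameters, with identical dimensions.
#' @return Named numeric vector of R-hat values.
#' @export
gelman_rubin <- function(chains) {
  if (!is.list(chains) || length(chains) < 2) {
    stop("at least 2 chains are required to compute R-hat.", call. = FALSE)
  }
  dims <- lapply(chains, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1) {
    stop("all chains must have identical dimensions.", call. = FALSE)
  }
  m <- length(chains)
  n <- nrow(chains[[1]])
  if (n < 2) stop("chains must contain at least 2 retained draws.", call. = FALSE)
  means <- sapply(chains, colMeans)                       # P x m
  vars <- sapply(chains, function(x) apply(x, 2, stats::var))
  if (is.null(dim(means))) { means <- rbind(means); vars <- rbind(vars) }
  W <- rowMeans(vars)
  B_over_n <- apply(means, 1, stats::var)                 # var of chain means
  vplus <- (n - 1) / n * W + B_over_n
  rhat <- sqrt(vplus / W)
  rhat[W < 1e-300] <- 1
  names(rhat) <- colnames(chains[[1]])
  attr(rhat, "flagged") <- names(rhat)[!is.na(rhat) & rhat >= 1.1]
  rhat
}

#' Posterior attribute-mastery probabilities
#'
#' @param fit A `cdm_fit`.
#' @return N x K matrix of posterior mastery probabilities.
#' @export
mastery_probs <- function(fit) {
  stopifnot(inherits(fit, "cdm_fit"))
  fit$mastery
}

#' Posterior latent-class probabilities
#'
#' @param fit A `cdm_fit`.
#' @return N x 2^K matrix; rows sum to 1 (classes in [attribute_patterns()]
#'   order).
#' @export
class_probs <- function(fit) {
  stopifnot(inherits(fit, "cdm_fit"))
  fit$class_probs
}

#' Classify attribute profiles from posterior mastery probabilities
#'
#' Attribute-wise threshold at 0.5; a probability of exactly 0.5 classifies
#' as mastery (ties resolve to 1).
#'
#' @param x A `cdm_fit` or a numeric matrix of mastery probabilities.
#' @return Integer matrix of 0/1 profiles.
#' @export
classify_profiles <- function(x) {
  m <- if (inherits(x, "cdm_fit")) x$mastery else as.matrix(x)
  stopifnot(all(m >= 0 & m <= 1))
  (m >= 0.5) * 1L
}

#' @export
print.cdm_fit <- function(x, ...) {
  cat(sprintf("<cdm_fit: %s %s, %d ratees x %d items x %d raters>\n",
              x$model, x$cdm, if (is.null(x$real_map)) x$data$N else
                max(x$real_map), x$data$J, x$data$R))
  cat(sprintf("  chains: %d x %d retained draws; max R-hat %.3f%s\n",
              length(x$draws), nrow(x$draws[[1]]), max(x$rhat, na.rm = TRUE),
              if (length(attr(x$rhat, "flagged")))
                sprintf(" (%d parameter(s) >= 1.1)",
                        length(attr(x$rhat, "flagged"))) else ""))
  invisible(x)
}

#' Summarize a fitted model
#'
#' @param object A `cdm_fit`.
#' @param ... Unused.
#' @return Data frame of EAP, posterior SD and R-hat per parameter.
#' @export
summary.cdm_fit <- function(object, ...) {
  data.frame(parameter = names(object$eap), eap = unname(object$eap),
             sd = unname(object$sd), rhat = unname(object$rhat))
}
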