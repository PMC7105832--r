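# Parameter-recovery study harnesses. Study one: facets-generated data under
# four rating designs, fit with the facets model and with the rater-free
# standard model (virtual items with identical parameters). Study two:
# HRM-generated data under the complete design with three or six raters, fit
# with the HRM (rater parameters held at their generating values) and with
# the standard model treating each rater's ratings as a virtual examinee
# whose attribute posteriors are averaged.

.study_truth <- function(with_eta = TRUE) {
  ip <- sim_item_params()
  l0 <- vapply(ip, `[[`, 0, "intercept")
  l1 <- vapply(ip, function(p) p$main_effects[[1]], 0)
  tr <- c(stats::setNames(l0, sprintf("lambda0[%d]", 1:10)),
          stats::setNames(l1, sprintf("lambda1[%d]", 1:10)),
          stats::setNames(vapply(ip[6:10], function(p) p$interactions[[1]], 0),
                          sprintf("lambda2[%d]", 6:10)))
  if (with_eta) {
    tr <- c(tr, stats::setNames(sim_rater_severities(),
                                sprintf("eta[%d]", 1:10)))
  }
  tr
}

.reduced_schedule <- function() chain_schedule(2000, 1000, 10, 2)

.run_conditions <- function(conditions, reps, schedule, seed, simulate_fn,
                            fit_fn, truth_fn, N, quiet) {
  res <- list()
  for (ci in seq_len(nrow(conditions))) {
    key <- paste(conditions[ci, ], collapse = ".")
    res[[key]] <- list(recovery = numeric(reps), attr_recovery = numeric(reps),
                       eap = NULL)
  }
  for (rep in seq_len(reps)) {
    for (ci in seq_len(nrow(conditions))) {
      cond <- conditions[ci, ]
      key <- paste(cond, collapse = ".")
      sim_seed <- seed + 10000L * rep + 100L * match(cond[[1]],
                                                    unique(conditions[[1]]))
      sim <- simulate_fn(cond, sim_seed)
      fit <- fit_fn(cond, sim, sim_seed + ci)
      if (!quiet) {
        message(sprintf("rep %d | %s: recovery %.2f%%", rep, key,
                        profile_recovery(fit$profiles, sim$truth$alpha)))
      }
      res[[key]]$recovery[rep] <- profile_recovery(fit$profiles,
                                                   sim$truth$alpha)
      res[[key]]$attr_recovery[rep] <- attribute_recovery(fit$profiles,
                                                          sim$truth$alpha)
      tr <- truth_fn(cond)
      eap <- fit$eap[intersect(names(tr), names(fit$eap))]
      if (is.null(res[[key]]$eap)) {
        res[[key]]$eap <- matrix(NA_real_, reps, length(eap),
                                 dimnames = list(NULL, names(eap)))
      }
      res[[key]]$eap[rep, ] <- eap
      res[[key]]$truth <- tr[names(eap)]
    }
  }
  res
}

#' Run the facets-model recovery study
#'
#' Simulates dichotomous facets-model ratings (500 ratees, 10 items over 5
#' attributes, 10 raters, profiles drawn with inter-attribute correlation
#' 0.5) under the requested rating designs, redrawing profiles and data
#' every replication while holding the generating item and rater parameters
#' fixed, and fits each dataset with the requested models at the given
#' chain schedule. Both fits use the shared-main-effect saturated kernel
#' (the generating layout) with diffuse normal(0, 4) priors.
#'
#' @param designs Subset of `c("complete", "balanced", "unbalanced",
#'   "random")`.
#' @param fits Subset of `c("facets", "standard")`; within a replication and
#'   design both models see the same dataset.
#' @param reps Number of replications (default 5, the reduced scale; the
#'   full-scale convention is 100).
#' @param schedule A [chain_schedule()]; defaults to the reduced
#'   2,000/1,000/thin-10/2-chain schedule.
#' @param seed Integer seed; all replication seeds derive from it.
#' @param N,R Ratee and rater counts.
#' @param quiet Suppress per-replication progress messages.
#' @return Object of class `study_report`.
#' @export
run_study_one <- function(designs = c("complete", "balanced", "unbalanced",
                                      "random"),
                          fits = c("facets", "standard"),
                          reps = 5, schedule = NULL, seed = 1,
                          N = 500, R = 10, quiet = TRUE) {
  designs <- match.arg(designs, several.ok = TRUE)
  fits <- match.arg(fits, several.ok = TRUE)
  if (is.null(schedule)) schedule <- .reduced_schedule()
  q <- sim_qmatrix(); ip <- sim_item_params(); eta <- sim_rater_severities()
  if (R != 10) eta <- rep_len(eta, R) - mean(rep_len(eta, R))
  conditions <- expand.grid(design = designs, fit = fits,
                            stringsAsFactors = FALSE)
  sim_cache <- new.env()
  simulate_fn <- function(cond, sim_seed) {
    key <- paste(cond$design, sim_seed)
    if (!is.null(sim_cache[[key]])) return(sim_cache[[key]])
    set.seed(sim_seed)
    prof <- sim_profiles(N, ncol(q), 0.5)
    des <- rating_design(cond$design, N, R)
    sim_cache[[key]] <- simulate_facets(q, ip, eta, des, profiles = prof)
    sim_cache[[key]]
  }
  fit_fn <- function(cond, sim, fit_seed) {
    fit_cdm(sim, q,
            model = if (cond$fit == "facets") "facets" else "standard",
            cdm = "saturated", main_effects = "shared",
            standard_scheme = "virtual_items", profile_prior = "independent",
            priors = prior_spec(), schedule = schedule, seed = fit_seed)
  }
  truth_fn <- function(cond) .study_truth(with_eta = cond$fit == "facets")
  res <- .run_conditions(conditions, reps, schedule, seed, simulate_fn,
                         fit_fn, truth_fn, N, quiet)
  structure(list(study = 1, conditions = conditions, results = res,
                 reps = reps, schedule = schedule, seed = seed, N = N, R = R),
            class = "study_report")
}

#' Run the HRM recovery study
#'
#' Simulates HRM ratings under the complete design with the study's item
#' kernels, rater severities fixed at 0 and variabilities at 0.5 for all
#' raters, for each requested rater count, then fits the HRM (rater
#' parameters held at their generating values) and/or the standard model
#' under the virtual-examinee scheme with attribute-posterior averaging.
#'
#' @param raters Rater counts to run (default 3 and 6).
#' @param fits Subset of `c("hrm", "standard")`.
#' @inheritParams run_study_one
#' @return Object of class `study_report`.
#' @export
run_study_two <- function(raters = c(3, 6), fits = c("hrm", "standard"),
                          reps = 5, schedule = NULL, seed = 1, N = 500,
                          quiet = TRUE) {
  fits <- match.arg(fits, several.ok = TRUE)
  if (is.null(schedule)) schedule <- .reduced_schedule()
  q <- sim_qmatrix(); ip <- sim_item_params()
  conditions <- expand.grid(raters = raters, fit = fits,
                            stringsAsFactors = FALSE)
  sim_cache <- new.env()
  simulate_fn <- function(cond, sim_seed) {
    key <- paste(cond$raters, sim_seed)
    if (!is.null(sim_cache[[key]])) return(sim_cache[[key]])
    set.seed(sim_seed)
    prof <- sim_profiles(N, ncol(q), 0.5)
    des <- rating_design("complete", N, cond$raters)
    sim_cache[[key]] <- simulate_hrm(q, ip, phi = rep(0, cond$raters),
                                     psi = rep(0.5, cond$raters), des,
                                     profiles = prof, xi = "per_rating")
    sim_cache[[key]]
  }
  fit_fn <- function(cond, sim, fit_seed) {
    if (cond$fit == "hrm") {
      fit_cdm(sim, q, model = "hrm", cdm = "saturated",
              main_effects = "shared", profile_prior = "independent",
              priors = prior_spec(), schedule = schedule, seed = fit_seed,
              hrm_phi = 0, hrm_psi = 0.5)
    } else {
      fit_cdm(sim, q, model = "standard", cdm = "saturated",
              main_effects = "shared", profile_prior = "independent",
              standard_scheme = "virtual_examinees",
              priors = prior_spec(), schedule = schedule, seed = fit_seed)
    }
  }
  truth_fn <- function(cond) .study_truth(with_eta = FALSE)
  res <- .run_conditions(conditions, reps, schedule, seed, simulate_fn,
                         fit_fn, truth_fn, N, quiet)
  structure(list(study = 2, conditions = conditions, results = res,
                 reps = reps, schedule = schedule, seed = seed, N = N),
            class = "study_report")
}

#' Summarize profile recovery across replications
#'
#' @param report A `study_report`.
#' @return Data frame with one row per condition: mean, minimum, maximum and
#'   SD of the whole-pattern recovery rate across replications, plus the
#'   mean attribute-wise recovery.
#' @export
recovery_summary <- function(report) {
  stopifnot(inherits(report, "study_report"))
  out <- report$conditions
  rec <- t(vapply(report$results, function(r)
    c(mean(r$recovery), min(r$recovery), max(r$recovery),
      stats::sd(r$recovery), mean(r$attr_recovery)), numeric(5)))
  colnames(rec) <- c("mean", "min", "max", "sd", "mean_attribute")
  cbind(out, as.data.frame(rec, row.names = seq_len(nrow(out))))
}

#' Per-parameter bias and RMSE tables
#'
#' @param report A `study_report`.
#' @return Named list (one element per condition) of [bias_rmse()] data
#'   frames over the generating parameters.
#' @export
param_recovery <- function(report) {
  stopifnot(inherits(report, "study_report"))
  lapply(report$results, function(r) bias_rmse(r$eap, r$truth))
}

#' Write a recovery report as a wide CSV table
#'
#' One row per generating parameter with bias and RMSE columns per
#' condition, followed by profile-recovery footer rows (minimum, maximum,
#' mean, SD across replications).
#'
#' @param report A `study_report`.
#' @param path Output CSV path, or `NULL` to just return the table.
#' @return The assembled data frame, invisibly when written.
#' @export
report_table <- function(report, path = NULL) {
  pr <- param_recovery(report)
  allpars <- unique(unlist(lapply(pr, function(d) d$parameter)))
  gen <- rep(NA_real_, length(allpars))
  tab <- data.frame(parameter = allpars, gen = gen)
  for (key in names(pr)) {
    d <- pr[[key]]
    tab$gen[match(d$parameter, tab$parameter)] <- d$gen
    tab[[paste0(key, ".bias")]] <- d$bias[match(tab$parameter, d$parameter)]
    tab[[paste0(key, ".rmse")]] <- d$rmse[match(tab$parameter, d$parameter)]
  }
  rec <- recovery_summary(report)
  foot <- data.frame(parameter = c("recovery.min", "recovery.max",
                                   "recovery.mean", "recovery.sd"),
                     gen = NA_real_)
  for (ki in seq_along(pr)) {
    key <- names(pr)[ki]
    foot[[paste0(key, ".bias")]] <- c(rec$min[ki], rec$max[ki], rec$mean[ki],
                                      rec$sd[ki])
    foot[[paste0(key, ".rmse")]] <- NA_real_
  }
  out <- rbind(tab, foot)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report: study %d, %d replication(s), %d condition(s)>\n",
              x$study, x$reps, nrow(x$conditions)))
  print(recovery_summary(x))
  invisible(x)
}
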