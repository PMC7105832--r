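# Metropolis-within-Gibbs engine: oracle equivalence on tiny models,
# prior recovery, identification constraints, convergence diagnostics,
# classification, reproducibility.

test_that("class posteriors match exact enumeration on a tiny standard model", {
  q <- tiny_qmatrix(); ip <- tiny_item_params()
  des <- structure(list(assignment = matrix(TRUE, 40, 2), kind = "complete",
                        N = 40L, R = 2L), class = "rating_design")
  for (seed in c(3, 14, 25)) {
    sim <- simulate_facets(q, ip, eta = c(0, 0), des, rho = 0, seed = seed)
    truth_coef <- c(-1.5, 2.5, -1.0, 2.0, -2.0, 1.2, 1.5)
    fit <- fit_cdm(sim, q, model = "standard", main_effects = "shared",
                   profile_prior = "uniform", update_coef = FALSE,
                   schedule = chain_schedule(4200, 200, 1, 2),
                   seed = seed + 100, init = list(coef = truth_coef))
    exact <- enum_class_posterior(sim$ratings, q, ip)
    expect_lt(max(abs(fit$class_probs - exact)), 0.03)
    # classification agrees with the exact-posterior classification
    pat <- attribute_patterns(2)
    expect_equal(classify_profiles(fit),
                 unname((exact %*% pat >= 0.5) * 1L), ignore_attr = TRUE)
  }
})

test_that("single-item conjugate case reproduces Bayes rule by hand", {
  # one K=1 item with known kernel: P(mastered | x) by two-term Bayes
  q <- as_qmatrix(matrix(1, 1, 1))
  ip <- list(item_params(-1, main_effects = 2))
  rt <- data.frame(ratee = 1:2, item = 1L, rater = 1L, score = c(1L, 0L))
  fit <- fit_cdm(rt, q, model = "standard", main_effects = "shared",
                 profile_prior = "uniform", update_coef = FALSE,
                 schedule = chain_schedule(4200, 200, 1, 2), seed = 8,
                 init = list(coef = c(-1, 2)))
  p1 <- stats::plogis(1); p0 <- stats::plogis(-1)
  post_given_1 <- p1 / (p1 + p0)                 # score 1
  post_given_0 <- (1 - p1) / ((1 - p1) + (1 - p0))
  expect_equal(unname(fit$mastery[1, 1]), post_given_1, tolerance = 0.03)
  expect_equal(unname(fit$mastery[2, 1]), post_given_0, tolerance = 0.03)
})

test_that("collapsed HRM class conditional equals full enumeration over categories", {
  # brute-force oracle: joint enumeration over all 2^J latent-category
  # patterns and both classes; the sampler marginalizes analytically
  q <- as_qmatrix(matrix(c(1, 1), 2, 1))
  ip <- list(item_params(-1, main_effects = 2),
             item_params(0.5, main_effects = 1.5))
  des <- structure(list(assignment = matrix(TRUE, 10, 2), kind = "complete",
                        N = 10L, R = 2L), class = "rating_design")
  phi <- c(0.3, -0.2); psi <- c(0.6, 0.8)
  sim <- simulate_hrm(q, ip, phi, psi, des, rho = 0, seed = 77)
  f1 <- function(xi, r) stats::plogis((2 * (xi - phi[r]) - 1) / (2 * psi[r]^2))
  exact <- vapply(1:10, function(i) {
    lik <- vapply(0:1, function(a) {
      tot <- 0
      for (x1 in 0:1) for (x2 in 0:1) {       # all category patterns
        xi <- c(x1, x2)
        term <- 1
        for (j in 1:2) {
          pxi <- lcdm_prob(ip[[j]], a, 1)
          term <- term * ifelse(xi[j] == 1, pxi, 1 - pxi)
          for (r in 1:2) {
            k <- sim$ratings$score[sim$ratings$ratee == i &
                                   sim$ratings$item == j &
                                   sim$ratings$rater == r]
            pk <- f1(xi[j], r)
            term <- term * ifelse(k == 1, pk, 1 - pk)
          }
        }
        tot <- tot + term
      }
      tot
    }, 0)
    lik[2] / sum(lik)
  }, 0)
  fit <- fit_cdm(sim, q, model = "hrm", profile_prior = "uniform",
                 update_coef = FALSE, hrm_phi = phi, hrm_psi = psi,
                 schedule = chain_schedule(4200, 200, 1, 2), seed = 9,
                 init = list(coef = c(-1, 2, 0.5, 1.5)))
  expect_lt(max(abs(fit$mastery[, 1] - exact)), 0.03)
})

test_that("with the likelihood disabled, draws recover the prior", {
  q <- tiny_qmatrix(); ip <- tiny_item_params()
  des <- structure(list(assignment = matrix(TRUE, 20, 2), kind = "complete",
                        N = 20L, R = 2L), class = "rating_design")
  sim <- simulate_facets(q, ip, c(0, 0), des, rho = 0, seed = 5)
  fit <- fit_cdm(sim, q, model = "standard", main_effects = "shared",
                 prior_only = TRUE, profile_prior = "uniform",
                 schedule = chain_schedule(27000, 2000, 5, 2), seed = 6)
  draws <- do.call(rbind, fit$draws)
  icpt <- draws[, "lambda0[1]"]
  expect_gt(length(icpt), 5000)
  expect_lt(abs(mean(icpt)), 0.25)
  expect_equal(stats::sd(icpt), 4, tolerance = 0.1)
  ks <- suppressWarnings(stats::ks.test(icpt, "pnorm", 0, 4))
  expect_lt(unname(ks$statistic), 0.05)
  # truncated main effects never at or below zero even prior-only
  expect_true(all(draws[, "lambda1[1]"] > 0))
})

test_that("facets identification holds at every retained draw", {
  q <- sim_qmatrix(); ip <- sim_item_params(); eta <- sim_rater_severities()
  des <- rating_design("balanced", 120, 6)
  sim <- simulate_facets(q, ip, rep_len(eta, 6) - mean(rep_len(eta, 6)),
                         des, seed = 61)
  fit <- suppressWarnings(
    fit_cdm(sim, q, model = "facets", main_effects = "shared",
            schedule = quick_schedule(), seed = 62))
  for (d in fit$draws) {
    ecols <- d[, grep("^eta\\[", colnames(d)), drop = FALSE]
    expect_lt(max(abs(rowMeans(ecols))), 1e-10)
  }
  # main effects respect the positivity constraint in real fits too
  alld <- do.call(rbind, fit$draws)
  expect_true(all(alld[, grep("^lambda1", colnames(alld))] > 0))
})

test_that("acceptance rates after adaptation sit in a sane band", {
  q <- sim_qmatrix(); ip <- sim_item_params(); eta <- sim_rater_severities()
  des <- rating_design("complete", 150, 5)
  sim <- simulate_facets(q, ip, rep_len(eta, 5) - mean(rep_len(eta, 5)),
                         des, seed = 71)
  fit <- suppressWarnings(
    fit_cdm(sim, q, model = "facets", main_effects = "shared",
            schedule = chain_schedule(900, 450, 2, 2), seed = 72))
  acc <- unlist(fit$accept)
  acc <- acc[is.finite(acc)]
  expect_true(all(acc >= 0.1 & acc <= 0.6))
})

test_that("null severities are recovered near zero on a complete design", {
  q <- sim_qmatrix(); ip <- sim_item_params()
  des <- rating_design("complete", 500, 10)
  sim <- simulate_facets(q, ip, rep(0, 10), des, seed = 81)
  fit <- suppressWarnings(
    fit_cdm(sim, q, model = "facets", main_effects = "shared",
            schedule = chain_schedule(2000, 1000, 10, 2), seed = 82))
  etas <- fit$eap[grep("^eta\\[", names(fit$eap))]
  expect_true(all(abs(etas) < 0.15))
})

test_that("HRM rater variability is recovered when estimated", {
  q <- sim_qmatrix(); ip <- sim_item_params()
  des <- rating_design("complete", 300, 6)
  sim <- simulate_hrm(q, ip, rep(0, 6), rep(0.5, 6), des, seed = 91)
  fit <- suppressWarnings(
    fit_cdm(sim, q, model = "hrm", main_effects = "shared",
            schedule = chain_schedule(1500, 750, 5, 2), seed = 92))
  psis <- fit$eap[grep("^psi\\[", names(fit$eap))]
  expect_true(all(psis > 0.3 & psis < 0.7))
  draws <- do.call(rbind, fit$draws)
  expect_true(all(draws[, grep("^psi\\[", colnames(draws))] > 0))
})

test_that("Gelman-Rubin behaves on canonical cases", {
  set.seed(31)
  same <- matrix(stats::rnorm(2000), 1000, 2)
  expect_equal(unname(gelman_rubin(list(same, same))), c(1, 1),
               tolerance = 1e-3)
  apart <- list(matrix(stats::rnorm(1000), ncol = 1),
                matrix(stats::rnorm(1000, mean = 5), ncol = 1))
  expect_gt(gelman_rubin(apart)[1], 3)
  iid <- list(matrix(stats::rnorm(2000), ncol = 1),
              matrix(stats::rnorm(2000), ncol = 1))
  expect_lt(gelman_rubin(iid)[1], 1.05)
  expect_error(gelman_rubin(list(same)), "2 chains")
  expect_error(gelman_rubin(list(same, same[1:10, ])), "identical dimensions")
})

test_that("classification thresholds at 0.5 with ties mastering", {
  m <- rbind(c(0.9, 0.2), c(0.5, 0.5), c(0.49, 0.51))
  expect_equal(unname(classify_profiles(m)),
               rbind(c(1L, 0L), c(1L, 1L), c(0L, 1L)))
})

test_that("fits are reproducible under a fixed seed", {
  q <- tiny_qmatrix(); ip <- tiny_item_params()
  des <- structure(list(assignment = matrix(TRUE, 60, 2), kind = "complete",
                        N = 60L, R = 2L), class = "rating_design")
  sim <- simulate_facets(q, ip, c(0.5, -0.5), des, seed = 15)
  f1 <- suppressWarnings(fit_cdm(sim, q, model = "facets",
                                 main_effects = "shared",
                                 schedule = quick_schedule(), seed = 16))
  f2 <- suppressWarnings(fit_cdm(sim, q, model = "facets",
                                 main_effects = "shared",
                                 schedule = quick_schedule(), seed = 16))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$profiles, f2$profiles)
})

test_that("invalid inputs fail loudly", {
  q <- tiny_qmatrix()
  rt <- data.frame(ratee = c(1, 1), item = c(1, 1), rater = c(1, 1),
                   score = c(1, 0))
  expect_error(fit_cdm(rt, q), "duplicate")
  rt2 <- data.frame(ratee = 1:3, item = 1:3, rater = 1, score = c(0, 1, 2))
  expect_error(fit_cdm(rt2, q), "0 or 1")
  rt3 <- data.frame(ratee = 1:2, item = c(1, 2), rater = 1, score = c(0, 1))
  expect_error(fit_cdm(rt3, q), "Q-matrix")
  # disconnected rater pool cannot anchor severities on one scale
  rt4 <- expand.grid(ratee = 1:10, item = 1:3)
  rt4$rater <- ifelse(rt4$ratee <= 5, 1L, 2L)
  rt4$score <- stats::rbinom(nrow(rt4), 1, 0.5)
  expect_error(fit_cdm(rt4, q, model = "facets"), "unidentified")
})
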