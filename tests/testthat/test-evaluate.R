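# Evaluation metrics: bias/RMSE, recovery, information criteria, posterior
# predictive checks, fair scores.

test_that("bias and RMSE follow their definitions", {
  expect_equal(bias_rmse(c(1, 1, 1), 1), list(bias = 0, rmse = 0))
  br <- bias_rmse(c(1.1, 0.9), 1)
  expect_equal(br$bias, 0)
  expect_equal(br$rmse, 0.1)
  one <- bias_rmse(0.7, 1)
  expect_equal(one$bias, -0.3)
  expect_equal(one$rmse, 0.3)
  expect_error(bias_rmse(numeric(0), 1), "no estimates")
  # matrix form matches by name and satisfies rmse >= |bias| always
  set.seed(2)
  est <- matrix(stats::rnorm(60), 10, 6,
                dimnames = list(NULL, paste0("p", 1:6)))
  tr <- stats::setNames(stats::rnorm(6), paste0("p", 1:6))
  tab <- bias_rmse(est, tr)
  expect_true(all(tab$rmse >= abs(tab$bias) - 1e-12))
  expect_equal(tab$rmse[1],
               sqrt(mean((est[, 1] - tr[1])^2)))
})

test_that("recovery rates count exact matches and cells", {
  a <- rbind(c(1, 0), c(0, 1), c(1, 1), c(0, 0))
  expect_equal(profile_recovery(a, a), 100)
  b <- a; b[1, 1] <- 0
  expect_equal(profile_recovery(b, a), 75)
  expect_equal(attribute_recovery(b, a), 100 * 7 / 8)
  expect_error(profile_recovery(a, a[1:2, ]), "dimension")
})

test_that("information criteria follow the formulas", {
  ic <- information_criteria(-100, 10, exp(10))
  expect_equal(ic$aic, 220)
  expect_equal(ic$bic, 300)
})

test_that("fair scores are expected totals under the rater-free kernel", {
  # certain success on every item: fair score equals the test length
  q <- as_qmatrix(matrix(1, 4, 1))
  sure <- replicate(4, item_params(50, main_effects = 1), simplify = FALSE)
  expect_equal(fair_scores(1, sure, q), 4, tolerance = 1e-6)
  # DINA items with g = 0.2, s = 0.1, half the items mastered
  q2 <- as_qmatrix(rbind(matrix(c(1, 0), 5, 2, byrow = TRUE),
                         matrix(c(0, 1), 5, 2, byrow = TRUE)))
  g <- stats::qlogis(0.2); full <- stats::qlogis(0.9)
  dp <- replicate(10, dina_params(g, full - g), simplify = FALSE)
  expect_equal(fair_scores(c(1, 0), dp, q2), 5 * 0.9 + 5 * 0.2,
               tolerance = 1e-9)
})

test_that("fair-versus-observed bookkeeping separates rater severity", {
  q <- sim_qmatrix(); ip <- sim_item_params()
  # one harsh and one lenient rater; a few shared ratees anchor the scale
  N <- 80
  A <- matrix(FALSE, N, 2)
  A[1:10, ] <- TRUE
  A[cbind(11:N, rep(1:2, length.out = N - 10))] <- TRUE
  des <- structure(list(assignment = A, kind = "random", N = N, R = 2L),
                   class = "rating_design")
  sim <- simulate_facets(q, ip, eta = c(2, -2), des, seed = 17)
  fit <- suppressWarnings(
    fit_cdm(sim, q, model = "facets", main_effects = "shared",
            schedule = quick_schedule(), seed = 18))
  rep <- fair_score_report(fit)
  expect_equal(rep$difference, rep$observed - rep$fair)
  harsh <- which(A[, 1] & !A[, 2])
  lenient <- which(A[, 2] & !A[, 1])
  expect_lt(mean(rep$difference[harsh]), mean(rep$difference[lenient]))
  # the raw and fair rankings disagree
  expect_lt(suppressWarnings(cor(rank(rep$observed), rank(rep$fair),
                                 method = "spearman")), 0.999)
})

test_that("posterior predictive p-values calibrate under the true model", {
  q <- sim_qmatrix(); ip <- sim_item_params(); eta <- sim_rater_severities()
  for (seed in c(5, 6, 7)) {
    des <- rating_design("complete", 120, 3)
    e3 <- rep_len(eta, 3) - mean(rep_len(eta, 3))
    sim <- simulate_facets(q, ip, e3, des, seed = seed)
    fit <- suppressWarnings(
      fit_cdm(sim, q, model = "facets", main_effects = "shared",
              schedule = chain_schedule(900, 450, 3, 2), seed = seed + 50))
    pp <- ppp_chisq(fit, seed = seed + 100)
    expect_gt(pp$ppp, 0.05)
    expect_lt(pp$ppp, 0.95)
  }
})

test_that("misspecification pushes the ppp toward an extreme and hurts AIC", {
  q <- sim_qmatrix(); ip <- sim_item_params()
  eta <- c(2, 2, -2, -2)                       # strong severity spread
  des <- rating_design("complete", 150, 4)
  sim <- simulate_facets(q, ip, eta, des, seed = 23)
  f_ok <- suppressWarnings(
    fit_cdm(sim, q, model = "facets", main_effects = "shared",
            schedule = chain_schedule(900, 450, 3, 2), seed = 24))
  f_bad <- suppressWarnings(
    fit_cdm(sim, q, model = "standard", main_effects = "shared",
            schedule = chain_schedule(900, 450, 3, 2), seed = 25))
  p_ok <- ppp_chisq(f_ok, seed = 26)$ppp
  p_bad <- ppp_chisq(f_bad, seed = 27)$ppp
  expect_gt(abs(p_bad - 0.5), abs(p_ok - 0.5) - 1e-9)
  # ignoring strong rater effects costs likelihood: facets AIC wins
  expect_lt(fit_ic(f_ok)$aic, fit_ic(f_bad)$aic)
  # same draws + same seed give the same ppp
  expect_equal(ppp_chisq(f_ok, seed = 26)$ppp, p_ok)
})

test_that("study reports carry recovery statistics and parameter tables", {
  # miniature end-to-end harness run (small N keeps it a smoke check)
  s <- suppressWarnings(
    run_study_one(designs = "complete", fits = "facets", reps = 2,
                  schedule = quick_schedule(), seed = 3, N = 60, R = 3))
  rs <- recovery_summary(s)
  expect_equal(nrow(rs), 1)
  expect_true(rs$mean >= 0 && rs$mean <= 100)
  expect_true(rs$min <= rs$mean && rs$mean <= rs$max)
  pr <- param_recovery(s)[[1]]
  expect_true(all(pr$rmse >= abs(pr$bias) - 1e-12))
  tab <- report_table(s)
  expect_true("recovery.mean" %in% tab$parameter)
  tf <- tempfile(fileext = ".csv")
  report_table(s, tf)
  expect_true(file.exists(tf))
})
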