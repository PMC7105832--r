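# Synthetic rating generators: facets, HRM (shared and per-rating latent
# categories), and the essay-checklist fixture.

test_that("generating severities sum to zero", {
  expect_equal(sum(sim_rater_severities()), 0)
})

test_that("facets generation honors kernels and severity ordering", {
  q <- sim_qmatrix(); ip <- sim_item_params(); eta <- sim_rater_severities()
  # with a single neutral rater, item means converge to kernel expectations
  d1 <- structure(list(assignment = matrix(TRUE, 1e4, 1), kind = "complete",
                       N = 1e4, R = 1), class = "rating_design")
  sim <- simulate_facets(q, ip, eta = 0, d1, seed = 21)
  ker <- sapply(seq_len(10), function(j)
    apply(attribute_patterns(5), 1, function(a) lcdm_kernel(ip[[j]], a, q[j, ])))
  expected <- colMeans(stats::plogis(ker[sim$truth$class, ]))
  observed <- tapply(sim$ratings$score, sim$ratings$item, mean)
  expect_equal(as.numeric(observed), as.numeric(expected),
               tolerance = 0.01)

  # complete design: lenient rater 10 scores higher than severe rater 4
  des <- rating_design("complete", 500, 10)
  simf <- simulate_facets(q, ip, eta, des, seed = 22)
  by_rater <- tapply(simf$ratings$score, simf$ratings$rater, mean)
  expect_gt(by_rater[["10"]], by_rater[["4"]])
  # and mean scores essentially reverse the severity ranking (adjacent
  # severities 0.57 and 0.59 can swap by sampling noise)
  expect_lt(cor(as.numeric(by_rater), eta, method = "spearman"), -0.95)
})

test_that("simulation is byte-identical under a repeated seed", {
  q <- sim_qmatrix(); ip <- sim_item_params(); eta <- sim_rater_severities()
  des <- rating_design("balanced", 500, 10)
  a <- simulate_facets(q, ip, eta, des, seed = 31)
  b <- simulate_facets(q, ip, eta, des, seed = 31)
  expect_identical(a$ratings, b$ratings)
  expect_identical(a$truth$alpha, b$truth$alpha)
  h1 <- simulate_hrm(q, ip, rep(0, 3), rep(0.5, 3),
                     rating_design("complete", 200, 3), seed = 32)
  h2 <- simulate_hrm(q, ip, rep(0, 3), rep(0.5, 3),
                     rating_design("complete", 200, 3), seed = 32)
  expect_identical(h1$ratings, h2$ratings)
})

test_that("HRM generation matches the rating-stage fidelity", {
  q <- sim_qmatrix(); ip <- sim_item_params()
  des <- rating_design("complete", 400, 3)
  # psi -> 0: raters echo the latent category almost surely
  s0 <- simulate_hrm(q, ip, rep(0, 3), rep(0.01, 3), des, seed = 41)
  agree0 <- mean(s0$ratings$score ==
                 s0$truth$xi[cbind(s0$ratings$ratee, s0$ratings$item)])
  expect_gt(agree0, 0.99)
  # psi = 0.5: P(score == xi) is logistic(2) = 0.8808
  s5 <- simulate_hrm(q, ip, rep(0, 3), rep(0.5, 3), des, seed = 42)
  agree5 <- mean(s5$ratings$score ==
                 s5$truth$xi[cbind(s5$ratings$ratee, s5$ratings$item)])
  expect_equal(agree5, 0.8808, tolerance = 0.01)
})

test_that("shared latent categories induce inter-rater correlation", {
  q <- sim_qmatrix(); ip <- sim_item_params()
  des <- rating_design("complete", 500, 2)
  prof <- sim_profiles(500, 5, 0.5, seed = 51)
  hs <- simulate_hrm(q, ip, rep(0, 2), rep(0.5, 2), des, profiles = prof,
                     seed = 52)
  ff <- simulate_facets(q, ip, rep(0, 2), des, profiles = prof, seed = 53)
  pair_agree <- function(sim) {
    wide <- matrix(sim$ratings$score[order(sim$ratings$ratee,
                                           sim$ratings$item,
                                           sim$ratings$rater)],
                   ncol = 2, byrow = TRUE)
    mean(wide[, 1] == wide[, 2])
  }
  expect_gt(pair_agree(hs), pair_agree(ff))
  # per-rating regeneration breaks that excess agreement
  hp <- simulate_hrm(q, ip, rep(0, 2), rep(0.5, 2), des, profiles = prof,
                     seed = 54, xi = "per_rating")
  expect_lt(pair_agree(hp), pair_agree(hs))
})

test_that("checklist fixture has the advertised shape and rater behavior", {
  fx <- checklist_fixture(seed = 7)
  expect_equal(fx$design$N, 287L)
  expect_equal(nrow(fx$qmatrix), 52L)
  expect_equal(fx$design$R, 9L)
  expect_equal(unname(colSums(checklist_qmatrix())), c(11, 20, 28, 23, 5, 7))
  rpp <- rowSums(fx$design$assignment)
  expect_true(all(rpp %in% 1:2))
  expect_true(design_connected(fx$design) == TRUE)
  # severe, consistent rater 1 scores below near-neutral rater 3
  by_rater <- tapply(fx$ratings$score, fx$ratings$rater, mean)
  expect_lt(by_rater[["1"]], by_rater[["3"]])
})
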