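# Measurement kernel: profile enumeration, linear predictor, success
# probabilities, DINA restriction, guessing/slip reparameterization.

test_that("profile enumeration is a canonical bijection onto {0,1}^K", {
  expect_equal(nrow(attribute_patterns(5)), 32L)
  expect_equal(attribute_patterns(1)[, 1], c(0L, 1L), ignore_attr = TRUE)
  expect_equal(unname(attribute_patterns(2)),
               rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L)))
  for (K in c(3, 5)) {
    pat <- attribute_patterns(K)
    expect_equal(nrow(unique(pat)), 2^K)           # distinct
    expect_true(all(pat %in% c(0L, 1L)))
    # attribute 1 is the most significant bit of the row number
    expect_equal(profile_index(pat), seq_len(2^K))
  }
  expect_error(attribute_patterns(0), "1..15")
  expect_error(attribute_patterns(16), "1..15")
})

test_that("linear predictor assembles intercept, mains and interactions", {
  it1 <- item_params(-2.00, main_effects = 3.72)
  expect_equal(lcdm_kernel(it1, c(1, 0, 0, 0, 0), c(1, 0, 0, 0, 0)), 1.72)
  # all-zero profile returns the intercept exactly
  it6 <- item_params(-2.42, main_effects = 1.26, interactions = c("1,2" = 2.16))
  expect_equal(lcdm_kernel(it6, c(0, 0), c(1, 1)), -2.42)
  # shared main effect applied to both required attributes
  expect_equal(lcdm_kernel(it6, c(1, 1), c(1, 1)), -2.42 + 1.26 + 1.26 + 2.16)
  # attributes the item does not require contribute nothing
  expect_equal(lcdm_kernel(it1, c(1, 1, 1, 1, 1), c(1, 0, 0, 0, 0)), 1.72)
  # interaction over a non-required attribute is an error
  bad <- item_params(-1, main_effects = 1, interactions = c("1,2" = 0.5))
  expect_error(lcdm_kernel(bad, c(1, 0), c(1, 0)), "not required")
})

test_that("success probability is the logistic kernel and is monotone", {
  it1 <- item_params(-2.00, main_effects = 3.72)
  expect_equal(lcdm_prob(it1, c(0, 0, 0, 0, 0), c(1, 0, 0, 0, 0)),
               0.11920292, tolerance = 1e-7)
  expect_equal(lcdm_prob(item_params(0, main_effects = 1), 0, 1), 0.5)
  # printed guessing endpoint for the flattest simulation item
  it4 <- sim_item_params()[[4]]
  expect_equal(round(lcdm_prob(it4, rep(0, 5), sim_qmatrix()[4, ]), 2), 0.20)
  # monotonicity across all ordered profile pairs, every simulation item
  q <- sim_qmatrix(); ip <- sim_item_params()
  pat <- attribute_patterns(5)
  for (j in seq_len(nrow(q))) {
    p <- apply(pat, 1, function(a) lcdm_prob(ip[[j]], a, q[j, ]))
    for (a in seq_len(nrow(pat))) {
      dom <- which(colSums(t(pat) >= pat[a, ]) == 5)
      expect_true(all(p[dom] >= p[a] - 1e-12))
    }
  }
})

test_that("DINA is the conjunctive two-value restriction", {
  d <- dina_params(-2, 4)
  expect_equal(dina_prob(d, c(1, 1, 1), c(1, 1, 1)),
               stats::plogis(2), tolerance = 1e-7)
  expect_equal(dina_prob(d, c(1, 0, 1), c(1, 1, 1)), stats::plogis(-2))
  # refuse saturated parameters
  expect_error(dina_prob(item_params(-1, main_effects = 2), 1, 1),
               "DINA")
  # K = 1: DINA and saturated LCDM coincide for matched parameters
  s <- item_params(-1.3, main_effects = 2.2)
  d1 <- dina_params(-1.3, 2.2)
  for (a in 0:1) {
    expect_equal(dina_prob(d1, a, 1), lcdm_prob(s, a, 1))
  }
  # zeroing all but the top interaction of a saturated item reproduces DINA
  pat <- attribute_patterns(2)
  d2 <- dina_params(-1.5, 3)
  s2 <- item_params(-1.5, main_effects = 1e-12, interactions = c("1,2" = 3))
  for (c in 1:4) {
    expect_equal(lcdm_prob(s2, pat[c, ], c(1, 1)),
                 dina_prob(d2, pat[c, ], c(1, 1)), tolerance = 1e-9)
  }
})

test_that("guessing/slip transforms reproduce the printed generating ranges", {
  q <- sim_qmatrix(); ip <- sim_item_params()
  gs <- t(vapply(seq_len(10), function(j)
    unlist(guess_slip(ip[[j]], q[j, ])), c(guessing = 0, slip = 0)))
  expect_equal(range(round(gs[, "guessing"], 2)), c(0.08, 0.20))
  expect_equal(range(round(gs[, "slip"], 2)), c(0.07, 0.19))
  # endpoints land on the advertised items
  expect_equal(unname(round(gs[6, "guessing"], 2)), 0.08)
  expect_equal(unname(round(gs[2, "slip"], 2)), 0.19)
  # flat kernel gives coin-flip guessing and slip
  flat <- guess_slip(item_params(0, main_effects = 1e-12), 1)
  expect_equal(flat$guessing, 0.5)
  expect_equal(flat$slip, 0.5, tolerance = 1e-9)
})

test_that("Q-matrix validation names offending rows and columns", {
  expect_s3_class(as_qmatrix(sim_qmatrix()), "qmatrix")
  expect_error(as_qmatrix(rbind(c(1, 0), c(0, 2))), "0 or 1.*2")
  expect_error(as_qmatrix(rbind(c(0, 0), c(1, 1))), "row.*1")
  expect_error(as_qmatrix(rbind(c(1, 0), c(1, 0))), "column.*2")
  tf <- tempfile(fileext = ".csv")
  write_qmatrix(sim_qmatrix(), tf)
  expect_equal(unclass(read_qmatrix(tf)), unclass(sim_qmatrix()),
               ignore_attr = TRUE)
})
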