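test_that("log-likelihood handles the textbook cases", {
  # all mass on observed cells
  expect_equal(log_likelihood(c(3, 0, 0), c(1, 0, 0)), 0)
  # uniform probability over the 12 response cells
  n <- c(10, rep(0, 11)); n[5] <- 14
  expect_equal(log_likelihood(n, rep(1 / 12, 12)), 24 * log(1 / 12))
  # hand arithmetic on a 3-cell toy table
  expect_equal(log_likelihood(c(2, 1, 1), c(0.5, 0.25, 0.25)),
               2 * log(0.5) + log(0.25) + log(0.25))
  # zero probability at an occupied cell yields -Inf, not an error
  expect_identical(log_likelihood(c(1, 1), c(0.5, 0)), -Inf)
  # but a zero-count cell may have zero probability
  expect_equal(log_likelihood(c(2, 0), c(1, 0)), 0)
  expect_error(log_likelihood(c(1, 2, 3), c(0.5, 0.5)), "shape")
})

test_that("response tables count trials and are order invariant", {
  d <- build_design("expt1")
  spec <- subject_spec(1, d, decision_params(0.27, lapse = 0.05),
                       model = "top2diff", seed = 2)
  tr <- simulate_subject(spec)
  tab <- response_table(tr, d)
  expect_equal(sum(tab), 576)
  expect_equal(dim(tab), c(3L, 4L, 6L, 6L))
  shuffled <- tr[withr::with_seed(1, sample.int(nrow(tr))), ]
  expect_identical(response_table(shuffled, d), tab)
  ct <- choice_table(tab)
  expect_equal(sum(ct), 576)
  expect_equal(ct, choice_table(tr, d))
})

test_that("predicted cell probabilities are normalized, seeded, and match quadrature", {
  d <- build_design("expt1")
  dp <- decision_params(0.27)
  cp <- default_confidence_criteria("top2diff")
  suppressMessages({
    p1 <- predict_cell_probabilities(d, dp, cp, "top2diff", mc_samples = 5000, seed = 9)
    p2 <- predict_cell_probabilities(d, dp, cp, "top2diff", mc_samples = 5000, seed = 9)
  })
  expect_identical(p1, p2)
  sums <- apply(p1, c(3, 4), sum)
  expect_equal(unname(sums), matrix(1, 6, 6), tolerance = 1e-12)
  # choice marginal of the MC cells matches the quadrature probability,
  # including the zero-dot condition 3 ([100, 75, 0])
  mc <- 40000
  p <- predict_cell_probabilities(d, dp, cp, "top2diff", mc_samples = mc, seed = 4)
  q <- choice_probabilities(d$conditions[3, ], d$configurations[1, ], dp)
  marg <- apply(p[, , 3, 1], 1, sum)
  se <- sqrt(pmax(q * (1 - q), 2.5e-5) / mc)
  expect_true(all(abs(marg - q) < 3 * se + 1e-4))
})

test_that("the one-parameter fit recovers alpha and orders noise levels", {
  d <- build_design("expt2")
  sim_ct <- function(alpha, seed) {
    spec <- subject_spec(1, d, decision_params(alpha), model = "top2diff",
                         seed = seed)
    choice_table(simulate_subject(spec), d)
  }
  f <- fit_decision_1p(sim_ct(0.27, 41), d)
  expect_equal(unname(f$params["alpha"]), 0.27, tolerance = 0.15)
  expect_equal(f$aic, -2 * f$loglik + 2)
  # monotone recovery: higher true noise, higher estimate, in every seed
  for (s in 1:4) {
    lo <- fit_decision_1p(sim_ct(0.10, s), d)$params["alpha"]
    hi <- fit_decision_1p(sim_ct(0.50, s + 100), d)$params["alpha"]
    expect_lt(lo, hi)
  }
  expect_error(fit_decision_1p(array(0, c(3, 12, 6)), d), "empty")
})

test_that("an all-correct table drives alpha to the lower bound, flagged", {
  d <- build_design("expt2")
  spec <- subject_spec(1, d, decision_params(1e-10), model = "top2diff", seed = 6)
  ct <- choice_table(simulate_subject(spec), d)
  f <- fit_decision_1p(ct, d)
  expect_lt(f$params["alpha"], 0.03)
  expect_true(f$details$at_boundary)
})

test_that("the four-parameter fit recovers colour bias and beats the 1p fit on biased data", {
  d <- build_design("expt2")
  spec <- subject_spec(1, d, decision_params(0.2, m_green = 1.3),
                       model = "top2diff", seed = 14)
  ct <- choice_table(simulate_subject(spec), d)
  f4 <- fit_decision_4p(ct, d, seed = 2)
  f1 <- fit_decision_1p(ct, d)
  expect_true(f4$converged)
  expect_equal(f4$aic, -2 * f4$loglik + 8)
  expect_gt(unname(f4$params["m_green"]), 1.1)
  expect_lt(f4$aic, f1$aic)
  # bias-free truth: the simpler model is not materially worse
  spec0 <- subject_spec(1, d, decision_params(0.27), model = "top2diff", seed = 15)
  ct0 <- choice_table(simulate_subject(spec0), d)
  f4_0 <- fit_decision_4p(ct0, d, seed = 2)
  f1_0 <- fit_decision_1p(ct0, d)
  expect_lt(f1_0$aic, f4_0$aic + 6)
})

test_that("confidence-criterion fits recover rating marginals and are deterministic", {
  d <- build_design("expt2")
  dp <- decision_params(0.27, lapse = 0.06)
  cp <- default_confidence_criteria("top2diff")
  spec <- subject_spec(1, d, dp, cp, model = "top2diff", seed = 23)
  tr <- simulate_subject(spec)
  tab <- response_table(tr, d)
  suppressMessages({
    f <- fit_confidence(tab, d, dp, "top2diff", mc_samples = 8000, seed = 5)
    f2 <- fit_confidence(tab, d, dp, "top2diff", mc_samples = 8000, seed = 5)
  })
  # restart determinism: same data + same seed reproduce the fit exactly
  expect_equal(f$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f$aic, -2 * f$loglik + 6)
  expect_true(all(diff(f$params) > 0))
  # fitted criteria reproduce the generating rating marginals within 3%
  pred <- predict_cell_probabilities(d, dp, confidence_params(f$params),
                                     "top2diff", mc_samples = 20000, seed = 77)
  # rating marginal over equal-weight (condition, configuration) cells
  pred_marg <- apply(pred, 2, sum) / prod(dim(pred)[3:4])
  obs_marg <- tabulate(tr$confidence, 4) / nrow(tr)
  expect_true(all(abs(pred_marg - obs_marg) < 0.03))
})

test_that("degenerate all-identical ratings still converge with extreme criteria", {
  d <- build_design("expt1")
  dp <- decision_params(0.27)
  spec <- subject_spec(1, d, dp, model = "top2diff", seed = 3)
  tr <- simulate_subject(spec)
  tr$confidence <- 4L
  tab <- response_table(tr, d)
  suppressMessages(
    f <- fit_confidence(tab, d, dp, "top2diff", mc_samples = 4000, seed = 8)
  )
  expect_true(f$converged)
  # nearly all reservoir mass must sit above c3
  expect_lt(unname(f$params["c1"]), 1)
})

test_that("model comparison arithmetic, bootstrap, and input checks", {
  # identical fits: zero differences, degenerate CI
  aics <- data.frame(subject = rep(1:5, 2),
                     model = rep(c("a", "b"), each = 5),
                     aic = rep(100, 10))
  cmp <- compare_models(aics, reference = "a", n_boot = 1000, seed = 1)
  expect_equal(cmp$summary$summed_delta_aic, 0)
  expect_equal(c(cmp$summary$ci_lo, cmp$summary$ci_hi), c(0, 0))
  # constant 2-point difference across 10 subjects
  aics2 <- data.frame(subject = rep(1:10, 2),
                      model = rep(c("ref", "worse"), each = 10),
                      aic = c(rep(100, 10), rep(102, 10)))
  cmp2 <- compare_models(aics2, n_boot = 1000, seed = 1)
  expect_equal(cmp2$reference, "ref")
  expect_equal(cmp2$summary$summed_delta_aic, 20)
  expect_equal(cmp2$summary$relative_likelihood, exp(10))
  expect_equal(cmp2$summary$wins_reference, 10)
  # mismatched subject sets are rejected
  expect_error(compare_models(aics2[-1, ]), "every model")
})

test_that("fit results serialize to JSON with reproducibility metadata", {
  d <- build_design("expt1")
  spec <- subject_spec(1, d, decision_params(0.3), model = "top2diff", seed = 2)
  f <- fit_decision_1p(choice_table(simulate_subject(spec), d), d)
  js <- jsonlite::fromJSON(fit_to_json(f))
  expect_equal(js$params$alpha, unname(f$params["alpha"]))
  expect_equal(js$aic, f$aic)
  expect_equal(js$n_restarts, 2)
})
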