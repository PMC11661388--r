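test_that("top-2 difference and positive evidence variables are correct", {
  expect_equal(conf_top2diff(c(10, 7, 5)), 3)
  expect_equal(conf_top2diff(c(5, 5, 2)), 0)
  expect_equal(conf_pe(c(10, 7, 5)), 10)
  expect_equal(conf_pe(c(-1, -2, -3)), -1)
  withr::with_seed(3, {
    x <- matrix(rnorm(300), ncol = 3)
    c1 <- conf_top2diff(x)
    expect_true(all(c1 >= 0))
    # homogeneity of top2diff; permutation invariance of both
    expect_equal(conf_top2diff(2.5 * x), 2.5 * c1)
    perm <- x[, c(3, 1, 2)]
    expect_equal(conf_top2diff(perm), c1)
    expect_equal(conf_pe(perm), conf_pe(x))
  })
})

test_that("dot-count likelihood is the scalar-variability Gaussian density", {
  expect_equal(dot_count_likelihood(100, 100, 0.27), 1 / (sqrt(2 * pi) * 27))
  expect_equal(dot_count_likelihood(80, 100, 0.27), dnorm(80, 100, 27))
  # with a multiplier the mean and sd scale together
  expect_equal(dot_count_likelihood(90, 100, 0.27, multiplier = 0.9),
               dnorm(90, 90, 0.27 * 90))
  expect_error(dot_count_likelihood(50, 0, 0.27), ">= 1")
  # integrates to 1 over activations
  int <- integrate(function(x) dot_count_likelihood(x, 60, 0.3), -100, 250)
  expect_equal(int$value, 1, tolerance = 1e-6)
})

test_that("factored BCH posterior equals the brute-force triple sum", {
  withr::with_seed(17, {
    for (rep in 1:12) {
      x <- sort(runif(3, 5, 40), decreasing = TRUE)[sample.int(3)]
      a <- runif(1, 0.1, 0.6)
      m <- runif(3, 0.7, 1.4)
      expect_equal(conf_bch(x, a, m, k_max = 40),
                   bch_brute_force(x, a, m, k_max = 40),
                   tolerance = 1e-10)
    }
  })
})

test_that("BCH posterior behaves like a posterior", {
  # symmetric activations give exactly 1/3 (tie corrections included)
  expect_equal(conf_bch(c(50, 50, 50), 0.27), 1 / 3)
  expect_equal(conf_bch(c(-2, -2, -2), 0.27), 1 / 3)
  # degenerate zero activations: an absent colour is known to have zero
  # dots, so it never outranks the chosen colour...
  expect_gt(conf_bch(c(100, 75, 0), 0.27), conf_bch(c(100, 75, 30), 0.27))
  # ...and the posterior stays scale invariant for two-colour conditions
  expect_lt(abs(conf_bch(c(100, 75, 0), 0.27) - conf_bch(c(80, 60, 0), 0.27)),
            0.003)
  # a chosen colour with zero activation cannot dominate grid counts >= 1
  expect_equal(conf_bch(c(0, -5, -3), 0.27), 0)
  expect_equal(conf_bch(c(0, 0, 0), 0.27), 1 / 3)
  # overwhelming evidence saturates towards 1
  expect_gt(conf_bch(c(150, 5, 5), 0.27), 0.99)
  withr::with_seed(21, {
    x <- matrix(runif(3 * 200, 10, 150), ncol = 3)
    post <- conf_bch(x, 0.27)
    expect_true(all(post >= 0 & post <= 1))
    # non-decreasing in the chosen activation, others held fixed
    grid <- seq(80, 140, by = 10)
    post_line <- conf_bch(cbind(grid, 60, 50), 0.27)
    expect_true(all(diff(post_line) > -1e-12))
  })
})

test_that("BCH is nearly scale invariant where top2diff is scale covariant", {
  d <- build_design("expt1")
  p <- decision_params(0.27)
  n <- 20000
  # common random numbers: activations of the 0.8-scaled condition are the
  # scaled activations of the large condition
  z <- withr::with_seed(8, matrix(rnorm(3 * n), ncol = 3))
  mk <- function(dots) sweep(sweep(z, 2, 0.27 * dots, "*"), 2, dots, "+")
  x_hi <- mk(c(100, 75, 75))
  x_lo <- mk(c(80, 60, 60))
  expect_lt(abs(mean(conf_bch(x_hi, 0.27)) - mean(conf_bch(x_lo, 0.27))), 0.005)
  expect_equal(conf_top2diff(x_lo), 0.8 * conf_top2diff(x_hi))
})

test_that("criterion mapping and its boundary convention", {
  cp <- confidence_params(c(1, 2, 3))
  expect_identical(map_to_rating(0.5, cp), 1L)
  expect_identical(map_to_rating(2.0, cp), 3L)  # boundary rounds up
  expect_identical(map_to_rating(99, cp), 4L)
  expect_identical(map_to_rating(c(-1, 1, 2.5, 3), cp), c(1L, 2L, 3L, 4L))
  expect_error(confidence_params(c(2, 1, 3)), "increasing")
  expect_error(confidence_params(c(1, 1, 3)), "increasing")
})

test_that("simulated responses respect the noise-free and pure-lapse limits", {
  cp <- confidence_params(c(1, 2, 3))
  r <- simulate_response(c(100, 75, 40), c(2, 1, 3), decision_params(1e-12),
                         cp, "top2diff", n = 50)
  expect_true(all(r$choice == 2) && all(r$correct))
  r <- withr::with_seed(4, simulate_response(c(100, 75, 40), c(1, 2, 3),
                                             decision_params(0.27, lapse = 1),
                                             cp, "pe", n = 9000))
  freq <- tabulate(r$choice, 3) / 9000
  expect_true(all(abs(freq - 1 / 3) < 3 * sqrt((1 / 3) * (2 / 3) / 9000)))
  # uniform lapse ratings cover all four levels
  expect_true(all(tabulate(r$confidence, 4) > 0))
})

test_that("top2diff ratings show the numerosity effect across scaled conditions", {
  d <- build_design("expt1")
  p <- decision_params(0.27)
  cp <- default_confidence_criteria("top2diff")
  n <- 50000
  withr::with_seed(12, {
    r_hi <- simulate_response(d$conditions[1, ], c(1, 2, 3), p, cp, "top2diff", n = n)
    r_lo <- simulate_response(d$conditions[4, ], c(1, 2, 3), p, cp, "top2diff", n = n)
  })
  expect_gt(mean(r_hi$confidence), mean(r_lo$confidence))
})

test_that("PE predicts higher confidence when the runner-up has more dots", {
  # the model's counterintuitive signature: [100, 90] beats [100, 70]
  p <- decision_params(0.27)
  cp <- default_confidence_criteria("pe")
  n <- 50000
  withr::with_seed(13, {
    r90 <- simulate_response(c(100, 90, 0), c(1, 2, 3), p, cp, "pe", n = n)
    r70 <- simulate_response(c(100, 70, 0), c(1, 2, 3), p, cp, "pe", n = n)
  })
  expect_gt(mean(r90$confidence), mean(r70$confidence))
})
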