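#' Confidence criteria
#'
#' Three strictly increasing criteria partition a continuous confidence
#' variable into the four ordinal confidence ratings. A value equal to a
#' criterion receives the higher rating.
#'
#' @param criteria Numeric triple `(c1, c2, c3)` with `c1 < c2 < c3`.
#' @return An object of class `dotconf_cparams`.
#' @export
confidence_params <- function(criteria) {
  if (length(criteria) != 3 || any(!is.finite(criteria)))
    stop("criteria must be three finite numbers")
  if (any(diff(criteria) <= 0))
    stop("criteria must be strictly increasing")
  structure(list(criteria = as.numeric(criteria)), class = "dotconf_cparams")
}

#' @export
print.dotconf_cparams <- function(x, ...) {
  cat(sprintf("confidence criteria: (%.4g, %.4g, %.4g)\n",
              x$criteria[1], x$criteria[2], x$criteria[3]))
  invisible(x)
}

#' Supported confidence models
#' @return Character vector of model labels.
#' @export
confidence_models <- function() c("top2diff", "bch", "pe")

.as_activation_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3)
    x
  } else {
    stopifnot(length(x) == 3)
    matrix(x, nrow = 1)
  }
}

#' Top-2 Difference confidence variable
#'
#' Confidence as the gap between the highest and second-highest activation:
#' `max(x) - max2(x)`. Always non-negative, and scale-covariant (multiplying
#' all activations by c > 0 multiplies the output by c), which is the
#' mechanism behind the numerosity effect this model predicts.
#'
#' @param x Activation triple, or an n x 3 matrix of triples.
#' @return Numeric vector of confidence-variable values.
#' @examples
#' conf_top2diff(c(10, 7, 5))  # 3
#' @export
conf_top2diff <- function(x) {
  x <- .as_activation_matrix(x)
  top <- pmax(x[, 1], x[, 2], x[, 3])
  bottom <- pmin(x[, 1], x[, 2], x[, 3])
  top - (x[, 1] + x[, 2] + x[, 3] - top - bottom)
}

#' Positive Evidence confidence variable
#'
#' Confidence as the activation of the chosen (maximal) option alone:
#' `max(x)`. Ignores the alternatives entirely.
#'
#' @inheritParams conf_top2diff
#' @return Numeric vector of confidence-variable values.
#' @export
conf_pe <- function(x) {
  x <- .as_activation_matrix(x)
  pmax(x[, 1], x[, 2], x[, 3])
}

#' Likelihood of an activation under a hypothesised dot count
#'
#' The scalar-variability likelihood `L_k(x)`: the Gaussian density with
#' mean `multiplier * k` and sd `alpha * multiplier * k`, i.e. the density
#' of the activation produced by `k` dots of a colour with the given bias
#' multiplier. With `multiplier = 1` this is
#' `1 / sqrt(2 pi alpha^2 k^2) * exp(-(x - k)^2 / (2 alpha^2 k^2))`.
#'
#' @param x Activation value(s).
#' @param k Hypothesised dot count, integer `>= 1`.
#' @param alpha Noise coefficient.
#' @param multiplier Colour-bias multiplier.
#' @return Density value(s).
#' @export
dot_count_likelihood <- function(x, k, alpha, multiplier = 1) {
  if (any(k < 1)) stop("hypothesised dot counts must be >= 1")
  stopifnot(alpha > 0, multiplier > 0)
  stats::dnorm(x, mean = multiplier * k, sd = alpha * multiplier * k)
}

# BCH posterior for rows whose chosen colour has activations xi against
# competitors xj, xb (multipliers mi, mj, mb). Accumulates the factored sums
# over the k grid:
#   num = sum_k L_k(xi) (C_{k-1}(xj) + L_k(xj)/2)(C_{k-1}(xb) + L_k(xb)/2)
#         + 1/12 sum_k L_k(xi) L_k(xj) L_k(xb)
#   den = sum_k L_k(xi) * sum_k L_k(xj) * sum_k L_k(xb)
# The 1/12 term lifts the triple-tie weight from 1/4 (two halves multiplied)
# to the correct 1/3.
.bch_group <- function(xi, xj, xb, mi, mj, mb, alpha, ks,
                       zj = FALSE, zb = FALSE) {
  n <- length(xi)
  num <- den_i <- numeric(n)
  # a competitor with a degenerate zero activation is known to have zero
  # dots: its dominance factor is identically 1 (every k >= 1 beats it),
  # its denominator factor is 1, and it can never tie, which the
  # zero-likelihood / unit-cumulative initialisation realises
  cum_j <- if (zj) rep(1, n) else numeric(n)
  cum_b <- if (zb) rep(1, n) else numeric(n)
  for (k in ks) {
    li <- stats::dnorm(xi, mi * k, alpha * mi * k)
    lj <- if (zj) 0 else stats::dnorm(xj, mj * k, alpha * mj * k)
    lb <- if (zb) 0 else stats::dnorm(xb, mb * k, alpha * mb * k)
    num <- num + li * (cum_j + 0.5 * lj) * (cum_b + 0.5 * lb) +
      (1 / 12) * li * lj * lb
    cum_j <- cum_j + lj
    cum_b <- cum_b + lb
    den_i <- den_i + li
  }
  # float guard: the ratio can stray outside [0, 1] by rounding when the
  # posterior saturates
  pmin(pmax(num / (den_i * cum_j * cum_b), 0), 1)
}

#' Bayesian Confidence Hypothesis posterior
#'
#' The posterior probability that the chosen (maximum-activation) colour
#' truly has the most dots, given the activation triple and the
#' scalar-variability generative model, marginalising the unknown dot counts
#' of all three colours over an integer grid (uniform independent prior over
#' `k_min..k_max` per colour). Tuples where the chosen colour ties one
#' competitor count as correct with probability 1/2, and triple ties with
#' probability 1/3. Each colour's likelihood uses that colour's bias
#' multiplier.
#'
#' An activation of exactly zero is the point-mass observation produced by a
#' zero-dot colour and dominates any continuous density: the observer
#' concludes that colour has zero dots with certainty, so it drops out of
#' the dominance competition (every hypothesised count of the chosen colour
#' beats it). This keeps the posterior scale invariant for designs
#' containing two-colour (zero-dot) conditions.
#'
#' @param x Activation triple, or an n x 3 matrix (columns red, green,
#'   blue).
#' @param alpha Noise coefficient of the decision model.
#' @param multipliers Colour-bias multipliers (red, green, blue).
#' @param k_min,k_max Integer bounds of the dot-count hypothesis grid.
#' @param chunk Rows processed per block (memory control only).
#' @return Numeric vector of posterior probabilities in \[0, 1\].
#' @examples
#' conf_bch(c(150, 5, 5), alpha = 0.27)  # ~1
#' conf_bch(c(80, 80, 80), alpha = 0.27) # exactly 1/3
#' @export
conf_bch <- function(x, alpha, multipliers = c(1, 1, 1), k_min = 1L,
                     k_max = 200L, chunk = 50000L) {
  x <- .as_activation_matrix(x)
  stopifnot(alpha > 0, length(multipliers) == 3, all(multipliers > 0),
            k_min >= 1, k_max >= k_min)
  ks <- seq.int(k_min, k_max)
  out <- numeric(nrow(x))
  chosen <- max.col(x, ties.method = "first")
  zero <- x == 0
  # degenerate chosen activation (all colours sampled <= 0): the chosen
  # colour is known to have zero dots and cannot dominate competitors whose
  # hypothesised counts start at k_min >= 1, unless every colour is zero
  deg_chosen <- zero[cbind(seq_len(nrow(x)), chosen)]
  out[deg_chosen] <- ifelse(rowSums(zero[deg_chosen, , drop = FALSE]) == 3,
                            1 / 3, 0)
  for (start in seq(1L, nrow(x), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(x))
    idx <- idx[!deg_chosen[idx]]
    for (i in 1:3) {
      for (zj in c(FALSE, TRUE)) for (zb in c(FALSE, TRUE)) {
        oth <- setdiff(1:3, i)
        rows <- idx[chosen[idx] == i & zero[idx, oth[1]] == zj &
                      zero[idx, oth[2]] == zb]
        if (!length(rows)) next
        out[rows] <- .bch_group(x[rows, i], x[rows, oth[1]], x[rows, oth[2]],
                                multipliers[i], multipliers[oth[1]],
                                multipliers[oth[2]], alpha, ks,
                                zj = zj, zb = zb)
      }
    }
  }
  out
}

#' Map a confidence variable to a 1-4 rating
#'
#' Rating = 1 + number of criteria less than or equal to the confidence
#' variable (a value on a criterion boundary receives the higher rating).
#'
#' @param conf_var Numeric vector of confidence-variable values.
#' @param c_params A [confidence_params()] object.
#' @return Integer vector of ratings in 1..4.
#' @export
map_to_rating <- function(conf_var, c_params) {
  stopifnot(inherits(c_params, "dotconf_cparams"))
  findInterval(conf_var, c_params$criteria) + 1L
}

# confidence variable for a matrix of activations under one model
.conf_variable <- function(x, model, d_params, k_min = 1L, k_max = 200L) {
  switch(model,
    top2diff = conf_top2diff(x),
    bch = conf_bch(x, d_params$alpha, d_params$multipliers,
                   k_min = k_min, k_max = k_max),
    pe = conf_pe(x),
    stop("unknown confidence model: ", model)
  )
}

#' Simulate choice and confidence responses
#'
#' Simulates `n` trials of one condition x configuration cell: activations
#' are drawn from the decision model; on non-lapse trials the choice is the
#' maximal activation and the rating is the criterion-mapped confidence
#' variable of the requested model; on lapse trials both the choice
#' (uniform over the three colours) and the rating (uniform over 1..4) are
#' random and stimulus-independent.
#'
#' @inheritParams sample_activations
#' @param c_params A [confidence_params()] object.
#' @param model One of `"top2diff"`, `"bch"`, `"pe"`.
#' @param n Number of trials.
#' @param lapse_confidence If `"uniform"` (default) lapse trials draw a
#'   uniform rating; if `"model"` the rating still reflects the sampled
#'   activations.
#' @return A data.frame with columns `choice` (colour index), `confidence`
#'   (rating 1-4), and `correct` (logical).
#' @export
simulate_response <- function(dots, config_row, d_params, c_params,
                              model = c("top2diff", "bch", "pe"), n = 1,
                              lapse_confidence = c("uniform", "model")) {
  model <- match.arg(model)
  lapse_confidence <- match.arg(lapse_confidence)
  stopifnot(inherits(d_params, "dotconf_dparams"),
            inherits(c_params, "dotconf_cparams"))
  x <- sample_activations(dots, config_row, d_params, n = n)
  choice <- max.col(x, ties.method = "first")
  rating <- map_to_rating(.conf_variable(x, model, d_params), c_params)
  if (d_params$lapse > 0) {
    lapsed <- stats::runif(n) < d_params$lapse
    if (any(lapsed)) {
      choice[lapsed] <- sample.int(3, sum(lapsed), replace = TRUE)
      if (lapse_confidence == "uniform")
        rating[lapsed] <- sample.int(4, sum(lapsed), replace = TRUE)
    }
  }
  data.frame(choice = choice, confidence = as.integer(rating),
             correct = choice == config_row[1])
}
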