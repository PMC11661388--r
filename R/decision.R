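#' Decision-model parameters
#'
#' Parameters of the scalar-variability decision model. The internal
#' activation produced by `n` dots of a colour with multiplier `m` is
#' Gaussian with mean `m * n` and standard deviation `alpha * m * n`
#' (Weber-law-consistent noise: the sd grows linearly with the count). The
#' one-parameter model is the special case `m_green = m_blue = 1`,
#' `lapse = 0`; the four-parameter model frees the two colour multipliers
#' (red is the reference colour, multiplier fixed at 1) and a lapse rate
#' `lapse`, the proportion of trials answered at random irrespective of the
#' stimulus.
#'
#' @param alpha Positive noise coefficient.
#' @param m_green,m_blue Positive colour-bias multipliers (red fixed at 1).
#' @param lapse Lapse rate in \[0, 1\].
#' @return An object of class `dotconf_dparams`.
#' @examples
#' decision_params(0.27)
#' decision_params(0.18, m_green = 1.1, m_blue = 0.9, lapse = 0.06)
#' @export
decision_params <- function(alpha, m_green = 1, m_blue = 1, lapse = 0) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, is.finite(alpha), alpha > 0,
            is.numeric(m_green), length(m_green) == 1, m_green > 0,
            is.numeric(m_blue), length(m_blue) == 1, m_blue > 0,
            is.numeric(lapse), length(lapse) == 1, lapse >= 0, lapse <= 1)
  structure(
    list(alpha = alpha, multipliers = c(red = 1, green = m_green, blue = m_blue),
         lapse = lapse),
    class = "dotconf_dparams"
  )
}

#' @export
print.dotconf_dparams <- function(x, ...) {
  cat(sprintf("decision params: alpha = %.4g, m = (1, %.4g, %.4g), lapse = %.4g\n",
              x$alpha, x$multipliers[2], x$multipliers[3], x$lapse))
  invisible(x)
}

#' Mean and sd of the activation produced by n dots
#'
#' @param n Non-negative dot count (vectorised).
#' @param multiplier Colour multiplier.
#' @param params A [decision_params()] object (supplies `alpha`).
#' @return A two-column matrix with columns `mean` and `sd`; `n = 0` yields
#'   the degenerate point mass at 0 (`sd = 0`).
#' @export
activation_distribution <- function(n, multiplier = 1, params) {
  if (any(n < 0)) stop("dot counts must be non-negative")
  stopifnot(inherits(params, "dotconf_dparams"))
  cbind(mean = multiplier * n, sd = params$alpha * multiplier * n)
}

# dot counts per colour implied by a condition's per-rank counts under one
# counterbalancing configuration
.dots_by_color <- function(dots, config_row) {
  out <- numeric(3)
  out[config_row] <- dots
  out
}

#' Sample internal activations for one condition and configuration
#'
#' Draws independent activations for the three colours from the Gaussian
#' activation distributions implied by the condition's dot counts, the
#' configuration's rank-to-colour assignment, and the decision parameters.
#'
#' @param dots Numeric triple of per-rank dot counts.
#' @param config_row Integer triple mapping ranks to colour indices (one row
#'   of [color_configurations()]).
#' @param params A [decision_params()] object.
#' @param n Number of samples.
#' @return An `n` x 3 matrix of activations, columns ordered red, green,
#'   blue.
#' @export
sample_activations <- function(dots, config_row, params, n = 1) {
  .validate_condition(dots)
  stopifnot(inherits(params, "dotconf_dparams"))
  nc <- .dots_by_color(dots, config_row)
  mu <- params$multipliers * nc
  sd <- params$alpha * params$multipliers * nc
  x <- matrix(stats::rnorm(3L * n, mean = rep(mu, each = n),
                           sd = rep(sd, each = n)), nrow = n)
  colnames(x) <- dotconf_colors()
  x
}

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenvalue
# method; cached per order.
.gl_cache <- new.env(parent = emptyenv())
.gauss_legendre <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  res <- list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
  .gl_cache[[key]] <- res
  res
}

# P(X_i is the maximum) for one colour i given per-colour means/sds,
# integrating phi_i(x) * prod_j F_j(x) over the support of X_i.
# Degenerate components (sd = 0, point mass at mu) enter the product as step
# functions. `method` "gl": fixed 201-node Gauss-Legendre panel (fast,
# deterministic); "adaptive": stats::integrate at rel.tol 1e-9.
.p_max_one <- function(i, mu, sd, method = "gl") {
  deg <- sd == 0
  others <- setdiff(1:3, i)
  if (deg[i]) {
    # point mass at mu[i]; ties among degenerate components resolve to the
    # lowest colour index
    p <- 1
    for (j in others) {
      p <- p * if (deg[j]) {
        if (mu[j] > mu[i] || (mu[j] == mu[i] && j < i)) 0 else 1
      } else stats::pnorm(mu[i], mu[j], sd[j])
    }
    return(p)
  }
  lo <- mu[i] - 10 * sd[i]
  hi <- mu[i] + 10 * sd[i]
  # a degenerate competitor at mu[j] contributes the step 1[x >= mu[j]]
  for (j in others) if (deg[j]) lo <- max(lo, mu[j])
  if (lo >= hi) return(0)
  f <- function(x) {
    v <- stats::dnorm(x, mu[i], sd[i])
    for (j in others) if (!deg[j]) v <- v * stats::pnorm(x, mu[j], sd[j])
    v
  }
  if (method == "adaptive") {
    return(stats::integrate(f, lo, hi, rel.tol = 1e-9, abs.tol = 1e-12,
                            subdivisions = 400L)$value)
  }
  gl <- .gauss_legendre(201L)
  x <- (hi - lo) / 2 * gl$nodes + (hi + lo) / 2
  (hi - lo) / 2 * sum(gl$weights * f(x))
}

#' Exact choice probabilities for one condition and configuration
#'
#' Computes `P(choice = colour)` under the decision model: the probability
#' that each colour's activation is the largest, mixed with the lapse
#' component, `p_i = (1 - lapse) P(X_i = max) + lapse / 3`. The
#' max-probability integral is evaluated by one-dimensional quadrature of
#' `phi_i(x) prod_j Phi_j(x)`; zero-dot colours are handled as point masses
#' at zero (step functions inside the product).
#'
#' @inheritParams sample_activations
#' @param method `"gl"` (default): fixed-order Gauss-Legendre panel
#'   quadrature; `"adaptive"`: adaptive quadrature via [stats::integrate()].
#'   The two agree to about 1e-8 on non-degenerate inputs.
#' @return Named numeric triple of probabilities (red, green, blue) summing
#'   to 1.
#' @examples
#' d <- build_design("expt1")
#' choice_probabilities(d$conditions[2, ], d$configurations[2, ],
#'                      decision_params(0.27))
#' @export
choice_probabilities <- function(dots, config_row, params, method = c("gl", "adaptive")) {
  method <- match.arg(method)
  .validate_condition(dots)
  stopifnot(inherits(params, "dotconf_dparams"))
  if (all(dots == 0)) stop("all-zero dot counts: no dominant colour exists")
  nc <- .dots_by_color(dots, config_row)
  mu <- params$multipliers * nc
  sd <- params$alpha * params$multipliers * nc
  p <- vapply(1:3, .p_max_one, numeric(1), mu = mu, sd = sd, method = method)
  p <- p / sum(p)  # quadrature residual of order <=1e-10
  p <- (1 - params$lapse) * p + params$lapse / 3
  names(p) <- dotconf_colors()
  p
}

#' Predicted accuracy for one condition
#'
#' Probability of choosing the dominant colour, averaged over the six
#' counterbalancing configurations. With identity multipliers the model is
#' colour-symmetric, so every configuration contributes the same value.
#'
#' @inheritParams sample_activations
#' @return A single probability.
#' @export
predicted_accuracy <- function(dots, params) {
  cfg <- .configurations()
  mean(vapply(seq_len(nrow(cfg)), function(c) {
    choice_probabilities(dots, cfg[c, ], params)[cfg[c, 1]]
  }, numeric(1)))
}
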