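# Independent oracles used across the suite. These deliberately avoid the
# package's factored/quadrature code paths.

# O(k^3) brute-force BCH posterior: enumerate every (k_chosen, k2, k3) tuple
# on the grid and apply the tie weights directly.
bch_brute_force <- function(x, alpha, multipliers = c(1, 1, 1), k_max = 40) {
  ks <- seq_len(k_max)
  L <- vapply(1:3, function(c) dnorm(x[c], multipliers[c] * ks,
                                     alpha * multipliers[c] * ks),
              numeric(k_max))
  i <- which.max(x)
  oth <- setdiff(1:3, i)
  g <- expand.grid(ki = ks, kj = ks, kb = ks)
  w <- numeric(nrow(g))
  w[g$ki > g$kj & g$ki > g$kb] <- 1
  w[g$ki == g$kj & g$ki > g$kb] <- 0.5
  w[g$ki == g$kb & g$ki > g$kj] <- 0.5
  w[g$ki == g$kj & g$ki == g$kb] <- 1 / 3
  num <- sum(w * L[g$ki, i] * L[g$kj, oth[1]] * L[g$kb, oth[2]])
  num / (sum(L[, 1]) * sum(L[, 2]) * sum(L[, 3]))
}

# Monte-Carlo choice-probability oracle: brute-force sampling + argmax.
mc_choice_probs <- function(dots, config_row, params, n = 1e6) {
  x <- sample_activations(dots, config_row, params, n = n)
  p <- tabulate(max.col(x, ties.method = "first"), 3) / n
  (1 - params$lapse) * p + params$lapse / 3
}

# random valid condition (distinct dominant count) for property tests
random_condition <- function(lo = 20, hi = 150) {
  d <- sort(sample(lo:hi, 3), decreasing = TRUE)
  if (d[1] == d[2]) d[1] <- d[1] + 1L
  d
}
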