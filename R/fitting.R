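#' Tabulate trials into a response table
#'
#' The response table is the sufficient statistic for all likelihoods: the
#' count of trials in every (choice, confidence, condition, configuration)
#' cell.
#'
#' @param trials A trial data.frame (see [simulate_subject()]) with columns
#'   `choice`, `confidence`, `condition`, `configuration`.
#' @param design The `dotconf_design` the trials were collected under.
#' @return A 3 x 4 x K x 6 integer array (choice, rating, condition,
#'   configuration).
#' @export
response_table <- function(trials, design) {
  stopifnot(inherits(design, "dotconf_design"))
  K <- design$n_conditions
  stopifnot(all(trials$choice %in% 1:3), all(trials$confidence %in% 1:4),
            all(trials$condition %in% seq_len(K)),
            all(trials$configuration %in% 1:6))
  idx <- trials$choice + 3L * ((trials$confidence - 1L) +
         4L * ((trials$condition - 1L) + K * (trials$configuration - 1L)))
  array(tabulate(idx, nbins = 12L * K * 6L), dim = c(3L, 4L, K, 6L))
}

#' Choice table (marginal over confidence)
#'
#' @param table A response table from [response_table()], or a trial
#'   data.frame plus `design`.
#' @param design Required when `table` is a trial data.frame.
#' @return A 3 x K x 6 array of choice counts.
#' @export
choice_table <- function(table, design = NULL) {
  if (is.data.frame(table)) table <- response_table(table, design)
  apply(table, c(1, 3, 4), sum)
}

#' Multinomial log-likelihood of a response table
#'
#' `sum(n * log(p))` over all cells. Cells with zero counts contribute
#' nothing even when their predicted probability is zero; a zero (or
#' negative) probability at an occupied cell returns `-Inf` rather than
#' raising an error, so optimizers can recover.
#'
#' @param counts Array of observed counts.
#' @param p Array of predicted probabilities, same shape.
#' @return The log-likelihood (possibly `-Inf`).
#' @export
log_likelihood <- function(counts, p) {
  if (length(counts) != length(p))
    stop("counts and probabilities must have the same shape")
  occ <- counts > 0
  if (any(p[occ] <= 0)) return(-Inf)
  sum(counts[occ] * log(p[occ]))
}

# Reservoir of simulated (choice, confidence-variable) pairs, one block of
# mc_samples activation draws per (condition, configuration) cell, generated
# with lapse = 0 (the lapse component is added analytically downstream).
# Fixed seed => fixed reservoir, so criterion searches see a consistent
# objective (common random numbers).
.confidence_reservoir <- function(design, d_params, model, mc_samples, seed) {
  if (mc_samples < 10000)
    message("mc_samples = ", mc_samples,
            " is low; cell probabilities will be noisy")
  K <- design$n_conditions
  d0 <- decision_params(d_params$alpha, d_params$multipliers[2],
                        d_params$multipliers[3], lapse = 0)
  withr::with_seed(seed, {
    n_tot <- K * 6L * mc_samples
    cond <- integer(n_tot); cfg <- integer(n_tot)
    choice <- integer(n_tot); conf <- numeric(n_tot)
    pos <- 0L
    for (c in 1:6) for (k in seq_len(K)) {
      x <- sample_activations(design$conditions[k, ],
                              design$configurations[c, ], d0, n = mc_samples)
      rows <- pos + seq_len(mc_samples)
      cond[rows] <- k; cfg[rows] <- c
      choice[rows] <- max.col(x, ties.method = "first")
      conf[rows] <- .conf_variable(x, model, d0)
      pos <- pos + mc_samples
    }
    list(cond = cond, cfg = cfg, choice = choice, conf = conf,
         mc_samples = mc_samples, K = K, model = model, seed = seed)
  })
}

# (choice, rating, condition, configuration) probabilities from a reservoir
# for a given criterion triple: the non-lapse component is the empirical
# frequency of each cell among the reservoir draws, the lapse component is
# the analytic lapse/12 per cell; cells are floored at eps and renormalized
# within each (condition, configuration) slice.
.cell_probs_from_reservoir <- function(res, criteria, lapse, eps = 1e-6) {
  K <- res$K
  rating <- findInterval(res$conf, criteria) + 1L
  idx <- res$choice + 3L * ((rating - 1L) +
         4L * ((res$cond - 1L) + K * (res$cfg - 1L)))
  p <- array(tabulate(idx, nbins = 12L * K * 6L) / res$mc_samples,
             dim = c(3L, 4L, K, 6L))
  p <- (1 - lapse) * p + lapse / 12
  p <- pmax(p, eps)
  slice_tot <- apply(p, c(3, 4), sum)
  sweep(p, c(3, 4), slice_tot, "/")
}

#' Model-predicted cell probabilities
#'
#' Joint probability of every (choice, confidence rating) pair within each
#' (condition, configuration) cell, under a decision model, a confidence
#' model, and a criterion set. The non-lapse component is estimated from a
#' common reservoir of `mc_samples` activation draws per cell (choice by
#' argmax, rating by criterion mapping of the model's confidence variable);
#' the lapse component contributes `lapse / 12` to every cell analytically.
#' Each cell is floored at `1e-6` and the slice renormalized.
#'
#' @param design A `dotconf_design`.
#' @param d_params A [decision_params()] object.
#' @param c_params A [confidence_params()] object.
#' @param model Confidence model label.
#' @param mc_samples Draws per (condition, configuration) cell.
#' @param seed Seed for the reservoir (same seed, same probabilities).
#' @return A 3 x 4 x K x 6 probability array; each (condition,
#'   configuration) slice sums to 1.
#' @export
predict_cell_probabilities <- function(design, d_params, c_params,
                                       model = c("top2diff", "bch", "pe"),
                                       mc_samples = 20000, seed = 1) {
  model <- match.arg(model)
  stopifnot(inherits(design, "dotconf_design"),
            inherits(d_params, "dotconf_dparams"),
            inherits(c_params, "dotconf_cparams"))
  res <- .confidence_reservoir(design, d_params, model, mc_samples, seed)
  .cell_probs_from_reservoir(res, c_params$criteria, d_params$lapse)
}

.fit_result <- function(params, loglik, n_params, n_restarts, converged,
                        model, details = list()) {
  structure(
    list(params = params, loglik = loglik,
         aic = -2 * loglik + 2 * n_params, n_params = n_params,
         n_restarts = n_restarts, converged = converged, model = model,
         details = details),
    class = "dotconf_fit"
  )
}

#' @export
print.dotconf_fit <- function(x, ...) {
  cat("model:", x$model, "\n")
  cat("params:", paste(sprintf("%s = %.4g", names(x$params), x$params),
                       collapse = ", "), "\n")
  cat(sprintf("logL = %.3f, AIC = %.3f (k = %d, restarts = %d, converged = %s)\n",
              x$loglik, x$aic, x$n_params, x$n_restarts, x$converged))
  invisible(x)
}

#' Serialize a fit result to JSON
#'
#' @param fit A `dotconf_fit`.
#' @param path Optional output file.
#' @return JSON string (invisibly when written to a file).
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "dotconf_fit"))
  obj <- fit
  class(obj) <- NULL
  obj$params <- as.list(obj$params)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

# choice counts re-expressed by dominance rank (valid whenever the model is
# colour-symmetric, i.e. identity multipliers): rank_counts[r, k] = number
# of trials in condition k whose chosen colour occupied rank r
.rank_choice_table <- function(ctab, design) {
  K <- design$n_conditions
  out <- matrix(0, 3, K)
  cfg <- design$configurations
  for (c in 1:6) for (r in 1:3) out[r, ] <- out[r, ] + ctab[cfg[c, r], , c]
  out
}

# per-rank choice probabilities for one condition (colour-symmetric model)
.rank_choice_probs <- function(dots, alpha, lapse = 0) {
  mu <- as.numeric(dots)
  sd <- alpha * mu
  p <- vapply(1:3, .p_max_one, numeric(1), mu = mu, sd = sd, method = "gl")
  p <- p / sum(p)
  (1 - lapse) * p + lapse / 3
}

#' Fit the one-parameter decision model
#'
#' Maximum-likelihood estimate of the noise coefficient `alpha` from the
#' choice marginal, using exact quadrature choice probabilities (no Monte
#' Carlo). `alpha` is searched on \[0.01, 2\] with a bounded derivative-free
#' method, run `n_restarts` times with the best solution kept.
#'
#' @param ctab A 3 x K x 6 choice-count array (see [choice_table()]).
#' @param design The matching `dotconf_design`.
#' @param n_restarts Number of optimization runs.
#' @return A `dotconf_fit` with `params["alpha"]`; `details$at_boundary`
#'   flags estimates within 1e-3 of the search bounds.
#' @export
fit_decision_1p <- function(ctab, design, n_restarts = 2) {
  stopifnot(inherits(design, "dotconf_design"))
  if (sum(ctab) == 0) stop("empty choice table")
  rtab <- .rank_choice_table(ctab, design)
  K <- design$n_conditions
  nll <- function(alpha) {
    ll <- 0
    for (k in seq_len(K)) {
      p <- .rank_choice_probs(design$conditions[k, ], alpha)
      ll <- ll + log_likelihood(rtab[, k], pmax(p, 1e-300))
    }
    -ll
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    opt <- stats::optimize(nll, interval = c(0.01, 2), tol = 1e-7)
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  alpha <- best$minimum
  .fit_result(c(alpha = alpha), -best$objective, 1L, n_restarts,
              converged = TRUE, model = "decision_1p",
              details = list(at_boundary = alpha < 0.01 + 0.02 ||
                               alpha > 2 - 0.02,
                             bounds = c(0.01, 2)))
}

# box transform for Nelder-Mead on bounded parameters
.to_unit <- function(theta, lb, ub) stats::qlogis(pmin(pmax((theta - lb) / (ub - lb), 1e-8), 1 - 1e-8))
.from_unit <- function(t, lb, ub) lb + (ub - lb) * stats::plogis(t)

#' Fit the four-parameter decision model
#'
#' Maximum-likelihood estimation of `(alpha, m_green, m_blue, lapse)` from
#' the choice marginal (red's multiplier is the reference, fixed at 1).
#' Choice probabilities are exact quadrature values; the bounded search
#' (alpha in \[0.01, 2\], multipliers in \[0.5, 2\], lapse in \[0, 0.5\])
#' uses Nelder-Mead on a logistic box transform with `n_restarts` jittered
#' starts, keeping the best run.
#'
#' @inheritParams fit_decision_1p
#' @param start Optional starting values `c(alpha, m_green, m_blue, lapse)`.
#' @param seed Seed for the restart jitter.
#' @return A `dotconf_fit` with named params.
#' @export
fit_decision_4p <- function(ctab, design, n_restarts = 2, start = NULL,
                            seed = 1) {
  stopifnot(inherits(design, "dotconf_design"))
  if (sum(ctab) == 0) stop("empty choice table")
  K <- design$n_conditions
  lb <- c(0.01, 0.5, 0.5, 0)
  ub <- c(2, 2, 2, 0.5)
  if (is.null(start)) start <- c(0.3, 1, 1, 0.05)
  nll <- function(t) {
    th <- .from_unit(t, lb, ub)
    dp <- decision_params(th[1], th[2], th[3], th[4])
    ll <- 0
    for (c in 1:6) for (k in seq_len(K)) {
      nk <- ctab[, k, c]
      if (sum(nk) == 0) next
      p <- choice_probabilities(design$conditions[k, ],
                                design$configurations[c, ], dp)
      ll <- ll + log_likelihood(nk, pmax(p, 1e-300))
    }
    -ll
  }
  starts <- withr::with_seed(seed, {
    lapply(seq_len(n_restarts), function(r) {
      t0 <- .to_unit(start, lb, ub)
      if (r > 1) t0 <- t0 + stats::rnorm(4, 0, 0.5)
      t0
    })
  })
  best <- NULL
  for (t0 in starts) {
    opt <- stats::optim(t0, nll, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-9))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  th <- .from_unit(best$par, lb, ub)
  names(th) <- c("alpha", "m_green", "m_blue", "lapse")
  .fit_result(th, -best$value, 4L, n_restarts,
              converged = best$convergence == 0, model = "decision_4p",
              details = list(bounds = rbind(lb = lb, ub = ub), seed = seed,
                             at_boundary = any(th < lb + 0.02 * (ub - lb) |
                                               th > ub - 0.02 * (ub - lb))))
}

#' Fit a confidence model's criteria
#'
#' Maximum-likelihood estimation of the three confidence criteria from the
#' full joint (choice, confidence) response table, with the decision
#' parameters held fixed at their previously fitted values (a common set of
#' assumptions across the three confidence models). Cell probabilities come
#' from a single fixed reservoir of activation draws (common random
#' numbers), so moving the criteria re-bins the same samples. Criteria are
#' parametrized as an ordered triple (base plus positive increments) on the
#' linear scale for Top2Diff / PE and on the logit scale for BCH, whose
#' confidence variable lives in (0, 1). All three confidence models have
#' k = 3 free parameters in the AIC.
#'
#' @param table A 3 x 4 x K x 6 response table.
#' @param design The matching `dotconf_design`.
#' @param d_params Fixed [decision_params()] (typically from
#'   [fit_decision_4p()]).
#' @param model Confidence model label.
#' @param mc_samples Reservoir draws per (condition, configuration).
#' @param seed Reservoir / restart seed.
#' @param n_restarts Number of jittered Nelder-Mead runs.
#' @return A `dotconf_fit` with `params = c(c1, c2, c3)`.
#' @export
fit_confidence <- function(table, design, d_params,
                           model = c("top2diff", "bch", "pe"),
                           mc_samples = 20000, seed = 1, n_restarts = 2) {
  model <- match.arg(model)
  stopifnot(inherits(design, "dotconf_design"),
            inherits(d_params, "dotconf_dparams"))
  if (sum(table) == 0) stop("empty response table")
  res <- .confidence_reservoir(design, d_params, model, mc_samples, seed)
  logit_scale <- model == "bch"
  bwd <- function(t) {   # unconstrained -> criteria
    z <- cumsum(c(t[1], exp(t[2:3])))
    if (logit_scale) stats::plogis(z) else z
  }
  nll <- function(t) {
    cr <- bwd(t)
    if (any(!is.finite(cr)) || any(diff(cr) <= 0)) return(1e12)
    p <- .cell_probs_from_reservoir(res, cr, d_params$lapse)
    -log_likelihood(table, p)
  }
  # start at the pooled confidence-variable quartiles, made strictly
  # increasing on the search scale (saturated reservoirs, e.g. a BCH
  # posterior pinned at 1, can give tied or degenerate quantiles)
  q <- stats::quantile(res$conf, c(0.25, 0.5, 0.75), names = FALSE)
  if (logit_scale) q <- pmin(pmax(q, 1e-6), 1 - 1e-6)
  z <- if (logit_scale) stats::qlogis(q) else q
  for (i in 2:3)
    if (z[i] <= z[i - 1]) z[i] <- z[i - 1] + max(0.1, 0.01 * abs(z[i - 1]))
  t_start <- c(z[1], log(diff(z)))
  starts <- withr::with_seed(seed + 1L, {
    lapply(seq_len(n_restarts), function(r) {
      if (r == 1) t_start else t_start + stats::rnorm(3, 0, 0.3)
    })
  })
  best <- NULL
  for (t0 in starts) {
    opt <- stats::optim(t0, nll, method = "Nelder-Mead",
                        control = list(maxit = 1500, reltol = 1e-8))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  cr <- bwd(best$par)
  names(cr) <- c("c1", "c2", "c3")
  .fit_result(cr, -best$value, 3L, n_restarts,
              converged = TRUE, model = model,
              details = list(d_params = unclass(d_params),
                             mc_samples = mc_samples, seed = seed,
                             scale = if (logit_scale) "logit" else "linear"))
}

#' Compare fitted models by AIC with bootstrap confidence intervals
#'
#' Takes one AIC per subject per model and reports, for every model against
#' the reference (by default the model with the lowest summed AIC):
#' per-subject AIC differences, the summed difference, the number of
#' subjects favouring the reference, a bootstrap 95% confidence interval of
#' the summed difference (resampling subjects with replacement), and the
#' relative-likelihood interpretation `exp(delta_AIC / 2)`.
#'
#' @param aic_table data.frame with columns `subject`, `model`, `aic`.
#' @param reference Reference model label; `NULL` picks the lowest summed
#'   AIC.
#' @param n_boot Bootstrap resamples (default 100,000).
#' @param seed Bootstrap seed.
#' @return An object of class `dotconf_comparison`: list with the reference
#'   label, a `summary` data.frame (one row per non-reference model) and the
#'   per-subject difference matrix.
#' @export
compare_models <- function(aic_table, reference = NULL, n_boot = 100000,
                           seed = 1) {
  stopifnot(all(c("subject", "model", "aic") %in% names(aic_table)))
  models <- unique(aic_table$model)
  if (length(models) < 2) stop("need at least two models to compare")
  subjects <- sort(unique(aic_table$subject))
  wide <- matrix(NA_real_, length(subjects), length(models),
                 dimnames = list(as.character(subjects), models))
  for (r in seq_len(nrow(aic_table))) {
    wide[as.character(aic_table$subject[r]), aic_table$model[r]] <-
      aic_table$aic[r]
  }
  if (anyNA(wide)) stop("every model must be fitted for every subject")
  if (is.null(reference)) reference <- models[which.min(colSums(wide))]
  if (!reference %in% models) stop("unknown reference model: ", reference)
  others <- setdiff(models, reference)
  n <- length(subjects)
  diffs <- wide[, others, drop = FALSE] - wide[, reference]
  boot <- withr::with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    vapply(others, function(m) {
      sums <- rowSums(matrix(diffs[, m][idx], nrow = n_boot))
      stats::quantile(sums, c(0.025, 0.975), names = FALSE)
    }, numeric(2))
  })
  summary <- data.frame(
    model = others,
    reference = reference,
    summed_delta_aic = colSums(diffs),
    mean_delta_aic = colMeans(diffs),
    wins_reference = colSums(diffs > 0),
    n_subjects = n,
    ci_lo = boot[1, others],
    ci_hi = boot[2, others],
    relative_likelihood = exp(colSums(diffs) / 2),
    row.names = NULL
  )
  structure(list(reference = reference, summary = summary, diffs = diffs,
                 n_boot = n_boot, seed = seed),
            class = "dotconf_comparison")
}

#' @export
print.dotconf_comparison <- function(x, ...) {
  cat("AIC comparison (reference:", x$reference, "; positive differences",
      "favour the reference)\n")
  print(x$summary, digits = 4)
  invisible(x)
}
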