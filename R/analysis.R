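#' Per-subject, per-condition accuracy and confidence
#'
#' @param trials Trial data.frame with columns `subject_id`, `condition`,
#'   `correct`, `confidence`.
#' @return A data.frame with one row per subject x condition: `subject_id`,
#'   `condition`, `accuracy` (proportion correct), `confidence` (mean
#'   rating). Errors if any subject is missing a condition present for
#'   others.
#' @export
summarize_conditions <- function(trials) {
  if (!nrow(trials)) stop("no trials to summarize")
  agg <- stats::aggregate(
    cbind(accuracy = as.numeric(trials$correct),
          confidence = as.numeric(trials$confidence)),
    by = list(subject_id = trials$subject_id, condition = trials$condition),
    FUN = mean
  )
  agg <- agg[order(agg$subject_id, agg$condition), ]
  rownames(agg) <- NULL
  counts <- table(agg$subject_id)
  if (length(unique(counts)) > 1)
    stop("subjects with missing conditions: ",
         paste(names(counts)[counts < max(counts)], collapse = ", "))
  agg
}

# per-subject mean of a measure over a set of conditions
.group_means <- function(summary, conditions, measure) {
  sub <- summary[summary$condition %in% conditions, ]
  if (!nrow(sub)) stop("no rows for conditions ", paste(conditions, collapse = ","))
  out <- tapply(sub[[measure]], sub$subject_id, mean)
  out[order(names(out))]
}

#' Paired contrast between two condition groups
#'
#' For each subject, the measure is averaged within each condition group and
#' the two group means are differenced (a - b); the differences enter a
#' paired t-test. Cohen's d for this paired design is
#' `mean(diff) / sd(diff)`. Two-sided p-values; no multiple-testing
#' correction.
#'
#' @param summary Output of [summarize_conditions()].
#' @param group_a,group_b Condition index vectors.
#' @param measure `"accuracy"` or `"confidence"`.
#' @param label Optional contrast label.
#' @return A one-row data.frame: `label`, `mean_diff`, `t`, `df`, `p`,
#'   `cohens_d`, `n`, `degenerate` (TRUE when the difference sd is 0, where
#'   t is infinite).
#' @export
paired_contrast <- function(summary, group_a, group_b,
                            measure = c("accuracy", "confidence"),
                            label = NULL) {
  measure <- match.arg(measure)
  a <- .group_means(summary, group_a, measure)
  b <- .group_means(summary, group_b, measure)
  stopifnot(identical(names(a), names(b)))
  d <- a - b
  n <- length(d)
  if (n < 2) stop("paired contrast needs at least two subjects")
  m <- mean(d)
  s <- stats::sd(d)
  degenerate <- s == 0
  t_stat <- if (degenerate) ifelse(m == 0, 0, sign(m) * Inf)
            else m / (s / sqrt(n))
  p <- if (degenerate) ifelse(m == 0, 1, 0)
       else 2 * stats::pt(-abs(t_stat), df = n - 1)
  data.frame(
    label = if (is.null(label))
      paste0(measure, ": {", paste(group_a, collapse = ","), "} vs {",
             paste(group_b, collapse = ","), "}") else label,
    measure = measure, mean_diff = m, t = t_stat, df = n - 1L, p = p,
    cohens_d = if (degenerate) ifelse(m == 0, 0, sign(m) * Inf) else m / s,
    n = n, degenerate = degenerate
  )
}

# matched condition groups for the scaled-numerosity contrast
.numerosity_groups <- function(design) {
  switch(design$name,
    expt1 = list(high = 1:3, low = 4:6),
    expt2 = list(high = 1:6, low = 7:12),
    stop("no numerosity grouping for design ", design$name)
  )
}

#' Numerosity-effect contrasts
#'
#' Compares the condition group with larger dot counts against its
#' ratio-matched scaled-down group (Experiment 1: conditions 1-3 vs 4-6;
#' Experiment 2: 1-6 vs 7-12) on both accuracy and confidence. The
#' behavioural signature is a confidence increase with little accuracy
#' change when all counts are scaled up at fixed ratios.
#'
#' @param summary Output of [summarize_conditions()].
#' @param design The `dotconf_design`.
#' @return A two-row data.frame (accuracy and confidence contrasts).
#' @export
numerosity_effect <- function(summary, design) {
  g <- .numerosity_groups(design)
  rbind(
    paired_contrast(summary, g$high, g$low, "accuracy",
                    label = "numerosity: accuracy"),
    paired_contrast(summary, g$high, g$low, "confidence",
                    label = "numerosity: confidence")
  )
}

#' Non-dominant-options trade-off contrasts
#'
#' The four Experiment 2 condition pairs in which the dominant count is held
#' fixed while the two non-dominant counts are redistributed more evenly:
#' 3 vs 5, 9 vs 11, 3 vs 4, 9 vs 10 (first listed condition is the less even
#' one). Reports accuracy and confidence contrasts (first minus second) for
#' each pair; the signature is lower accuracy but equal-or-higher confidence
#' in the less even condition.
#'
#' @param summary Output of [summarize_conditions()] for Experiment 2 data.
#' @param design The `dotconf_design` (must be `"expt2"`).
#' @return An eight-row data.frame.
#' @export
tradeoff_effect <- function(summary, design) {
  if (design$name != "expt2")
    stop("the trade-off contrasts are defined for the expt2 design only")
  pairs <- list(c(3, 5), c(9, 11), c(3, 4), c(9, 10))
  do.call(rbind, lapply(pairs, function(pr) {
    rbind(
      paired_contrast(summary, pr[1], pr[2], "accuracy",
                      label = sprintf("tradeoff %dv%d: accuracy", pr[1], pr[2])),
      paired_contrast(summary, pr[1], pr[2], "confidence",
                      label = sprintf("tradeoff %dv%d: confidence", pr[1], pr[2]))
    )
  }))
}

#' Root-mean-squared error between observed and predicted values
#'
#' The comparison surface is whatever matched pair of numeric structures is
#' supplied (per-condition accuracies, full per-condition choice
#' proportions, confidence means, ...).
#'
#' @param observed,predicted Numeric vectors/arrays of identical shape.
#' @return `sqrt(mean((observed - predicted)^2))`.
#' @export
goodness_of_fit_rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have the same shape")
  sqrt(mean((as.numeric(observed) - as.numeric(predicted))^2))
}

#' Model-implied per-condition accuracy and confidence
#'
#' Computes, from fitted (or assumed) decision and confidence parameters,
#' the model-predicted probability of a correct choice and the predicted
#' mean confidence rating for every condition, marginalised over the six
#' configurations via [predict_cell_probabilities()].
#'
#' @inheritParams predict_cell_probabilities
#' @return A data.frame with columns `condition`, `accuracy`, `confidence`.
#' @export
model_prediction_summary <- function(design, d_params, c_params,
                                     model = c("top2diff", "bch", "pe"),
                                     mc_samples = 20000, seed = 1) {
  model <- match.arg(model)
  p <- predict_cell_probabilities(design, d_params, c_params, model,
                                  mc_samples = mc_samples, seed = seed)
  K <- design$n_conditions
  cfg <- design$configurations
  acc <- conf <- numeric(K)
  for (k in seq_len(K)) {
    for (c in 1:6) {
      slice <- p[, , k, c]
      acc[k] <- acc[k] + sum(slice[cfg[c, 1], ]) / 6
      conf[k] <- conf[k] + sum(colSums(slice) * (1:4)) / 6
    }
  }
  data.frame(condition = seq_len(K), accuracy = acc, confidence = conf)
}
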