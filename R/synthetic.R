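# deterministic sub-seed derivation (minstd congruence keeps values < 2^31)
.derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 7919 + 12345) %% 2147483647)
}

# truncated-normal draws by inverse-CDF (exact, no rejection)
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(min(max(mean, lo), hi), n))
  if (lo >= hi) stop("invalid truncation bounds")
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Default confidence criteria for the synthetic generator
#'
#' Population criterion triples for each confidence model, frozen after a
#' one-off calibration: the quartiles of the pooled confidence-variable
#' distribution under the Experiment 2 design at `alpha = 0.27` with
#' identity multipliers, so that simulated cohorts use all four ratings in
#' roughly equal proportion.
#'
#' @param model Confidence model label.
#' @return A [confidence_params()] object.
#' @export
default_confidence_criteria <- function(model = c("top2diff", "bch", "pe")) {
  model <- match.arg(model)
  confidence_params(switch(model,
    top2diff = c(9.8, 21.3, 37.2),
    bch = c(0.543, 0.661, 0.790),
    pe = c(82.4, 95.8, 110.7)
  ))
}

#' Specification of one synthetic subject
#'
#' A subject spec fully determines the simulated dataset: the same spec
#' always yields identical trials.
#'
#' @param subject_id Identifier (integer or string).
#' @param design A `dotconf_design` or design name.
#' @param d_params A [decision_params()] object.
#' @param c_params A [confidence_params()] object; defaults to the
#'   generating model's [default_confidence_criteria()].
#' @param model Generating confidence model.
#' @param seed Integer seed.
#' @return An object of class `dotconf_subject_spec`.
#' @export
subject_spec <- function(subject_id, design, d_params,
                         c_params = NULL,
                         model = c("top2diff", "bch", "pe"), seed = 1) {
  model <- match.arg(model)
  if (is.character(design)) design <- build_design(design)
  stopifnot(inherits(design, "dotconf_design"),
            inherits(d_params, "dotconf_dparams"))
  if (is.null(c_params)) c_params <- default_confidence_criteria(model)
  stopifnot(inherits(c_params, "dotconf_cparams"))
  structure(list(subject_id = subject_id, design = design,
                 d_params = d_params, c_params = c_params, model = model,
                 seed = as.integer(seed)),
            class = "dotconf_subject_spec")
}

#' Simulate one subject's full session
#'
#' Builds the counterbalanced trial plan for the spec's design and simulates
#' every trial with the spec's decision parameters, confidence model, and
#' criteria. Trials are generated cell-by-cell (condition x configuration)
#' but returned in the shuffled plan order.
#'
#' @param spec A [subject_spec()].
#' @return A data.frame of trial records: `subject_id`, `trial`,
#'   `condition`, `configuration`, `choice` (colour index), `correct`,
#'   `confidence`.
#' @export
simulate_subject <- function(spec) {
  stopifnot(inherits(spec, "dotconf_subject_spec"))
  design <- spec$design
  plan <- trial_plan(design, .derive_seed(spec$seed, 1L))
  choice <- integer(nrow(plan))
  correct <- logical(nrow(plan))
  rating <- integer(nrow(plan))
  withr::with_seed(.derive_seed(spec$seed, 2L), {
    for (c in 1:6) for (k in seq_len(design$n_conditions)) {
      rows <- which(plan$condition == k & plan$configuration == c)
      if (!length(rows)) next
      resp <- simulate_response(design$conditions[k, ],
                                design$configurations[c, ],
                                spec$d_params, spec$c_params, spec$model,
                                n = length(rows))
      choice[rows] <- resp$choice
      correct[rows] <- resp$correct
      rating[rows] <- resp$confidence
    }
  })
  data.frame(subject_id = spec$subject_id, trial = plan$trial,
             condition = plan$condition, configuration = plan$configuration,
             choice = choice, correct = correct, confidence = rating)
}

#' Simulate a cohort of synthetic subjects
#'
#' Draws per-subject parameters from population distributions and simulates
#' a complete dataset per subject. Defaults reflect the fitted population
#' values of the task: `alpha` ~ truncated normal(0.27, 0.09), lapse ~
#' truncated normal(0.065, 0.04) (both truncated to the fitting bounds),
#' colour multipliers ~ truncated normal(1, 0.05), and criteria jittered
#' around the model's [default_confidence_criteria()] on the search scale
#' (logit for BCH, linear for the others). Per-subject seeds are derived
#' deterministically from the cohort seed.
#'
#' @param n_subjects Number of subjects.
#' @param design A `dotconf_design` or design name.
#' @param model Generating confidence model.
#' @param seed Cohort seed.
#' @param param_distributions List overriding any of `alpha = c(mean, sd)`,
#'   `lapse = c(mean, sd)`, `multiplier = c(mean, sd)`,
#'   `criteria_jitter_sd` (a single sd on the criterion search scale).
#' @return A list with `trials` (one stacked data.frame) and `subjects` (a
#'   data.frame of the true per-subject parameters and seeds).
#' @export
simulate_cohort <- function(n_subjects, design,
                            model = c("top2diff", "bch", "pe"), seed = 1,
                            param_distributions = list()) {
  model <- match.arg(model)
  stopifnot(n_subjects >= 1)
  if (is.character(design)) design <- build_design(design)
  pd <- utils::modifyList(
    list(alpha = c(0.27, 0.09), lapse = c(0.065, 0.04),
         multiplier = c(1, 0.05), criteria_jitter_sd = 0.1),
    param_distributions
  )
  if (pd$alpha[2] < 0 || pd$lapse[2] < 0 || pd$multiplier[2] < 0 ||
      pd$criteria_jitter_sd < 0)
    stop("distribution spreads must be non-negative")
  pop_cr <- default_confidence_criteria(model)$criteria
  subjects <- withr::with_seed(.derive_seed(seed, 0L), {
    data.frame(
      subject_id = seq_len(n_subjects),
      alpha = .rtruncnorm(n_subjects, pd$alpha[1], pd$alpha[2], 0.01, 2),
      m_green = .rtruncnorm(n_subjects, pd$multiplier[1], pd$multiplier[2], 0.5, 2),
      m_blue = .rtruncnorm(n_subjects, pd$multiplier[1], pd$multiplier[2], 0.5, 2),
      lapse = .rtruncnorm(n_subjects, pd$lapse[1], pd$lapse[2], 0, 0.5),
      c1 = NA_real_, c2 = NA_real_, c3 = NA_real_,
      seed = vapply(seq_len(n_subjects), function(i) .derive_seed(seed, i + 100L),
                    integer(1))
    )
  })
  jitter_criteria <- function(jit) {
    if (model == "bch") stats::plogis(stats::qlogis(pop_cr) + jit)
    else pop_cr * exp(jit)
  }
  trials <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    jit <- withr::with_seed(.derive_seed(seed, i + 500L),
                            stats::rnorm(1, 0, pd$criteria_jitter_sd))
    cr <- jitter_criteria(jit)
    subjects[i, c("c1", "c2", "c3")] <- cr
    spec <- subject_spec(
      subject_id = i, design = design,
      d_params = decision_params(subjects$alpha[i], subjects$m_green[i],
                                 subjects$m_blue[i], subjects$lapse[i]),
      c_params = confidence_params(cr), model = model,
      seed = subjects$seed[i]
    )
    trials[[i]] <- simulate_subject(spec)
  }
  list(trials = do.call(rbind, trials), subjects = subjects,
       design = design, model = model, seed = seed)
}
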