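#' Colour labels used throughout the package
#'
#' Colours are represented internally as integer indices 1, 2, 3 with the
#' fixed canonical naming 1 = red, 2 = green, 3 = blue. All computations are
#' colour-symmetric except the bias multipliers of the four-parameter
#' decision model.
#'
#' @return Character vector `c("red", "green", "blue")`.
#' @export
dotconf_colors <- function() c("red", "green", "blue")

# The six counterbalancing configurations. Each row maps dominance rank
# (dominant, middle, fewest) to a colour index; every colour occupies every
# rank in exactly two of the six rows.
.configurations <- function() {
  m <- rbind(
    c(1L, 3L, 2L),  # red,   blue,  green
    c(1L, 2L, 3L),  # red,   green, blue
    c(3L, 1L, 2L),  # blue,  red,   green
    c(3L, 2L, 1L),  # blue,  green, red
    c(2L, 1L, 3L),  # green, red,   blue
    c(2L, 3L, 1L)   # green, blue,  red
  )
  dimnames(m) <- list(NULL, c("dominant", "middle", "fewest"))
  m
}

#' Colour configurations for counterbalancing
#'
#' Returns the six permutations assigning the three colours to the three
#' dominance ranks (dominant, middle, fewest). Used so that each colour
#' appears equally often in each rank across a session.
#'
#' @return A 6 x 3 integer matrix; entry `[c, r]` is the colour index
#'   (1 = red, 2 = green, 3 = blue) occupying rank `r` under configuration
#'   `c`.
#' @export
color_configurations <- function() .configurations()

.expt1_dots <- function() {
  rbind(
    c(100, 75, 75),
    c(100, 75, 40),
    c(100, 75,  0),
    c( 80, 60, 60),
    c( 80, 60, 32),
    c( 80, 60,  0)
  )
}

.expt2_dots <- function() {
  rbind(
    c(98, 84, 72),
    c(98, 84, 60),
    c(98, 84, 48),
    c(98, 72, 72),
    c(98, 72, 60),
    c(98, 72, 48),
    c(84, 72, 62),
    c(84, 72, 52),
    c(84, 72, 42),
    c(84, 62, 62),
    c(84, 62, 52),
    c(84, 62, 42)
  )
}

.validate_condition <- function(dots) {
  if (length(dots) != 3 || any(!is.finite(dots)) || any(dots < 0))
    stop("a condition is a triple of non-negative finite dot counts")
  if (!(dots[1] >= dots[2] && dots[2] >= dots[3]))
    stop("dot counts must be ordered by dominance rank (non-increasing)")
  if (!(dots[1] > dots[2]))
    stop("a unique dominant rank must exist (dots[1] > dots[2])")
  invisible(dots)
}

#' Build an experiment design
#'
#' Constructs the canonical design object for one of the two dot-numerosity
#' experiments: the per-condition dot counts (by dominance rank), the number
#' of trials per subject, and the six counterbalancing colour
#' configurations. Experiment 1 has 6 conditions and 576 trials per subject;
#' conditions 4-6 use exactly 80% of the dot counts of conditions 1-3.
#' Experiment 2 has 12 conditions and 1,440 trials per subject; conditions
#' 7-12 use approximately 85.7% of the counts of conditions 1-6 (integer
#' rounding makes the ratio matching inexact by at most 0.01).
#'
#' @param name `"expt1"` or `"expt2"`.
#' @return An object of class `dotconf_design`: a list with elements
#'   `name`, `conditions` (matrix, one row per condition, columns =
#'   dominance ranks), `n_conditions`, `trials_per_subject`, and
#'   `configurations`.
#' @examples
#' d <- build_design("expt1")
#' d$conditions[2, ]  # 100 75 40
#' @export
build_design <- function(name) {
  if (!is.character(name) || length(name) != 1 || !name %in% c("expt1", "expt2"))
    stop("unknown design name: ", deparse(substitute(name)),
         " (expected \"expt1\" or \"expt2\")")
  dots <- if (name == "expt1") .expt1_dots() else .expt2_dots()
  apply(dots, 1, .validate_condition)
  colnames(dots) <- c("dominant", "middle", "fewest")
  design <- list(
    name = name,
    conditions = dots,
    n_conditions = nrow(dots),
    trials_per_subject = if (name == "expt1") 576L else 1440L,
    configurations = .configurations()
  )
  class(design) <- "dotconf_design"
  design
}

#' @export
print.dotconf_design <- function(x, ...) {
  cat("Dot-numerosity design \"", x$name, "\": ", x$n_conditions,
      " conditions, ", x$trials_per_subject, " trials/subject, ",
      nrow(x$configurations), " colour configurations\n", sep = "")
  print(x$conditions)
  invisible(x)
}

#' Dot-count ratios of a condition
#'
#' Ratios of the three per-rank dot counts relative to the dominant count,
#' e.g. `(100, 75, 40)` gives `(1, .75, .40)`.
#'
#' @param dots Numeric triple of dot counts ordered by dominance rank.
#' @return Numeric triple `(1, dots[2]/dots[1], dots[3]/dots[1])`.
#' @export
condition_ratios <- function(dots) {
  .validate_condition(dots)
  if (dots[1] <= 0) stop("dominant dot count must be positive")
  as.numeric(dots) / dots[1]
}

#' Counterbalanced trial plan
#'
#' Produces the ordered list of (condition, configuration) pairs for one
#' subject. Every pair appears exactly
#' `trials_per_subject / (n_conditions * 6)` times; the order is shuffled
#' uniformly under the given seed. Uniform shuffling is the only ordering
#' constraint applied.
#'
#' @param design A `dotconf_design`.
#' @param seed Integer seed controlling the shuffle.
#' @return A data.frame with columns `trial`, `condition`, `configuration`.
#' @export
trial_plan <- function(design, seed) {
  stopifnot(inherits(design, "dotconf_design"))
  n_cells <- design$n_conditions * nrow(design$configurations)
  if (design$trials_per_subject %% n_cells != 0)
    stop("trials_per_subject (", design$trials_per_subject,
         ") is not divisible by the ", n_cells,
         " condition x configuration cells")
  reps <- design$trials_per_subject %/% n_cells
  grid <- expand.grid(
    condition = seq_len(design$n_conditions),
    configuration = seq_len(nrow(design$configurations))
  )
  plan <- grid[rep(seq_len(nrow(grid)), each = reps), ]
  ord <- withr::with_seed(seed, sample.int(nrow(plan)))
  plan <- plan[ord, ]
  data.frame(
    trial = seq_len(nrow(plan)),
    condition = as.integer(plan$condition),
    configuration = as.integer(plan$configuration)
  )
}

#' Serialize a design to JSON
#'
#' @param design A `dotconf_design`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly if written to a file.
#' @export
design_to_json <- function(design, path = NULL) {
  stopifnot(inherits(design, "dotconf_design"))
  obj <- list(
    name = design$name,
    conditions = unname(apply(design$conditions, 1, as.integer, simplify = FALSE)),
    trials_per_subject = design$trials_per_subject
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a design from JSON
#'
#' Accepts the output of [design_to_json()]. Named designs are rebuilt via
#' [build_design()] so the invariants are re-checked.
#'
#' @param path File path or a JSON string.
#' @return A `dotconf_design`.
#' @export
design_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (obj$name %in% c("expt1", "expt2")) {
    design <- build_design(obj$name)
    stored <- if (is.list(obj$conditions))
      do.call(rbind, lapply(obj$conditions, as.numeric))
    else matrix(as.numeric(obj$conditions), ncol = 3)
    if (!isTRUE(all.equal(unname(design$conditions), unname(stored))) ||
        design$trials_per_subject != obj$trials_per_subject)
      stop("stored design does not match the canonical \"", obj$name, "\" design")
    return(design)
  }
  stop("unknown design name in JSON: ", obj$name)
}
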