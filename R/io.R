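#' Write trial records to the canonical CSV dialect
#'
#' Columns: `subject_id`, `trial`, `condition`, `configuration`,
#' `chosen_color` (lowercase colour name), `correct` (TRUE/FALSE),
#' `confidence` (1-4). UTF-8, header required.
#'
#' @param trials Trial data.frame (see [simulate_subject()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  stopifnot(all(c("subject_id", "trial", "condition", "configuration",
                  "choice", "correct", "confidence") %in% names(trials)))
  out <- data.frame(
    subject_id = trials$subject_id,
    trial = trials$trial,
    condition = trials$condition,
    configuration = trials$configuration,
    chosen_color = dotconf_colors()[trials$choice],
    correct = as.logical(trials$correct),
    confidence = as.integer(trials$confidence)
  )
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

.report_bad_rows <- function(bad, what) {
  if (any(bad))
    stop("invalid ", what, " on row(s): ",
         paste(utils::head(which(bad), 20), collapse = ", "),
         if (sum(bad) > 20) " ..." else "", call. = FALSE)
}

#' Read trial records from CSV
#'
#' Reads and validates a trial CSV in the canonical dialect (see
#' [write_trials()]). Files from other sources can be adapted through
#' `mapping`, a named list whose names are the canonical column names and
#' whose values are the column names found in the file (unmapped canonical
#' names are assumed present verbatim). Validation failures report the
#' offending row numbers.
#'
#' @param path CSV file path.
#' @param design Optional `dotconf_design`; when supplied, condition indices
#'   are checked against its range.
#' @param mapping Optional named list of column-name substitutions, e.g.
#'   `list(subject_id = "Subj", chosen_color = "Resp")`.
#' @return A validated trial data.frame with the internal `choice` colour
#'   index column.
#' @export
read_trials <- function(path, design = NULL, mapping = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  canonical <- c("subject_id", "trial", "condition", "configuration",
                 "chosen_color", "correct", "confidence")
  if (!is.null(mapping)) {
    for (nm in names(mapping)) {
      if (!mapping[[nm]] %in% names(raw))
        stop("mapped column \"", mapping[[nm]], "\" not found in ", path)
      names(raw)[names(raw) == mapping[[nm]]] <- nm
    }
  }
  missing <- setdiff(canonical, names(raw))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  choice <- match(tolower(raw$chosen_color), dotconf_colors())
  .report_bad_rows(is.na(choice), "chosen_color")
  conf <- suppressWarnings(as.integer(raw$confidence))
  .report_bad_rows(is.na(conf) | conf < 1 | conf > 4, "confidence")
  cond <- suppressWarnings(as.integer(raw$condition))
  k_max <- if (is.null(design)) Inf else design$n_conditions
  .report_bad_rows(is.na(cond) | cond < 1 | cond > k_max, "condition")
  cfg <- suppressWarnings(as.integer(raw$configuration))
  .report_bad_rows(is.na(cfg) | cfg < 1 | cfg > 6, "configuration")
  correct <- as.logical(raw$correct)
  .report_bad_rows(is.na(correct), "correct")
  data.frame(subject_id = raw$subject_id, trial = raw$trial,
             condition = cond, configuration = cfg, choice = choice,
             correct = correct, confidence = conf)
}
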