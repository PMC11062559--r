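#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and the CLI) can distinguish bad input from
# I/O failures and from computations that cannot proceed.

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("specrel_validation_error", "specrel_error")))
}

stop_io <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("specrel_io_error", "specrel_error")))
}

stop_computation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("specrel_computation_error", "specrel_error")))
}

# Behavioural outcome labels understood by the package, with their mapping to
# success (correct behaviour) used when splitting Specificity distributions.
.outcome_success <- c(
  hit = TRUE, miss = FALSE,
  correct_rejection = TRUE, false_positive = FALSE,
  correct = TRUE, incorrect = FALSE
)

#' Map behavioural outcome labels to success/failure
#'
#' Hits and correct rejections count as behaviourally correct; misses and
#' false positives as incorrect. The generic `correct`/`incorrect` pair is
#' passed through.
#'
#' @param outcome character vector of outcome labels.
#' @return logical vector, `TRUE` for behaviourally correct trials.
#' @export
outcome_success <- function(outcome) {
  bad <- setdiff(unique(outcome), names(.outcome_success))
  if (length(bad) > 0) {
    stop_validation("unknown outcome label(s): %s", paste(bad, collapse = ", "))
  }
  unname(.outcome_success[as.character(outcome)])
}
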