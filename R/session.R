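#' Construct a population session
#'
#' The unit of analysis: a trials x neurons matrix of time-averaged activity
#' (continuous \eqn{\Delta F/F} values or integer spike counts in a fixed
#' analysis window) together with per-trial metadata (stimulus condition,
#' behavioural outcome, optional covariates).
#'
#' @param responses numeric matrix, trials in rows, neurons in columns.
#' @param trials data.frame with columns `trial_id`, `condition`, `outcome`,
#'   plus optional covariate columns prefixed `cov_`. One row per matrix row,
#'   in the same order.
#' @param modality `"continuous"` (e.g. \eqn{\Delta F/F}, possibly negative)
#'   or `"counts"` (nonnegative integer spike counts).
#' @param neuron_ids character vector of unique neuron identifiers; defaults
#'   to the matrix column names or `n1..nJ`.
#' @param area_label,window_annotation free-text annotations carried along
#'   (e.g. `"S1"`, `"0.5 s post-offset"`); the analysis window itself is
#'   applied upstream, sessions arrive pre-averaged.
#' @return an object of class `population_session`.
#' @examples
#' resp <- matrix(rpois(20, 5), nrow = 4)
#' tr <- data.frame(trial_id = paste0("t", 1:4),
#'                  condition = c("left", "left", "right", "right"),
#'                  outcome = c("hit", "miss", "hit", "hit"))
#' s <- population_session(resp, tr, modality = "counts")
#' @export
population_session <- function(responses, trials,
                               modality = c("continuous", "counts"),
                               neuron_ids = NULL,
                               area_label = NA_character_,
                               window_annotation = NA_character_) {
  modality <- match.arg(modality)
  responses <- as.matrix(responses)
  if (!is.numeric(responses)) {
    stop_validation("responses must be a numeric matrix")
  }
  if (!is.data.frame(trials)) stop_validation("trials must be a data.frame")
  required <- c("trial_id", "condition", "outcome")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols) > 0) {
    stop_validation("trials table lacks column(s): %s",
                    paste(missing_cols, collapse = ", "))
  }
  if (nrow(trials) != nrow(responses)) {
    stop_validation("trial table has %d rows but response matrix has %d",
                    nrow(trials), nrow(responses))
  }
  if (anyDuplicated(trials$trial_id)) {
    stop_validation("trial_id values must be unique")
  }
  if (is.null(neuron_ids)) {
    neuron_ids <- colnames(responses)
    if (is.null(neuron_ids)) neuron_ids <- paste0("n", seq_len(ncol(responses)))
  }
  neuron_ids <- as.character(neuron_ids)
  if (length(neuron_ids) != ncol(responses)) {
    stop_validation("neuron_ids length (%d) != number of neurons (%d)",
                    length(neuron_ids), ncol(responses))
  }
  if (anyDuplicated(neuron_ids)) stop_validation("neuron_ids must be unique")
  if (anyNA(responses)) stop_validation("responses must not contain NA")
  if (modality == "counts") {
    if (any(responses < 0) || any(responses != round(responses))) {
      stop_validation("counts modality requires nonnegative integer responses")
    }
  }
  outcome_success(trials$outcome)  # validates labels
  dimnames(responses) <- list(as.character(trials$trial_id), neuron_ids)
  trials$trial_id <- as.character(trials$trial_id)
  trials$condition <- as.character(trials$condition)
  trials$outcome <- as.character(trials$outcome)
  structure(
    list(responses = responses, trials = trials, modality = modality,
         neuron_ids = neuron_ids, area_label = area_label,
         window_annotation = window_annotation),
    class = "population_session"
  )
}

#' @export
print.population_session <- function(x, ...) {
  cat(sprintf("<population_session> %d trials x %d neurons (%s)\n",
              nrow(x$responses), ncol(x$responses), x$modality))
  cat("  conditions:", paste(sort(unique(x$trials$condition)), collapse = ", "), "\n")
  cat("  outcomes:  ", paste(sort(unique(x$trials$outcome)), collapse = ", "), "\n")
  if (!is.na(x$area_label)) cat("  area:      ", x$area_label, "\n")
  invisible(x)
}

#' @export
dim.population_session <- function(x) dim(x$responses)

#' Number of trials in a session
#' @param session a `population_session`.
#' @return integer trial count.
#' @export
n_trials <- function(session) nrow(session$responses)

#' Number of neurons in a session
#' @param session a `population_session`.
#' @return integer neuron count.
#' @export
n_neurons <- function(session) ncol(session$responses)

#' Restrict a session to a subset of trials and/or neurons
#'
#' @param session a `population_session`.
#' @param trials logical/integer/character index into trials (trial ids).
#' @param neurons logical/integer/character index into neurons (neuron ids).
#' @return a new `population_session` with metadata carried over.
#' @export
subset_session <- function(session, trials = NULL, neurons = NULL) {
  resp <- session$responses
  tr <- session$trials
  if (!is.null(trials)) {
    if (is.character(trials)) trials <- match(trials, tr$trial_id)
    resp <- resp[trials, , drop = FALSE]
    tr <- tr[trials, , drop = FALSE]
  }
  ids <- session$neuron_ids
  if (!is.null(neurons)) {
    if (is.character(neurons)) neurons <- match(neurons, ids)
    resp <- resp[, neurons, drop = FALSE]
    ids <- ids[neurons]
  }
  population_session(resp, tr, modality = session$modality, neuron_ids = ids,
                     area_label = session$area_label,
                     window_annotation = session$window_annotation)
}

#' Declare the correct/wrong template pairing for a two-condition task
#'
#' Returns a named character vector mapping each condition to the condition
#' whose template is the "wrong" comparison for its trials (e.g. stimulus
#' present vs absent, or target left vs right).
#'
#' @param a,b the two condition labels.
#' @return named character vector `c(a = b, b = a)`.
#' @export
condition_pair <- function(a, b) {
  if (identical(a, b)) stop_validation("the two conditions must differ")
  stats::setNames(c(b, a), c(a, b))
}
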