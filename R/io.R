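# Session serialization: a session lives on disk as a file set of
#   <name>_responses.csv  header row = neuron ids, one row per trial
#   <name>_trials.csv     trial_id, condition, outcome, cov_* columns
#   <name>_manifest.json  modality, annotations, provenance
# Plain delimited text keeps fixtures diffable and language-neutral.

session_paths <- function(dir, name) {
  list(responses = file.path(dir, paste0(name, "_responses.csv")),
       trials = file.path(dir, paste0(name, "_trials.csv")),
       manifest = file.path(dir, paste0(name, "_manifest.json")))
}

#' Write a session to a delimited-text file set
#'
#' @param session a [population_session()].
#' @param dir output directory (created if absent).
#' @param name file-set stem; default `"session"`.
#' @param provenance optional list recorded in the manifest (e.g. generator
#'   and seed for synthetic sessions).
#' @return (invisibly) the list of written paths.
#' @export
write_session <- function(session, dir, name = "session", provenance = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- session_paths(dir, name)
  resp <- as.data.frame(session$responses)
  names(resp) <- session$neuron_ids
  tryCatch({
    utils::write.csv(resp, p$responses, row.names = FALSE)
    utils::write.csv(session$trials, p$trials, row.names = FALSE)
    jsonlite::write_json(
      list(modality = session$modality,
           area_label = session$area_label,
           window_annotation = session$window_annotation,
           n_trials = n_trials(session), n_neurons = n_neurons(session),
           provenance = provenance),
      p$manifest, auto_unbox = TRUE, pretty = TRUE, null = "null", na = "null")
  }, error = function(e) stop_io("failed writing session: %s", conditionMessage(e)))
  invisible(p)
}

#' Read a session from a delimited-text file set
#'
#' Validates everything at load: row counts match, trial ids line up,
#' outcome labels are known, and counts modality implies nonnegative
#' integer cells.
#'
#' @param dir directory holding the file set.
#' @param name file-set stem; default `"session"`.
#' @return a [population_session()].
#' @export
read_session <- function(dir, name = "session") {
  p <- session_paths(dir, name)
  for (f in unlist(p)) {
    if (!file.exists(f)) stop_io("missing session file: %s", f)
  }
  resp <- tryCatch(utils::read.csv(p$responses, check.names = FALSE),
                   error = function(e) stop_io("cannot parse %s: %s",
                                               p$responses, conditionMessage(e)))
  trials <- tryCatch(utils::read.csv(p$trials, stringsAsFactors = FALSE),
                     error = function(e) stop_io("cannot parse %s: %s",
                                                 p$trials, conditionMessage(e)))
  manifest <- tryCatch(jsonlite::read_json(p$manifest),
                       error = function(e) stop_io("cannot parse %s: %s",
                                                   p$manifest, conditionMessage(e)))
  if (nrow(resp) != nrow(trials)) {
    stop_validation("row-count mismatch: %d response rows vs %d trial rows",
                    nrow(resp), nrow(trials))
  }
  population_session(
    as.matrix(resp), trials,
    modality = manifest$modality,
    neuron_ids = names(resp),
    area_label = if (is.null(manifest$area_label)) NA_character_ else manifest$area_label,
    window_annotation = if (is.null(manifest$window_annotation)) NA_character_
                        else manifest$window_annotation
  )
}

#' Write an analysis result to disk
#'
#' Generic: each result class writes a JSON summary of its scalars plus tidy
#' delimited tables of its per-trial/per-neuron content. Output is
#' deterministic for identical inputs (no timestamps inside result files).
#' Flagged-undefined results are recorded with `status: "undefined"` and a
#' reason, never a fabricated number.
#'
#' @param results a result object (`specificity_result`,
#'   `relevance_result`, `jackknife_result`, `grouped_metrics`,
#'   `subsample_result`, `surrogate_ensemble`, `landscape_result`,
#'   `simulation_result`).
#' @param out_dir output directory (created if absent).
#' @param name file stem; defaults to the result class.
#' @param ... unused.
#' @return (invisibly) character vector of written paths.
#' @export
write_results <- function(results, out_dir, name = NULL, ...) {
  UseMethod("write_results")
}

prep_out <- function(out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- tryCatch({ dir.create(out_dir, recursive = TRUE); TRUE },
                   warning = function(w) FALSE, error = function(e) FALSE)
    if (!ok || !dir.exists(out_dir)) stop_io("cannot create directory %s", out_dir)
  }
}

write_summary_json <- function(x, path) {
  tryCatch(jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA, na = "null", null = "null"),
           error = function(e) stop_io("failed writing %s: %s", path,
                                       conditionMessage(e)))
}

#' @export
write_results.specificity_result <- function(results, out_dir,
                                             name = "specificity", ...) {
  prep_out(out_dir)
  trials_path <- file.path(out_dir, paste0(name, "_trials.csv"))
  excl_path <- file.path(out_dir, paste0(name, "_excluded.csv"))
  json_path <- file.path(out_dir, paste0(name, "_summary.json"))
  utils::write.csv(results$trials, trials_path, row.names = FALSE)
  utils::write.csv(results$excluded, excl_path, row.names = FALSE)
  write_summary_json(list(
    n_trials = nrow(results$trials), n_excluded = nrow(results$excluded),
    leave_one_out = results$leave_one_out,
    median_rho = stats::median(results$trials$rho),
    median_cor_correct = stats::median(results$trials$cor_correct),
    median_cor_wrong = stats::median(results$trials$cor_wrong)
  ), json_path)
  invisible(c(trials_path, excl_path, json_path))
}

#' @export
write_results.relevance_result <- function(results, out_dir,
                                           name = "relevance", ...) {
  prep_out(out_dir)
  json_path <- file.path(out_dir, paste0(name, "_summary.json"))
  payload <- if (results$defined) {
    list(status = "defined", omega = results$omega, A = results$A,
         U = results$U, U_X = results$U_X, U_Y = results$U_Y,
         R_X = results$R_X, R_Y = results$R_Y,
         n_X = results$n_X, n_Y = results$n_Y,
         groups_compared = results$groups_compared)
  } else {
    list(status = "undefined", reason = results$reason,
         n_X = results$n_X, n_Y = results$n_Y,
         groups_compared = results$groups_compared)
  }
  write_summary_json(payload, json_path)
  invisible(json_path)
}

#' @export
write_results.jackknife_result <- function(results, out_dir,
                                           name = "jackknife", ...) {
  prep_out(out_dir)
  mat_path <- file.path(out_dir, paste0(name, "_contributions.csv"))
  json_path <- file.path(out_dir, paste0(name, "_summary.json"))
  df <- data.frame(trial_id = rownames(results$contributions),
                   results$contributions, check.names = FALSE)
  utils::write.csv(df, mat_path, row.names = FALSE)
  write_summary_json(list(
    n_trials = length(results$trial_ids), n_neurons = length(results$neuron_ids),
    gamma_pooled = results$gamma_pooled,
    gamma_per_neuron = as.list(results$gamma_per_neuron),
    neuron_medians = as.list(results$neuron_medians)
  ), json_path)
  invisible(c(mat_path, json_path))
}

#' @export
write_results.grouped_metrics <- function(results, out_dir,
                                          name = "grouped", ...) {
  prep_out(out_dir)
  grp_path <- file.path(out_dir, paste0(name, "_groups.csv"))
  json_path <- file.path(out_dir, paste0(name, "_summary.json"))
  utils::write.csv(results$groups, grp_path, row.names = FALSE)
  write_summary_json(list(
    baseline = as.list(results$baseline),
    groups = results$groups,
    skipped = results$skipped
  ), json_path)
  invisible(c(grp_path, json_path))
}

#' @export
write_results.subsample_result <- function(results, out_dir,
                                           name = "subsample", ...) {
  prep_out(out_dir)
  path <- file.path(out_dir, paste0(name, ".csv"))
  utils::write.csv(as.data.frame(results), path, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.surrogate_ensemble <- function(results, out_dir,
                                             name = "surrogate", ...) {
  prep_out(out_dir)
  draws_path <- file.path(out_dir, paste0(name, "_draws.csv"))
  json_path <- file.path(out_dir, paste0(name, "_manifest.json"))
  utils::write.csv(as.data.frame(results$draws), draws_path, row.names = FALSE)
  write_summary_json(list(generator = results$generator,
                          n_surrogates = results$n_surrogates,
                          seed = results$seed,
                          provenance = results$provenance), json_path)
  invisible(c(draws_path, json_path))
}

#' @export
write_results.landscape_result <- function(results, out_dir,
                                           name = "landscape", ...) {
  prep_out(out_dir)
  mat_path <- file.path(out_dir, paste0(name, "_values.csv"))
  rep_path <- file.path(out_dir, paste0(name, "_replicates.csv"))
  json_path <- file.path(out_dir, paste0(name, "_summary.json"))
  utils::write.csv(data.frame(beta = results$beta_grid, results$values,
                              check.names = FALSE), mat_path, row.names = FALSE)
  utils::write.csv(results$replicates, rep_path, row.names = FALSE)
  payload <- list(metric = results$metric, second_axis = results$second_axis,
                  beta_grid = results$beta_grid,
                  second_grid = results$second_grid,
                  threshold = results$threshold)
  if (!is.null(results$compatibility)) {
    payload$measured_value <- results$measured_value
    payload$compatibility <- results$compatibility
  }
  write_summary_json(payload, json_path)
  invisible(c(mat_path, rep_path, json_path))
}

#' @export
write_results.simulation_result <- function(results, out_dir,
                                            name = "simulation", ...) {
  prep_out(out_dir)
  prefix <- file.path(out_dir, name)
  write_session(results$session, out_dir, paste0(name, "_session"),
                provenance = list(generator = "run_simulation",
                                  seed = results$config$seed))
  spec_paths <- write_results(results$specificity, out_dir,
                              paste0(name, "_specificity"))
  rel_path <- write_results(results$relevance, out_dir, paste0(name, "_relevance"))
  dec_path <- paste0(prefix, "_decisions.csv")
  utils::write.csv(results$decision, dec_path, row.names = FALSE)
  cfg_path <- paste0(prefix, "_config.json")
  write_summary_json(unclass(results$config), cfg_path)
  invisible(c(spec_paths, rel_path, dec_path, cfg_path))
}
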