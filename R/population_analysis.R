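#' Jackknife leave-one-neuron-out contributions to Specificity
#'
#' Removes one neuron at a time (from trial vectors and templates alike),
#' recomputes each trial's Specificity \eqn{\rho_i^{(\neg j)}}, and applies
#' the jackknife identity
#' \deqn{SpecIdx_{JK}[i, j] = n \rho_i - (n - 1) \rho_i^{(\neg j)}}
#' with `n` the neuron count. A positive contribution marks a neuron whose
#' presence raises that trial's Specificity ("super-coder" candidates sit in
#' the right tail). Distribution symmetry is summarized by the Yule-Kendall
#' \eqn{\gamma}, per neuron (across trials) and pooled over all cells — the
#' pooled value is the headline summary.
#'
#' @param session a [population_session()] with >= 2 neurons.
#' @param wrong_of correct/wrong condition mapping (see [condition_pair()]).
#' @param leave_one_out passed through to [specificity_index()].
#' @return `jackknife_result`: list with `contributions` (trials x neurons
#'   matrix, `NA` where a removal left a zero-variance vector),
#'   `neuron_medians`, `gamma_pooled`, `gamma_per_neuron`, `rho_full`,
#'   `trial_ids`, `neuron_ids`.
#' @export
jackknife_contributions <- function(session, wrong_of, leave_one_out = FALSE) {
  n <- n_neurons(session)
  if (n < 2) stop_validation("jackknife needs >= 2 neurons")
  full <- specificity_index(session, wrong_of, leave_one_out = leave_one_out)
  ids <- full$trials$trial_id
  rho_full <- stats::setNames(full$trials$rho, ids)
  contrib <- matrix(NA_real_, nrow = length(ids), ncol = n,
                    dimnames = list(ids, session$neuron_ids))
  for (j in seq_len(n)) {
    sub <- subset_session(session, neurons = setdiff(seq_len(n), j))
    sj <- tryCatch(
      specificity_index(sub, wrong_of, leave_one_out = leave_one_out),
      specrel_computation_error = function(e) NULL
    )
    if (is.null(sj)) next
    common <- intersect(ids, sj$trials$trial_id)
    rho_wo <- stats::setNames(sj$trials$rho, sj$trials$trial_id)[common]
    contrib[common, j] <- n * rho_full[common] - (n - 1) * rho_wo
  }
  gamma_per_neuron <- apply(contrib, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 3) return(NA_real_)
    yule_kendall(v)
  })
  pooled <- contrib[!is.na(contrib)]
  structure(
    list(contributions = contrib,
         neuron_medians = apply(contrib, 2, stats::median, na.rm = TRUE),
         gamma_pooled = if (length(pooled) >= 3) yule_kendall(pooled) else NA_real_,
         gamma_per_neuron = gamma_per_neuron,
         rho_full = rho_full,
         trial_ids = ids, neuron_ids = session$neuron_ids),
    class = "jackknife_result"
  )
}

#' @export
print.jackknife_result <- function(x, ...) {
  cat(sprintf("<jackknife_result> %d trials x %d neurons; pooled gamma = %.4f\n",
              length(x$trial_ids), length(x$neuron_ids), x$gamma_pooled))
  invisible(x)
}

#' Select the most (or least) informative neurons
#'
#' Ranks neurons by their median jackknifed contribution and returns the top
#' or bottom `ceil(fraction * n)`, ties broken by neuron order (stable).
#'
#' @param jk a `jackknife_result`.
#' @param fraction fraction of the population to select, in `(0, 0.5]`;
#'   default 0.10.
#' @param which `"top"` (highest median contribution) or `"bottom"`.
#' @return character vector of neuron ids.
#' @export
select_extreme_neurons <- function(jk, fraction = 0.10,
                                   which = c("top", "bottom")) {
  which <- match.arg(which)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 0.5) {
    stop_validation("fraction must lie in (0, 0.5]")
  }
  med <- jk$neuron_medians
  k <- ceiling(fraction * length(med))
  ord <- order(med, decreasing = (which == "top"))  # stable: ties keep index order
  jk$neuron_ids[ord[seq_len(k)]]
}

#' Specificity and Relevance across neuron subsample sizes
#'
#' For each fraction, draws random neuron subsets without replacement,
#' recomputes templates, per-trial \eqn{\rho} and \eqn{\Omega} on the
#' subset, and returns the full per-fraction distributions. No functional
#' extrapolation is fitted; the raw distributions are the contract.
#'
#' @param session a [population_session()].
#' @param wrong_of correct/wrong condition mapping.
#' @param fractions fractions of the population, default `seq(0.1, 1, 0.1)`;
#'   each must yield >= 2 neurons.
#' @param n_repeats random subsets per fraction (default 20; a fraction of
#'   1.0 is deterministic and still repeated for shape consistency).
#' @param seed integer seed.
#' @return `subsample_result`: data.frame with columns `fraction`, `repeat_`,
#'   `n_neurons`, `median_rho`, `omega`.
#' @export
subsample_metrics <- function(session, wrong_of,
                              fractions = seq(0.1, 1, by = 0.1),
                              n_repeats = 20, seed) {
  if (missing(seed)) stop_validation("an explicit seed is required")
  n <- n_neurons(session)
  sizes <- pmax(2L, ceiling(fractions * n))
  if (any(ceiling(fractions * n) < 2)) {
    stop_validation("smallest fraction yields < 2 neurons (n = %d)", n)
  }
  set.seed(as.integer(seed))
  rows <- list()
  for (fi in seq_along(fractions)) {
    for (rep_i in seq_len(n_repeats)) {
      keep <- sort(sample.int(n, sizes[fi]))
      sub <- subset_session(session, neurons = keep)
      spec <- specificity_index(sub, wrong_of)
      rel <- relevance_of(spec)
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = fractions[fi], repeat_ = rep_i, n_neurons = sizes[fi],
        median_rho = stats::median(spec$trials$rho),
        omega = if (rel$defined) rel$omega else NA_real_
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("subsample_result", class(out))
  out
}

#' Cluster trials by population-response similarity
#'
#' Standardizes each neuron across trials (so high-rate neurons do not
#' dominate Euclidean distance), runs k-means with multiple restarts for
#' each candidate `k`, and picks the `k` with the highest mean silhouette
#' width. Deterministic under the supplied seed.
#'
#' @param session a [population_session()] with at least `max(k_range) + 1`
#'   trials.
#' @param k_range candidate cluster counts, default `2:5`.
#' @param seed integer seed.
#' @param nstart k-means restarts per `k` (default 10).
#' @return list with `labels` (named by trial id, for the chosen `k`),
#'   `chosen_k`, `silhouette` (mean silhouette width per `k`), and
#'   `all_labels` (matrix of labels for every `k`).
#' @export
cluster_trials <- function(session, k_range = 2:5, seed, nstart = 10) {
  if (missing(seed)) stop_validation("an explicit seed is required")
  if (n_trials(session) < max(k_range) + 1) {
    stop_validation("need at least max(k_range) + 1 = %d trials", max(k_range) + 1)
  }
  x <- session$responses
  sds <- apply(x, 2, stats::sd)
  x <- x[, sds > 0, drop = FALSE]
  if (ncol(x) == 0 || all(stats::dist(x) == 0)) {
    stop_computation("degenerate data: all trials identical")
  }
  x <- scale(x)
  d <- stats::dist(x)
  set.seed(as.integer(seed))
  sil <- numeric(length(k_range))
  labs <- matrix(NA_integer_, nrow = nrow(x), ncol = length(k_range),
                 dimnames = list(session$trials$trial_id, paste0("k", k_range)))
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    km <- stats::kmeans(x, centers = k, nstart = nstart, iter.max = 100)
    labs[, ki] <- km$cluster
    sil[ki] <- mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
  }
  best <- which.max(sil)
  list(labels = stats::setNames(labs[, best], session$trials$trial_id),
       chosen_k = k_range[best],
       silhouette = stats::setNames(sil, paste0("k", k_range)),
       all_labels = labs)
}

#' Recompute Specificity and Relevance within trial groups
#'
#' Templates, per-trial \eqn{\rho} and \eqn{\Omega} are recomputed inside
#' each trial group (cluster labels, a covariate quantile split such as
#' pupil size, or an easy/difficult condition split — all through the same
#' contract), with the pooled, ungrouped metrics as baseline. Groups below
#' `min_group_size` are reported as skipped, not silently dropped.
#'
#' @param session a [population_session()].
#' @param wrong_of correct/wrong condition mapping.
#' @param grouping one of: a named vector of group labels (names = trial
#'   ids, or unnamed in trial order); the name of a column of the trials
#'   table; or `list(covariate = "name", n_groups = k)` for a quantile split
#'   of covariate column `cov_<name>`.
#' @param min_group_size smallest group analysed (default 4: >= 2 trials per
#'   condition is the practical floor for templates).
#' @return `grouped_metrics`: list with `groups` (per-group data.frame:
#'   label, n_trials, median_rho, omega), `skipped`, `baseline`
#'   (pooled median rho and omega), `labels`.
#' @export
metrics_by_group <- function(session, wrong_of, grouping, min_group_size = 4) {
  labels <- resolve_grouping(session, grouping)
  if (anyNA(labels)) stop_validation("grouping undefined for some trials")
  pooled_spec <- specificity_index(session, wrong_of)
  pooled_rel <- relevance_of(pooled_spec)
  groups <- split(seq_len(n_trials(session)), labels)
  res <- list()
  skipped <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    if (length(idx) < min_group_size) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        label = g, n_trials = length(idx), reason = "insufficient trials")
      next
    }
    sub <- subset_session(session, trials = idx)
    sp <- tryCatch(specificity_index(sub, wrong_of),
                   specrel_validation_error = function(e) NULL,
                   specrel_computation_error = function(e) NULL)
    if (is.null(sp)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        label = g, n_trials = length(idx),
        reason = "specificity not computable (missing condition?)")
      next
    }
    rel <- relevance_of(sp)
    res[[length(res) + 1L]] <- data.frame(
      label = g, n_trials = length(idx),
      median_rho = stats::median(sp$trials$rho),
      omega = if (rel$defined) rel$omega else NA_real_
    )
  }
  if (length(res) == 0) stop_computation("no group meets min_group_size")
  structure(
    list(groups = do.call(rbind, res),
         skipped = if (length(skipped)) do.call(rbind, skipped) else NULL,
         baseline = data.frame(
           median_rho = stats::median(pooled_spec$trials$rho),
           omega = if (pooled_rel$defined) pooled_rel$omega else NA_real_),
         labels = stats::setNames(labels, session$trials$trial_id)),
    class = "grouped_metrics"
  )
}

#' @export
print.grouped_metrics <- function(x, ...) {
  cat(sprintf("<grouped_metrics> %d group(s), %d skipped\n",
              nrow(x$groups), if (is.null(x$skipped)) 0L else nrow(x$skipped)))
  print(x$groups)
  invisible(x)
}

# Turn any accepted grouping specification into a per-trial label vector.
resolve_grouping <- function(session, grouping) {
  tr <- session$trials
  if (is.list(grouping) && !is.null(grouping$covariate)) {
    col <- paste0("cov_", grouping$covariate)
    if (!col %in% names(tr)) stop_validation("covariate column '%s' not found", col)
    k <- if (is.null(grouping$n_groups)) 2L else as.integer(grouping$n_groups)
    v <- tr[[col]]
    breaks <- stats::quantile(v, probs = seq(0, 1, length.out = k + 1),
                              names = FALSE, type = 7)
    breaks <- unique(breaks)
    if (length(breaks) < 2) stop_validation("covariate '%s' is constant", grouping$covariate)
    as.character(cut(v, breaks = breaks, include.lowest = TRUE,
                     labels = paste0("q", seq_len(length(breaks) - 1))))
  } else if (is.character(grouping) && length(grouping) == 1 &&
             grouping %in% names(tr)) {
    as.character(tr[[grouping]])
  } else if (length(grouping) == n_trials(session)) {
    g <- grouping
    if (!is.null(names(g))) g <- g[tr$trial_id]
    as.character(unname(g))
  } else {
    stop_validation("unrecognized grouping specification")
  }
}
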