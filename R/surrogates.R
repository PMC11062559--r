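#' Gaussian surrogate ensemble for continuous (calcium imaging) sessions
#'
#' The null model for \eqn{\Delta F/F} data: for one condition, each neuron's
#' surrogate values are i.i.d. draws from a normal distribution whose mean
#' and variance are that neuron's across-trial average and variance within
#' the condition. Draws are independent across neurons and are not clipped:
#' \eqn{\Delta F/F} is legitimately negative. A neuron with zero across-trial
#' variance yields all draws equal to its mean (degenerate normal).
#'
#' @param session a [population_session()] with continuous modality.
#' @param condition condition label (needs >= 2 trials so the variance is
#'   defined).
#' @param n_surrogates ensemble size; default 200 draws per condition.
#' @param seed integer seed; ensembles are bit-reproducible.
#' @return `surrogate_ensemble` with `generator = "gaussian"`, a
#'   `n_surrogates x neurons` matrix in `$draws`, and provenance.
#' @export
gaussian_surrogate <- function(session, condition, n_surrogates = 200, seed) {
  if (session$modality != "continuous") {
    stop_validation(paste("gaussian surrogates require continuous modality;",
                          "use poisson_reallocation_surrogate for counts"))
  }
  if (missing(seed)) stop_validation("an explicit seed is required")
  idx <- session$trials$condition == condition
  if (sum(idx) < 2) {
    stop_validation("condition '%s' needs >= 2 trials for a trial-variance", condition)
  }
  m <- session$responses[idx, , drop = FALSE]
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  set.seed(as.integer(seed))
  draws <- vapply(seq_along(mu), function(j) {
    stats::rnorm(n_surrogates, mean = mu[j], sd = sdv[j])
  }, numeric(n_surrogates))
  colnames(draws) <- session$neuron_ids
  structure(
    list(generator = "gaussian", n_surrogates = n_surrogates,
         seed = as.integer(seed), draws = draws,
         provenance = list(condition = condition,
                           n_source_trials = sum(idx),
                           area_label = session$area_label)),
    class = "surrogate_ensemble"
  )
}

#' Spike-conserving multinomial reallocation surrogate (spike data)
#'
#' The null model for spike-count data: each surrogate keeps the trial's
#' total spike count fixed and reassigns every spike independently to neuron
#' `m` with probability \eqn{\lambda_m / \sum_m \lambda_m}, where
#' \eqn{\lambda} is the condition template. One multinomial draw per
#' surrogate realizes exactly the constraints of a Poissonian resampling of
#' the template under neuron independence, i.e. scrambling across trials.
#'
#' @param session a [population_session()] with counts modality.
#' @param trial_id the source trial whose total spike count is conserved.
#' @param template a `condition_template` supplying the allocation
#'   probabilities (normally the trial's correct-condition template).
#' @param n_surrogates ensemble size; default 100 vectors per trial.
#' @param seed integer seed.
#' @return `surrogate_ensemble` with `generator = "poisson_reallocation"`
#'   and an integer `n_surrogates x neurons` matrix in `$draws`; every row
#'   sums exactly to the source trial's total spike count.
#' @export
poisson_reallocation_surrogate <- function(session, trial_id, template,
                                           n_surrogates = 100, seed) {
  if (session$modality != "counts") {
    stop_validation("spike reallocation surrogates require counts modality")
  }
  if (missing(seed)) stop_validation("an explicit seed is required")
  i <- match(as.character(trial_id), session$trials$trial_id)
  if (is.na(i)) stop_validation("trial_id '%s' not found in session", trial_id)
  lambda <- template$mean_vector
  if (length(lambda) != n_neurons(session)) {
    stop_validation("template length (%d) != neuron count (%d)",
                    length(lambda), n_neurons(session))
  }
  total <- sum(session$responses[i, ])
  if (sum(lambda) <= 0 && total > 0) {
    stop_validation("template has zero total mass but trial has %d spikes", total)
  }
  set.seed(as.integer(seed))
  if (total == 0) {
    draws <- matrix(0L, nrow = n_surrogates, ncol = length(lambda))
  } else {
    draws <- t(stats::rmultinom(n_surrogates, size = total,
                                prob = lambda / sum(lambda)))
    storage.mode(draws) <- "integer"
  }
  colnames(draws) <- session$neuron_ids
  structure(
    list(generator = "poisson_reallocation", n_surrogates = n_surrogates,
         seed = as.integer(seed), draws = draws,
         provenance = list(trial_id = as.character(trial_id),
                           total_spikes = total,
                           template_condition = template$condition,
                           area_label = session$area_label)),
    class = "surrogate_ensemble"
  )
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf("<surrogate_ensemble> %s: %d draws x %d neurons (seed %d)\n",
              x$generator, nrow(x$draws), ncol(x$draws), x$seed))
  invisible(x)
}

#' Percentile band of surrogate Specificity
#'
#' Scores every surrogate vector against the same correct/wrong templates
#' used for real trials, pools the resulting \eqn{\rho} values across the
#' supplied ensembles (e.g. across per-trial ensembles of one session), and
#' returns the median plus a percentile band. Percentiles use linear
#' interpolation (`stats::quantile` type 7), the package-wide convention.
#'
#' @param ensembles a single `surrogate_ensemble` or a list of them.
#' @param correct_template,wrong_template `condition_template` objects (or
#'   bare numeric vectors) giving the comparison templates.
#' @param percentiles length-2 numeric, default `c(5, 95)` (percent).
#' @return list with `median`, `lower`, `upper`, `percentiles`, `rho`
#'   (pooled surrogate values) and `per_ensemble_median`.
#' @export
surrogate_specificity_band <- function(ensembles, correct_template,
                                       wrong_template,
                                       percentiles = c(5, 95)) {
  if (inherits(ensembles, "surrogate_ensemble")) ensembles <- list(ensembles)
  if (length(ensembles) == 0) stop_validation("no ensembles supplied")
  lam_c <- if (inherits(correct_template, "condition_template"))
    correct_template$mean_vector else as.numeric(correct_template)
  lam_w <- if (inherits(wrong_template, "condition_template"))
    wrong_template$mean_vector else as.numeric(wrong_template)
  per_ens <- lapply(ensembles, function(e) {
    apply(e$draws, 1, function(v) {
      cc <- pearson_correlation(lam_c, v)
      cw <- pearson_correlation(lam_w, v)
      cc - cw
    })
  })
  pooled <- unlist(per_ens, use.names = FALSE)
  pooled <- pooled[!is.na(pooled)]
  if (length(pooled) == 0) {
    stop_computation("all surrogate correlations are undefined")
  }
  band <- stats::quantile(pooled, percentiles / 100, names = FALSE, type = 7)
  list(median = stats::median(pooled), lower = band[1], upper = band[2],
       percentiles = percentiles, rho = pooled,
       per_ensemble_median = vapply(per_ens, function(v)
         stats::median(v, na.rm = TRUE), numeric(1)))
}
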