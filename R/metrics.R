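#' Pearson correlation with an explicit undefined marker
#'
#' Standard product-moment correlation, except that a zero-variance input
#' yields `NA_real_` rather than an error or an imputed value: a constant
#' vector has no defined correlation, and downstream code treats such trials
#' as excluded, never as zero.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation in `[-1, 1]`, or `NA_real_` when either vector has
#'   zero variance.
#' @examples
#' pearson_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3))  # 0.6
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) {
    stop_validation("x and y must have equal length (%d vs %d)",
                    length(x), length(y))
  }
  if (length(x) < 2) stop_validation("vectors must have length >= 2")
  if (anyNA(x) || anyNA(y)) stop_validation("inputs must not contain NA")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Compute per-condition trial-averaged templates
#'
#' The template \eqn{\lambda} of a condition is the arithmetic mean across
#' that condition's trials of each neuron's activity, in the session's units.
#'
#' @param session a [population_session()].
#' @param conditions condition labels to average; defaults to all present.
#' @return named list of `condition_template` objects, each holding
#'   `condition`, `mean_vector` (named by neuron id) and `n_trials`.
#' @export
compute_templates <- function(session, conditions = NULL) {
  if (is.null(conditions)) conditions <- unique(session$trials$condition)
  out <- lapply(conditions, function(cond) {
    idx <- session$trials$condition == cond
    if (!any(idx)) stop_validation("condition '%s' has no trials", cond)
    structure(
      list(condition = cond,
           mean_vector = colMeans(session$responses[idx, , drop = FALSE]),
           n_trials = sum(idx)),
      class = "condition_template"
    )
  })
  stats::setNames(out, conditions)
}

#' @export
print.condition_template <- function(x, ...) {
  cat(sprintf("<condition_template> '%s': %d neurons, mean of %d trial(s)\n",
              x$condition, length(x$mean_vector), x$n_trials))
  invisible(x)
}

#' Per-trial Specificity Index
#'
#' For every trial, \eqn{\rho_i = cor(\lambda_{correct}, r_i) -
#' cor(\lambda_{wrong}, r_i)}: the excess Pearson correlation of the trial's
#' population vector to the template of its own condition over the template
#' of the alternative condition. Because each correlation lies in
#' \eqn{[-1, 1]}, \eqn{\rho_i \in [-2, 2]}.
#'
#' Trials whose own or wrong correlation is undefined (zero-variance vector)
#' are reported in `excluded` with a reason, never silently dropped or set
#' to 0.
#'
#' @param session a [population_session()].
#' @param wrong_of named character vector mapping each condition to the
#'   condition supplying the "wrong" template (see [condition_pair()]).
#' @param templates optional precomputed templates (as from
#'   [compute_templates()]); by default templates include the scored trial.
#' @param leave_one_out if `TRUE`, the correct template is recomputed with
#'   the scored trial excluded (requires >= 2 trials in its condition);
#'   self-inclusion inflates correlations when trial counts are small.
#' @return `specificity_result`: list with `trials` (data.frame `trial_id`,
#'   `condition`, `outcome`, `cor_correct`, `cor_wrong`, `rho`) and
#'   `excluded` (data.frame `trial_id`, `reason`).
#' @export
specificity_index <- function(session, wrong_of, templates = NULL,
                              leave_one_out = FALSE) {
  conds <- unique(session$trials$condition)
  missing_map <- setdiff(conds, names(wrong_of))
  if (length(missing_map) > 0) {
    stop_validation("no wrong-template mapping for condition(s): %s",
                    paste(missing_map, collapse = ", "))
  }
  needed <- unique(c(conds, unname(wrong_of[conds])))
  if (is.null(templates)) {
    templates <- compute_templates(session, needed)
  }
  missing_tpl <- setdiff(needed, names(templates))
  if (length(missing_tpl) > 0) {
    stop_validation("missing template(s): %s", paste(missing_tpl, collapse = ", "))
  }

  tr <- session$trials
  n <- nrow(tr)
  cor_correct <- cor_wrong <- rep(NA_real_, n)
  reasons <- character(n)
  for (i in seq_len(n)) {
    r_i <- session$responses[i, ]
    cond <- tr$condition[i]
    lam_c <- templates[[cond]]$mean_vector
    if (leave_one_out) {
      idx <- which(tr$condition == cond)
      if (length(idx) < 2) {
        stop_validation(
          "leave_one_out requires >= 2 trials in condition '%s'", cond)
      }
      others <- setdiff(idx, i)
      lam_c <- colMeans(session$responses[others, , drop = FALSE])
    }
    lam_w <- templates[[wrong_of[[cond]]]]$mean_vector
    cc <- pearson_correlation(lam_c, r_i)
    cw <- pearson_correlation(lam_w, r_i)
    cor_correct[i] <- cc
    cor_wrong[i] <- cw
    if (is.na(cc) || is.na(cw)) {
      parts <- c(
        if (stats::sd(r_i) == 0) "zero-variance trial vector",
        if (stats::sd(lam_c) == 0) "zero-variance correct template",
        if (stats::sd(lam_w) == 0) "zero-variance wrong template"
      )
      reasons[i] <- paste(parts, collapse = "; ")
    }
  }
  keep <- reasons == ""
  if (!any(keep)) stop_computation("all trials excluded: no defined correlations")
  trials_df <- data.frame(
    trial_id = tr$trial_id[keep], condition = tr$condition[keep],
    outcome = tr$outcome[keep],
    cor_correct = cor_correct[keep], cor_wrong = cor_wrong[keep],
    rho = cor_correct[keep] - cor_wrong[keep],
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(
    list(trials = trials_df,
         excluded = data.frame(trial_id = tr$trial_id[!keep],
                               reason = reasons[!keep],
                               stringsAsFactors = FALSE, row.names = NULL),
         leave_one_out = leave_one_out),
    class = "specificity_result"
  )
}

#' @export
print.specificity_result <- function(x, ...) {
  cat(sprintf("<specificity_result> %d trial(s), %d excluded; median rho = %.4f\n",
              nrow(x$trials), nrow(x$excluded), stats::median(x$trials$rho)))
  invisible(x)
}

#' Mann-Whitney U statistic with mid-rank tie handling
#'
#' All observations are pooled and ranked low to high; tied values receive
#' the average of the ranks they span. `U_X = R_X - n_X(n_X+1)/2` counts the
#' pairs in which an `x` exceeds a `y`, ties half-credited, and symmetrically
#' for `U_Y`; `U = min(U_X, U_Y)` and `U_X + U_Y = n_X n_Y`.
#'
#' @param x,y numeric samples (each non-empty).
#' @return list with `U`, `U_X`, `U_Y`, `R_X`, `R_Y`, `n_X`, `n_Y`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) stop_validation("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop_validation("samples must not contain NA")
  n_x <- length(x)
  n_y <- length(y)
  rk <- rank(c(x, y), ties.method = "average")
  r_x <- sum(rk[seq_len(n_x)])
  r_y <- sum(rk[n_x + seq_len(n_y)])
  u_x <- r_x - n_x * (n_x + 1) / 2
  u_y <- r_y - n_y * (n_y + 1) / 2
  list(U = min(u_x, u_y), U_X = u_x, U_Y = u_y,
       R_X = r_x, R_Y = r_y, n_X = n_x, n_Y = n_y)
}

#' Vargha-Delaney A effect size (measure of stochastic superiority)
#'
#' The probability that a random draw from `x` exceeds a random draw from
#' `y`, exact ties counted half. Computed from the rank-based `U_X`;
#' algebraically identical to the pairwise definition implemented in
#' [brute_force_A()].
#'
#' @param x,y numeric samples (each non-empty).
#' @return A in `[0, 1]`.
#' @export
vargha_delaney_A <- function(x, y) {
  u <- mann_whitney_u(x, y)
  u$U_X / (u$n_X * u$n_Y)
}

#' Pairwise-enumeration oracle for the A effect size
#'
#' Explicit double loop over all `n_X * n_Y` pairs with half credit for exact
#' ties. Deliberately naive; serves as the normative reference for
#' [vargha_delaney_A()].
#'
#' @param x,y numeric samples (each non-empty).
#' @return A in `[0, 1]`.
#' @export
brute_force_A <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) stop_validation("both samples must be non-empty")
  wins <- 0
  for (xi in x) {
    for (yj in y) {
      if (xi > yj) wins <- wins + 1
      else if (xi == yj) wins <- wins + 0.5
    }
  }
  wins / (length(x) * length(y))
}

#' Behavioural Relevance Index
#'
#' \eqn{\Omega = max(A, 1 - A)} comparing Specificity values of behaviourally
#' correct trials (`spec_correct`) against incorrect ones (`spec_incorrect`).
#' \eqn{\Omega} is bounded in `[0.5, 1]`: 0.5 means the two distributions
#' overlap completely, 1 means complete stochastic dominance. The `max`
#' makes the index symmetric in its two arguments.
#'
#' With fewer than 2 observations in either group the rank test is
#' degenerate, so the result is flagged undefined (carrying the group sizes)
#' rather than given a fabricated value.
#'
#' @param spec_correct,spec_incorrect numeric samples of per-trial
#'   Specificity values (or any paired statistic) for the two outcome groups.
#' @param groups_compared optional character pair naming the groups.
#' @return `relevance_result`: list with `omega`, `A`, `U`, `U_X`, `U_Y`,
#'   `R_X`, `R_Y`, `n_X`, `n_Y`, `groups_compared`, `defined`.
#' @export
behavioural_relevance <- function(spec_correct, spec_incorrect,
                                  groups_compared = c("correct", "incorrect")) {
  n_x <- length(spec_correct)
  n_y <- length(spec_incorrect)
  if (n_x < 2 || n_y < 2) {
    return(structure(
      list(omega = NA_real_, A = NA_real_, U = NA_real_,
           U_X = NA_real_, U_Y = NA_real_, R_X = NA_real_, R_Y = NA_real_,
           n_X = n_x, n_Y = n_y, groups_compared = groups_compared,
           defined = FALSE,
           reason = "each group needs >= 2 observations"),
      class = "relevance_result"
    ))
  }
  u <- mann_whitney_u(spec_correct, spec_incorrect)
  a <- u$U_X / (u$n_X * u$n_Y)
  # max(A, 1 - A) evaluated as max(U_X, U_Y)/(n_X n_Y): algebraically equal,
  # and exactly symmetric in the two groups at floating point
  omega <- max(u$U_X, u$U_Y) / (u$n_X * u$n_Y)
  structure(
    c(list(omega = omega, A = a), u,
      list(groups_compared = groups_compared, defined = TRUE)),
    class = "relevance_result"
  )
}

#' @export
print.relevance_result <- function(x, ...) {
  if (!x$defined) {
    cat(sprintf("<relevance_result> undefined (%s; n = %d vs %d)\n",
                x$reason, x$n_X, x$n_Y))
  } else {
    cat(sprintf("<relevance_result> Omega = %.4f (A = %.4f, U = %.1f; n = %d vs %d)\n",
                x$omega, x$A, x$U, x$n_X, x$n_Y))
  }
  invisible(x)
}

#' Yule-Kendall skewness index
#'
#' \eqn{\gamma = (Q_{3/4} + Q_{1/4} - 2 Q_{1/2}) / (Q_{3/4} - Q_{1/4})}, a
#' dimensionless, quartile-based skewness measure bounded in `[-1, 1]`.
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile` type 7), the convention used throughout the package,
#' so values are reproducible bit for bit.
#'
#' @param sample numeric sample of size >= 3.
#' @return `gamma` in `[-1, 1]`, or `NA_real_` when the interquartile range
#'   is zero.
#' @export
yule_kendall <- function(sample) {
  sample <- sample[!is.na(sample)]
  if (length(sample) < 3) stop_validation("sample must have >= 3 non-NA values")
  q <- stats::quantile(sample, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  if (iqr == 0) return(NA_real_)
  (q[3] + q[1] - 2 * q[2]) / iqr
}

#' Per-neuron Fano factor within a condition
#'
#' Across-trial unbiased sample variance of each neuron's activity divided by
#' its mean; equals 1 for a homogeneous Poisson process, so it benchmarks
#' spike-count variability. Neurons with zero mean are returned as
#' `NA_real_`.
#'
#' @param session a [population_session()]; counts modality is the intended
#'   use, continuous input is allowed but less interpretable.
#' @param condition condition label whose trials are used (>= 2 required).
#' @return named numeric vector, one Fano factor per neuron.
#' @export
fano_factor <- function(session, condition) {
  idx <- session$trials$condition == condition
  if (sum(idx) < 2) {
    stop_validation("condition '%s' needs >= 2 trials, has %d", condition, sum(idx))
  }
  m <- session$responses[idx, , drop = FALSE]
  mu <- colMeans(m)
  v <- apply(m, 2, stats::var)
  ff <- ifelse(mu == 0, NA_real_, v / mu)
  stats::setNames(ff, session$neuron_ids)
}

# Split a specificity result into behaviourally correct/incorrect rho samples.
split_by_success <- function(spec) {
  ok <- outcome_success(spec$trials$outcome)
  list(correct = spec$trials$rho[ok], incorrect = spec$trials$rho[!ok])
}

#' Behavioural Relevance of a Specificity result
#'
#' Convenience wrapper: splits per-trial \eqn{\rho} values by behavioural
#' success (hit/CR vs miss/FP, or correct vs incorrect) and computes
#' [behavioural_relevance()].
#'
#' @param spec a `specificity_result`.
#' @return a `relevance_result`.
#' @export
relevance_of <- function(spec) {
  parts <- split_by_success(spec)
  behavioural_relevance(parts$correct, parts$incorrect,
                        groups_compared = c("success", "failure"))
}
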