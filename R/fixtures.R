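# Synthetic session generators emulating the two experimental styles the
# metrics are designed for: a continuous-response detection session
# (calcium-imaging style, hit/miss/CR/FP outcomes) and an integer-count
# two-alternative session (electrophysiology style, hit/miss outcomes).
# These are first-class generators with controllable ground truth, used both
# as test fixtures and for power/calibration exploration.

# Ground-truth match quality of each trial vector against the true condition
# mean profiles: cor to own-condition profile minus cor to the other.
true_match_quality <- function(responses, cond, profiles, wrong_of) {
  vapply(seq_len(nrow(responses)), function(i) {
    mu_c <- profiles[[cond[i]]]
    mu_w <- profiles[[wrong_of[[cond[i]]]]]
    cc <- pearson_correlation(mu_c, responses[i, ])
    cw <- pearson_correlation(mu_w, responses[i, ])
    if (is.na(cc) || is.na(cw)) 0 else cc - cw
  }, numeric(1))
}

# Sigmoid link from (condition-centred) match quality to success probability.
# Centring at the within-condition median keeps outcome classes balanced and
# makes slope = 0 produce exactly chance-level outcomes.
link_success <- function(match, cond, slope, decision_noise, rng_noise) {
  centred <- match
  for (cn in unique(cond)) {
    idx <- cond == cn
    centred[idx] <- match[idx] - stats::median(match[idx])
  }
  stats::plogis(slope * centred + rng_noise * decision_noise)
}

#' Synthetic continuous-response detection session
#'
#' Emulates a stimulus-detection experiment with continuous responses
#' (\eqn{\Delta F/F} style): conditions `"stim"` and `"no_stim"`, responses
#' equal to the condition mean profile plus Gaussian noise, and outcomes
#' (hit/miss within `stim`, correct rejection/false positive within
#' `no_stim`) drawn from a sigmoid link on the trial's ground-truth match
#' quality. A link slope of 0 decouples outcome from response entirely.
#'
#' @param n_neurons number of neurons (default 40).
#' @param n_trials trials per condition: scalar, or named vector with
#'   entries `stim`, `no_stim`.
#' @param effect_size per-neuron condition effect: scalar SD of the normal
#'   law of per-neuron stimulus effects, or a length-`n_neurons` vector of
#'   explicit effects. 0 gives identical condition profiles (no signal).
#' @param noise_sd per-trial response noise SD (0 makes every trial equal
#'   its condition profile).
#' @param link_slope slope of the sigmoid outcome link on centred match
#'   quality.
#' @param decision_noise SD of Gaussian noise added inside the link.
#' @param outcome_counts optional named list (per condition) of named
#'   outcome counts, e.g. `list(stim = c(hit = 30, miss = 10), ...)`; when
#'   supplied, the successful outcome is assigned deterministically to the
#'   trials with the highest link probability so the counts hold exactly.
#' @param seed integer seed.
#' @return a continuous-modality [population_session()]; the true profiles
#'   and match qualities are attached as attribute `"ground_truth"`.
#' @export
make_continuous_fixture <- function(n_neurons = 40, n_trials = 50,
                                    effect_size = 0.5, noise_sd = 0.5,
                                    link_slope = 5, decision_noise = 0,
                                    outcome_counts = NULL, seed) {
  if (missing(seed)) stop_validation("an explicit seed is required")
  if (n_neurons < 2) stop_validation("need >= 2 neurons")
  conds <- c("stim", "no_stim")
  if (length(n_trials) == 1) n_trials <- stats::setNames(rep(n_trials, 2), conds)
  if (!all(conds %in% names(n_trials))) {
    stop_validation("n_trials must name conditions 'stim' and 'no_stim'")
  }
  if (any(n_trials < 2)) stop_validation("need >= 2 trials per condition")
  set.seed(as.integer(seed))
  baseline <- stats::rnorm(n_neurons, 0.1, 0.2)
  effects <- if (length(effect_size) == n_neurons) effect_size
             else stats::rnorm(n_neurons, 0, effect_size)
  profiles <- list(stim = baseline + effects, no_stim = baseline)
  cond <- rep(conds, times = n_trials[conds])
  n_tot <- length(cond)
  responses <- t(vapply(cond, function(cn) {
    profiles[[cn]] + stats::rnorm(n_neurons, 0, noise_sd)
  }, numeric(n_neurons)))
  rownames(responses) <- NULL

  wrong <- condition_pair("stim", "no_stim")
  match <- true_match_quality(responses, cond, profiles, wrong)
  p_success <- link_success(match, cond, link_slope, decision_noise,
                            stats::rnorm(n_tot))
  success_label <- c(stim = "hit", no_stim = "correct_rejection")
  failure_label <- c(stim = "miss", no_stim = "false_positive")
  outcome <- character(n_tot)
  if (is.null(outcome_counts)) {
    ok <- stats::runif(n_tot) < p_success
    outcome <- ifelse(ok, success_label[cond], failure_label[cond])
  } else {
    for (cn in conds) {
      idx <- which(cond == cn)
      counts <- outcome_counts[[cn]]
      n_ok <- counts[[success_label[[cn]]]]
      if (n_ok + counts[[failure_label[[cn]]]] != length(idx)) {
        stop_validation("outcome_counts for '%s' must sum to %d", cn, length(idx))
      }
      best <- idx[order(p_success[idx], decreasing = TRUE)]
      outcome[best[seq_len(n_ok)]] <- success_label[[cn]]
      outcome[setdiff(idx, best[seq_len(n_ok)])] <- failure_label[[cn]]
    }
  }
  tr <- data.frame(trial_id = sprintf("t%03d", seq_len(n_tot)),
                   condition = cond, outcome = outcome,
                   stringsAsFactors = FALSE)
  s <- population_session(responses, tr, modality = "continuous",
                          area_label = "synthetic-continuous",
                          window_annotation = "synthetic (pre-averaged)")
  attr(s, "ground_truth") <- list(profiles = profiles, match = match,
                                  p_success = p_success, seed = as.integer(seed))
  s
}

#' Synthetic spike-count two-alternative session
#'
#' Emulates a two-choice discrimination session with integer spike counts:
#' conditions `"left"` and `"right"`, Poisson counts around per-condition
#' rate profiles, hit/miss outcomes from a sigmoid link on ground-truth
#' match quality, and optional latent two-mode structure within each
#' condition (two distinct rate profiles per condition) for testing trial
#' clustering and grouped recomputation. A pupil-like covariate column
#' `cov_pupil` tracks the latent mode (plus noise) when modes are on, and is
#' pure noise otherwise.
#'
#' @param n_neurons number of neurons (default 40).
#' @param n_trials trials per condition: scalar or named vector (`left`,
#'   `right`).
#' @param baseline_rate mean baseline rate (spikes per window), default 5.
#' @param separation scale of per-neuron rate differences between the two
#'   conditions; 0 gives identical profiles (no signal).
#' @param latent_modes if `TRUE`, each condition has two latent response
#'   modes whose profiles differ by `mode_strength`; trials pick a mode at
#'   random.
#' @param mode_strength SD of the per-neuron mode offsets (default 3).
#' @param link_slope,decision_noise sigmoid outcome link parameters, as in
#'   [make_continuous_fixture()].
#' @param seed integer seed.
#' @return a counts-modality [population_session()] with attribute
#'   `"ground_truth"` (profiles, per-trial mode, match quality).
#' @export
make_count_fixture <- function(n_neurons = 40, n_trials = 50,
                               baseline_rate = 5, separation = 2,
                               latent_modes = FALSE, mode_strength = 3,
                               link_slope = 5, decision_noise = 0, seed) {
  if (missing(seed)) stop_validation("an explicit seed is required")
  if (n_neurons < 2) stop_validation("need >= 2 neurons")
  conds <- c("left", "right")
  if (length(n_trials) == 1) n_trials <- stats::setNames(rep(n_trials, 2), conds)
  if (!all(conds %in% names(n_trials))) {
    stop_validation("n_trials must name conditions 'left' and 'right'")
  }
  if (any(n_trials < 2)) stop_validation("need >= 2 trials per condition")
  set.seed(as.integer(seed))
  xi <- stats::runif(n_neurons, -1, 1)  # signed preference left vs right
  floor_rate <- 0.05
  profiles <- list(left = pmax(baseline_rate + separation * xi, floor_rate),
                   right = pmax(baseline_rate - separation * xi, floor_rate))
  mode_offsets <- if (latent_modes) {
    lapply(stats::setNames(conds, conds), function(cn) {
      list(m1 = stats::rnorm(n_neurons, 0, mode_strength),
           m2 = stats::rnorm(n_neurons, 0, mode_strength))
    })
  } else NULL

  cond <- rep(conds, times = n_trials[conds])
  n_tot <- length(cond)
  mode <- if (latent_modes) sample(c(1L, 2L), n_tot, replace = TRUE)
          else rep(NA_integer_, n_tot)
  rates <- t(vapply(seq_len(n_tot), function(i) {
    r <- profiles[[cond[i]]]
    if (latent_modes) {
      off <- mode_offsets[[cond[i]]][[mode[i]]]
      r <- pmax(r + off, floor_rate)
    }
    r
  }, numeric(n_neurons)))
  counts <- matrix(stats::rpois(length(rates), rates), nrow = n_tot)

  wrong <- condition_pair("left", "right")
  match <- true_match_quality(counts, cond, profiles, wrong)
  p_success <- link_success(match, cond, link_slope, decision_noise,
                            stats::rnorm(n_tot))
  ok <- stats::runif(n_tot) < p_success
  pupil <- if (latent_modes) mode + stats::rnorm(n_tot, 0, 0.1)
           else stats::rnorm(n_tot)
  tr <- data.frame(trial_id = sprintf("t%03d", seq_len(n_tot)),
                   condition = cond,
                   outcome = ifelse(ok, "hit", "miss"),
                   cov_pupil = pupil, stringsAsFactors = FALSE)
  s <- population_session(counts, tr, modality = "counts",
                          area_label = "synthetic-counts",
                          window_annotation = "synthetic (pre-averaged)")
  attr(s, "ground_truth") <- list(profiles = profiles, mode = mode,
                                  match = match, p_success = p_success,
                                  seed = as.integer(seed))
  s
}
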