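#' Simulation configuration
#'
#' Parameters of the generative model used to map how selectivity spread,
#' noise, and decision noise shape Specificity and Behavioural Relevance:
#' two binary stimuli drawn Bernoulli per trial, a population of Poisson
#' neurons whose rates are a ReLU of baseline + gain x selectivity x
#' stimulus difference plus half-normal background noise, and a sigmoidal
#' choice rule on the noisy Specificity Index.
#'
#' @param n_trials number of trials.
#' @param n_neurons population size; default 200.
#' @param p1,p2 Bernoulli parameters of the two stimuli; default 0.5 each
#'   (two equally likely values per stimulus).
#' @param beta selectivity concentration of the `Beta(beta, beta)` law:
#'   `beta < 1` gives segregated, bimodal preferences; `beta = 1` uniform;
#'   `beta > 1` homogeneous near-zero selectivity.
#' @param baseline_mean,baseline_sd normal law of per-neuron baseline rates
#'   \eqn{r_j^0}; defaults N(5, 1) (spikes per window).
#' @param gain_mean,gain_sd normal law of per-neuron stimulus gains
#'   \eqn{g_j^s}; defaults N(5, 1).
#' @param snr signal-to-noise control > 0. The background-noise scale is
#'   `noise_sd = gain_mean / snr`, so the default `snr = 5` gives the
#'   unit-variance half-normal noise of the base setting.
#' @param decision_noise_q standard deviation `q >= 0` of the Gaussian
#'   perturbation added to the Specificity Index before the sigmoid choice.
#' @param seed integer master seed; per-stage streams are derived from it so
#'   adding a stage never perturbs earlier draws.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_trials = 200, n_neurons = 200,
                              p1 = 0.5, p2 = 0.5, beta = 1,
                              baseline_mean = 5, baseline_sd = 1,
                              gain_mean = 5, gain_sd = 1,
                              snr = 5, decision_noise_q = 0, seed = 1) {
  stopifnot_config <- function(ok, msg) if (!ok) stop_validation(msg)
  stopifnot_config(n_trials >= 1 && n_neurons >= 2, "need n_trials >= 1, n_neurons >= 2")
  stopifnot_config(p1 >= 0 && p1 <= 1 && p2 >= 0 && p2 <= 1, "p1, p2 must lie in [0, 1]")
  stopifnot_config(beta > 0, "beta must be > 0")
  stopifnot_config(baseline_sd >= 0 && gain_sd >= 0, "sds must be >= 0")
  stopifnot_config(snr > 0, "snr must be > 0")
  stopifnot_config(decision_noise_q >= 0, "decision_noise_q must be >= 0")
  structure(
    list(n_trials = as.integer(n_trials), n_neurons = as.integer(n_neurons),
         p1 = p1, p2 = p2, beta = beta,
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         gain_mean = gain_mean, gain_sd = gain_sd,
         snr = snr, noise_sd = gain_mean / snr,
         decision_noise_q = decision_noise_q, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# Deterministic per-stage seed derived from the master seed; keeps stages
# independent so adding one never perturbs earlier draws. Stays below 2^31.
stage_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 10000L
  as.integer((abs(as.integer(seed)) %% 100000L) * 20011L + h)
}

#' Draw the per-trial stimulus pair
#'
#' Each trial draws the two binary stimuli independently:
#' `S1 ~ Bernoulli(p1)`, `S2 ~ Bernoulli(p2)`; the stimulus difference is
#' `delta_s = S1 - S2` (positive when stimulus 1 is larger). Trials with
#' `delta_s = 0` carry no correct answer and are excluded downstream.
#'
#' @param config a [simulation_config()].
#' @return data.frame with columns `S1`, `S2`, `delta_s`.
#' @export
draw_stimuli <- function(config) {
  set.seed(stage_seed(config$seed, "stimuli"))
  s1 <- stats::rbinom(config$n_trials, 1, config$p1)
  s2 <- stats::rbinom(config$n_trials, 1, config$p2)
  data.frame(S1 = s1, S2 = s2, delta_s = s1 - s2)
}

#' Draw the simulated neuronal population
#'
#' Per-neuron selectivity `xi = 2 * Beta(beta, beta) - 1` (shift-and-scale
#' to `[-1, 1]`), baseline rates and stimulus gains i.i.d. normal with the
#' configured parameters.
#'
#' @param config a [simulation_config()].
#' @return `simulated_population`: list with `xi`, `baseline`, `gain`.
#' @export
draw_population <- function(config) {
  set.seed(stage_seed(config$seed, "population"))
  n <- config$n_neurons
  structure(
    list(xi = 2 * stats::rbeta(n, config$beta, config$beta) - 1,
         baseline = stats::rnorm(n, config$baseline_mean, config$baseline_sd),
         gain = stats::rnorm(n, config$gain_mean, config$gain_sd)),
    class = "simulated_population"
  )
}

#' Firing rates from population and stimulus differences
#'
#' \deqn{r_{i,j} = ReLU(r_j^0 + g_j^s \xi_j \Delta S_i) + |N(0, \sigma^2)|}
#' The ReLU enforces nonnegativity of the stimulus-driven part; the folded
#' normal adds background noise while keeping rates nonnegative.
#'
#' @param population a `simulated_population`.
#' @param delta_s per-trial stimulus differences.
#' @param noise_sd background-noise scale (>= 0).
#' @param seed integer seed for the noise draw.
#' @return trials x neurons rate matrix, all entries >= 0.
#' @export
simulate_rates <- function(population, delta_s, noise_sd, seed) {
  if (noise_sd < 0) stop_validation("noise_sd must be >= 0")
  if (missing(seed)) stop_validation("an explicit seed is required")
  drive <- outer(delta_s, population$xi * population$gain) +
    rep(population$baseline, each = length(delta_s))
  drive <- pmax(drive, 0)
  set.seed(as.integer(seed))
  noise <- abs(matrix(stats::rnorm(length(drive), 0, noise_sd),
                      nrow = nrow(drive)))
  drive + noise
}

#' Poisson spike counts from rates
#'
#' @param rates nonnegative trials x neurons rate matrix.
#' @param seed integer seed.
#' @return integer matrix of the same shape, `s_ij ~ Poisson(r_ij)`.
#' @export
simulate_spikes <- function(rates, seed) {
  if (any(rates < 0)) stop_validation("rates must be nonnegative")
  if (missing(seed)) stop_validation("an explicit seed is required")
  set.seed(as.integer(seed))
  s <- matrix(stats::rpois(length(rates), rates), nrow = nrow(rates))
  dimnames(s) <- dimnames(rates)
  s
}

#' Noisy sigmoidal decision rule
#'
#' \eqn{\psi' = \rho + N(0, q^2)}; the decision probability is
#' \eqn{p = 1 / (1 + e^{-\psi'})} and the outcome is 1 (correct) iff
#' \eqn{p \ge 0.5}, equivalently \eqn{\psi' \ge 0}.
#'
#' @param rho_base per-trial Specificity values entering the decision.
#' @param q decision-noise standard deviation (>= 0).
#' @param seed integer seed.
#' @return data.frame with `psi_noisy`, `decision_probability`, `outcome`
#'   (integer 0/1).
#' @export
simulate_decision <- function(rho_base, q, seed) {
  if (q < 0) stop_validation("q must be >= 0")
  if (missing(seed)) stop_validation("an explicit seed is required")
  set.seed(as.integer(seed))
  psi <- rho_base + stats::rnorm(length(rho_base), 0, q)
  p <- stats::plogis(psi)
  data.frame(psi_noisy = psi, decision_probability = p,
             outcome = as.integer(p >= 0.5))
}

#' Run the full generative pipeline
#'
#' Stimuli -> population -> rates -> Poisson spikes -> empirical templates
#' for `delta_s = +1` and `-1` (trials with `delta_s = 0` have no correct
#' behavioural response and are excluded from all Specificity and Relevance
#' computations) -> per-trial Specificity against the empirical templates
#' (what an analyst can compute, not the ground-truth rate profiles) ->
#' noisy sigmoid decisions -> Behavioural Relevance comparing correct
#' (outcome 1) vs incorrect (outcome 0) trials.
#'
#' @param config a [simulation_config()].
#' @return `simulation_result`: list with `config`, `stimuli`, `population`,
#'   `rates`, `spikes`, `session` (counts-modality [population_session()] of
#'   the included trials, conditions `"stim1"`/`"stim2"`), `templates`,
#'   `specificity`, `decision`, `relevance`.
#' @export
run_simulation <- function(config) {
  stim <- draw_stimuli(config)
  pop <- draw_population(config)
  rates <- simulate_rates(pop, stim$delta_s, config$noise_sd,
                          seed = stage_seed(config$seed, "rates"))
  spikes <- simulate_spikes(rates, seed = stage_seed(config$seed, "spikes"))

  included <- which(stim$delta_s != 0)
  if (sum(stim$delta_s == 1) < 2 || sum(stim$delta_s == -1) < 2) {
    stop_computation("need >= 2 trials with delta_s = +1 and -1 for templates")
  }
  cond <- ifelse(stim$delta_s[included] == 1, "stim1", "stim2")
  # Outcomes are filled in after the decision stage; placeholder labels keep
  # the session valid for template/specificity computation.
  tr <- data.frame(trial_id = paste0("t", included), condition = cond,
                   outcome = "correct", stringsAsFactors = FALSE)
  session <- population_session(spikes[included, , drop = FALSE], tr,
                                modality = "counts",
                                area_label = "simulated")
  pair <- condition_pair("stim1", "stim2")
  templates <- compute_templates(session, c("stim1", "stim2"))
  spec <- specificity_index(session, pair, templates = templates)

  rho <- stats::setNames(spec$trials$rho, spec$trials$trial_id)
  dec <- simulate_decision(unname(rho), config$decision_noise_q,
                           seed = stage_seed(config$seed, "decision"))
  dec$trial_id <- names(rho)
  session$trials$outcome <- ifelse(
    session$trials$trial_id %in% dec$trial_id[dec$outcome == 1],
    "correct", "incorrect")
  rel <- behavioural_relevance(rho[dec$outcome == 1], rho[dec$outcome == 0],
                               groups_compared = c("correct", "incorrect"))
  structure(
    list(config = config, stimuli = stim, population = pop,
         rates = rates, spikes = spikes, session = session,
         templates = templates, specificity = spec, decision = dec,
         relevance = rel),
    class = "simulation_result"
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %d trials (%d analysed), %d neurons\n",
              x$config$n_trials, nrow(x$specificity$trials), x$config$n_neurons))
  cat(sprintf("  median rho = %.4f; Omega = %s\n",
              stats::median(x$specificity$trials$rho),
              if (x$relevance$defined) sprintf("%.4f", x$relevance$omega) else "undefined"))
  invisible(x)
}

#' Parameter-landscape sweep
#'
#' Runs seeded replicate simulations over a grid of selectivity
#' concentrations (`beta_grid`) crossed with either signal-to-noise levels
#' (`snr_grid`; the cell statistic is the median Specificity \eqn{\rho}) or
#' decision-noise levels (`q_grid`; the cell statistic is \eqn{\Omega}).
#' Optionally masks cells compatible with a measured value:
#' `|measured - modelled| < threshold` (default threshold 0.05).
#'
#' @param config_template a [simulation_config()] supplying all parameters
#'   not on the grid.
#' @param beta_grid numeric vector of beta values.
#' @param snr_grid,q_grid exactly one of the two must be non-NULL.
#' @param n_replicates replicate simulations per cell.
#' @param seed integer seed; each (cell, replicate) gets a distinct derived
#'   seed.
#' @param measured_value optional measured median rho (or Omega) to compare
#'   against.
#' @param threshold compatibility threshold; default 0.05.
#' @return `landscape_result`: list with `beta_grid`, `second_axis`
#'   (`"snr"` or `"q"`), `second_grid`, `values` (beta x second grid matrix
#'   of cell medians across replicates), `replicates` (long data.frame),
#'   `metric`, and optionally `compatibility` mask.
#' @export
sweep_landscape <- function(config_template, beta_grid,
                            snr_grid = NULL, q_grid = NULL,
                            n_replicates = 10, seed,
                            measured_value = NULL, threshold = 0.05) {
  if (missing(seed)) stop_validation("an explicit seed is required")
  if (length(beta_grid) == 0) stop_validation("beta_grid must be non-empty")
  if (is.null(snr_grid) == is.null(q_grid)) {
    stop_validation("supply exactly one of snr_grid or q_grid")
  }
  second <- if (!is.null(snr_grid)) snr_grid else q_grid
  if (length(second) == 0) stop_validation("grid must be non-empty")
  axis <- if (!is.null(snr_grid)) "snr" else "q"
  metric <- if (axis == "snr") "median_rho" else "omega"

  values <- matrix(NA_real_, nrow = length(beta_grid), ncol = length(second),
                   dimnames = list(paste0("beta=", beta_grid),
                                   paste0(axis, "=", second)))
  reps <- list()
  cell <- 0L
  for (bi in seq_along(beta_grid)) {
    for (si in seq_along(second)) {
      cell <- cell + 1L
      vals <- numeric(n_replicates)
      for (r in seq_len(n_replicates)) {
        cfg <- config_template
        cfg$beta <- beta_grid[bi]
        if (axis == "snr") {
          cfg$snr <- second[si]
          cfg$noise_sd <- cfg$gain_mean / cfg$snr
        } else {
          cfg$decision_noise_q <- second[si]
        }
        cfg$seed <- as.integer((abs(as.integer(seed)) + 7919 * cell + r) %% 2147483647)
        sim <- run_simulation(cfg)
        vals[r] <- if (metric == "median_rho") {
          stats::median(sim$specificity$trials$rho)
        } else {
          if (sim$relevance$defined) sim$relevance$omega else NA_real_
        }
      }
      values[bi, si] <- stats::median(vals, na.rm = TRUE)
      reps[[cell]] <- data.frame(beta = beta_grid[bi], second = second[si],
                                 replicate = seq_len(n_replicates), value = vals)
    }
  }
  out <- list(beta_grid = beta_grid, second_axis = axis, second_grid = second,
              values = values, replicates = do.call(rbind, reps),
              metric = metric, threshold = threshold)
  if (!is.null(measured_value)) {
    out$measured_value <- measured_value
    out$compatibility <- abs(measured_value - values) < threshold
  }
  structure(out, class = "landscape_result")
}

#' @export
print.landscape_result <- function(x, ...) {
  cat(sprintf("<landscape_result> %s over %d beta x %d %s cells\n",
              x$metric, length(x$beta_grid), length(x$second_grid), x$second_axis))
  print(round(x$values, 4))
  invisible(x)
}
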