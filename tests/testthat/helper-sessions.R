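# Shared in-code fixtures: tiny deterministic sessions and random sample
# pairs for the rank-statistic oracle comparisons.

toy_session <- function() {
  # 4 trials x 3 neurons, two conditions, fully deterministic
  resp <- rbind(c(1, 2, 3),
                c(2, 3, 4),
                c(3, 2, 1),
                c(4, 3, 2))
  tr <- data.frame(trial_id = paste0("t", 1:4),
                   condition = c("a", "a", "b", "b"),
                   outcome = c("hit", "miss", "hit", "hit"),
                   stringsAsFactors = FALSE)
  population_session(resp, tr, modality = "continuous")
}

random_count_session <- function(seed, n_trials = 20, n_neurons = 8) {
  set.seed(seed)
  resp <- matrix(rpois(n_trials * n_neurons, lambda = runif(n_neurons, 2, 10)),
                 nrow = n_trials, byrow = TRUE)
  tr <- data.frame(trial_id = paste0("t", seq_len(n_trials)),
                   condition = rep(c("a", "b"), length.out = n_trials),
                   outcome = sample(c("hit", "miss"), n_trials, replace = TRUE),
                   stringsAsFactors = FALSE)
  population_session(resp, tr, modality = "counts")
}

# Random sample pairs spanning sizes 2-50, continuous and heavily tied.
random_sample_pair <- function(seed) {
  set.seed(seed)
  n_x <- sample(2:50, 1)
  n_y <- sample(2:50, 1)
  style <- sample(c("uniform", "normal", "ties"), 1)
  gen <- switch(style,
    uniform = function(n) runif(n),
    normal = function(n) rnorm(n),
    ties = function(n) sample(0:4, n, replace = TRUE))
  list(x = gen(n_x), y = gen(n_y))
}

ab_pair <- function() condition_pair("a", "b")
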