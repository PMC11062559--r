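test_that("jackknife contributions satisfy the leave-one-out identity", {
  s <- random_count_session(21, n_trials = 10, n_neurons = 5)
  jk <- jackknife_contributions(s, ab_pair())
  n <- n_neurons(s)
  full <- specificity_index(s, ab_pair())
  rho_full <- setNames(full$trials$rho, full$trials$trial_id)
  # independent recomputation of rho without each neuron, straight from cor()
  for (j in seq_len(n)) {
    tpl <- compute_templates(s)
    for (id in jk$trial_ids) {
      i <- match(id, s$trials$trial_id)
      cond <- s$trials$condition[i]
      wrong <- ab_pair()[[cond]]
      r <- s$responses[i, -j]
      rho_wo <- cor(tpl[[cond]]$mean_vector[-j], r) -
        cor(tpl[[wrong]]$mean_vector[-j], r)
      expect_equal(jk$contributions[id, j],
                   n * rho_full[[id]] - (n - 1) * rho_wo,
                   tolerance = 1e-10)
    }
  }
})

test_that("a neuron whose removal leaves rho unchanged contributes exactly rho", {
  # noiseless mirrored session: every 'a' trial equals v, every 'b' trial
  # equals -v, so rho = 1 - (-1) = 2 for every trial and every neuron subset;
  # the identity then forces every contribution to equal rho itself
  v <- c(1, 2, 3, 5)
  resp <- rbind(v, v, -v, -v)
  tr <- data.frame(trial_id = paste0("t", 1:4),
                   condition = c("a", "a", "b", "b"),
                   outcome = "hit")
  s <- population_session(resp, tr)
  jk <- jackknife_contributions(s, ab_pair())
  expect_true(all(abs(jk$contributions - 2) < 1e-12))
})

test_that("gamma is zero for symmetric contribution distributions", {
  expect_equal(yule_kendall(c(-2, -1, 0, 1, 2)), 0)
  mirrored <- c(-5, -3, -1, 1, 3, 5)
  expect_equal(yule_kendall(mirrored), 0)
})

test_that("extreme-neuron selection sizes, stability and disjointness", {
  s <- random_count_session(31, n_trials = 16, n_neurons = 10)
  jk <- jackknife_contributions(s, ab_pair())
  top <- select_extreme_neurons(jk, 0.10, "top")
  expect_length(top, 1)  # ceil(0.1 * 10)
  # ceiling rule at n = 7
  s7 <- random_count_session(32, n_trials = 16, n_neurons = 7)
  jk7 <- jackknife_contributions(s7, ab_pair())
  expect_length(select_extreme_neurons(jk7, 0.10, "top"), 1)
  # oracle: independent sort of the medians
  med <- jk$neuron_medians
  expect_identical(select_extreme_neurons(jk, 0.3, "top"),
                   jk$neuron_ids[order(med, decreasing = TRUE)][1:3])
  expect_identical(select_extreme_neurons(jk, 0.3, "bottom"),
                   jk$neuron_ids[order(med)][1:3])
  expect_length(intersect(select_extreme_neurons(jk, 0.3, "top"),
                          select_extreme_neurons(jk, 0.3, "bottom")), 0)
  expect_error(select_extreme_neurons(jk, 0.6), class = "specrel_validation_error")
  expect_error(select_extreme_neurons(jk, 0), class = "specrel_validation_error")
})

test_that("subsampling at fraction 1 reproduces the full-population metrics", {
  s <- make_count_fixture(n_trials = 30, seed = 14)
  pair <- condition_pair("left", "right")
  res <- subsample_metrics(s, pair, fractions = c(0.5, 1), n_repeats = 3,
                           seed = 9)
  expect_equal(nrow(res), 2 * 3)  # one row per fraction x repeat
  full_spec <- specificity_index(s, pair)
  full_omega <- relevance_of(full_spec)$omega
  at1 <- res[res$fraction == 1, ]
  expect_true(all(at1$median_rho == median(full_spec$trials$rho)))
  expect_true(all(at1$omega == full_omega))
  expect_error(subsample_metrics(s, pair, fractions = 0.01, seed = 1),
               class = "specrel_validation_error")
  # reproducible under seed
  res2 <- subsample_metrics(s, pair, fractions = c(0.5, 1), n_repeats = 3,
                            seed = 9)
  expect_identical(as.data.frame(res), as.data.frame(res2))
})

test_that("median rho stays roughly flat when selectivity is spread out", {
  s <- make_count_fixture(n_neurons = 40, n_trials = 80, separation = 3,
                          seed = 2)
  res <- subsample_metrics(s, condition_pair("left", "right"),
                           fractions = seq(0.2, 1, 0.2), n_repeats = 10,
                           seed = 3)
  ct <- suppressWarnings(stats::cor.test(res$fraction, res$median_rho,
                                         method = "spearman",
                                         alternative = "greater"))
  expect_gt(ct$p.value, 0.05)  # no significant rise with population size
})

test_that("trial clustering recovers well-separated response modes", {
  set.seed(6)
  blob1 <- matrix(rnorm(20 * 5, mean = 0), ncol = 5)
  blob2 <- matrix(rnorm(20 * 5, mean = 6), ncol = 5)
  resp <- rbind(blob1, blob2)
  tr <- data.frame(trial_id = paste0("t", 1:40),
                   condition = rep(c("a", "b"), 20),
                   outcome = "hit")
  s <- population_session(resp, tr)
  cl <- cluster_trials(s, k_range = 2:4, seed = 1)
  expect_equal(cl$chosen_k, 2)
  membership <- rep(1:2, each = 20)
  agreement <- max(mean(cl$labels == membership),
                   mean(cl$labels == 3 - membership))
  expect_equal(agreement, 1)
  expect_identical(cl$labels, cluster_trials(s, k_range = 2:4, seed = 1)$labels)
})

test_that("mean silhouette matches the textbook formula on a worked example", {
  # 4 trials in 2 dimensions, both columns equal: points 0, 1, 10, 11
  resp <- cbind(c(0, 1, 10, 11), c(0, 1, 10, 11))
  tr <- data.frame(trial_id = paste0("t", 1:4), condition = "a",
                   outcome = "hit")
  s <- population_session(resp, tr)
  cl <- cluster_trials(s, k_range = 2, seed = 3)
  # hand evaluation after per-column standardization x -> (x - 5.5)/sd
  z <- (c(0, 1, 10, 11) - 5.5) / sd(c(0, 1, 10, 11))
  d <- function(i, j) sqrt(2) * abs(z[i] - z[j])
  s_i <- function(a, b) (b - a) / max(a, b)
  sil <- c(
    s_i(d(1, 2), mean(c(d(1, 3), d(1, 4)))),
    s_i(d(2, 1), mean(c(d(2, 3), d(2, 4)))),
    s_i(d(3, 4), mean(c(d(3, 1), d(3, 2)))),
    s_i(d(4, 3), mean(c(d(4, 1), d(4, 2)))))
  expect_equal(unname(cl$silhouette["k2"]), mean(sil), tolerance = 1e-12)
})

test_that("clustering rejects degenerate all-identical data", {
  resp <- matrix(5, nrow = 8, ncol = 3)
  tr <- data.frame(trial_id = paste0("t", 1:8), condition = "a",
                   outcome = "hit")
  s <- population_session(resp, tr)
  expect_error(cluster_trials(s, k_range = 2:3, seed = 1),
               class = "specrel_computation_error")
})

test_that("grouped metrics: identity grouping reproduces the pooled baseline", {
  s <- make_count_fixture(n_trials = 25, seed = 17)
  pair <- condition_pair("left", "right")
  gm <- metrics_by_group(s, pair, rep("all", n_trials(s)))
  expect_equal(nrow(gm$groups), 1)
  expect_equal(gm$groups$median_rho, gm$baseline$median_rho)
  expect_equal(gm$groups$omega, gm$baseline$omega)
  expect_equal(gm$groups$n_trials, n_trials(s))
})

test_that("groups below the minimum size are skipped with a reason", {
  s <- make_count_fixture(n_trials = 25, seed = 18)
  labels <- rep("big", n_trials(s))
  labels[1] <- "solo"
  gm <- metrics_by_group(s, condition_pair("left", "right"), labels,
                         min_group_size = 4)
  expect_equal(gm$skipped$label, "solo")
  expect_match(gm$skipped$reason, "insufficient")
  expect_error(metrics_by_group(s, condition_pair("left", "right"),
                                as.character(seq_len(n_trials(s)))),
               class = "specrel_computation_error")
})

test_that("grouping accepts covariate quantile splits and table columns", {
  s <- make_count_fixture(n_trials = 40, latent_modes = TRUE,
                          mode_strength = 4, seed = 19)
  pair <- condition_pair("left", "right")
  gm_cov <- metrics_by_group(s, pair, list(covariate = "pupil", n_groups = 2))
  expect_equal(nrow(gm_cov$groups), 2)
  s$trials$block <- rep(c("early", "late"), length.out = n_trials(s))
  gm_col <- metrics_by_group(s, pair, "block", min_group_size = 2)
  expect_setequal(gm_col$groups$label, c("early", "late"))
  expect_error(metrics_by_group(s, pair, list(covariate = "absent")),
               class = "specrel_validation_error")
})

test_that("latent response modes raise within-group specificity over pooled", {
  wins <- vapply(1:10, function(seed) {
    s <- make_count_fixture(n_trials = 60, separation = 1,
                            latent_modes = TRUE, mode_strength = 4,
                            seed = seed)
    gt <- attr(s, "ground_truth")
    gm <- metrics_by_group(s, condition_pair("left", "right"),
                           as.character(gt$mode))
    median(gm$groups$median_rho) > gm$baseline$median_rho
  }, logical(1))
  expect_gte(sum(wins), 8)
})
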