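test_that("pearson_correlation matches hand-computed values and flags degeneracy", {
  expect_equal(pearson_correlation(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(-1, -2, -3)), -1)
  # covariance/SD formula by hand: centred dot 3, norms sqrt(5)*sqrt(5)
  expect_equal(pearson_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_identical(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), NA_real_)
  expect_identical(pearson_correlation(c(1, 2, 3), c(5, 5, 5)), NA_real_)
  expect_error(pearson_correlation(1:3, 1:4), class = "specrel_validation_error")
  expect_error(pearson_correlation(1, 2), class = "specrel_validation_error")
})

test_that("compute_templates averages per condition and errors on empty conditions", {
  s <- toy_session()
  tpl <- compute_templates(s)
  expect_named(tpl, c("a", "b"))
  expect_equal(unname(tpl$a$mean_vector), c(1.5, 2.5, 3.5))
  expect_equal(tpl$a$n_trials, 2L)
  # single-trial condition: template equals that trial
  resp <- matrix(c(0, 2), nrow = 1)
  one <- population_session(resp, data.frame(trial_id = "t1", condition = "A",
                                             outcome = "hit"))
  expect_equal(unname(compute_templates(one, "A")$A$mean_vector), c(0, 2))
  expect_error(compute_templates(s, "missing_cond"),
               class = "specrel_validation_error",
               regexp = "missing_cond")
})

test_that("specificity index reproduces hand-evaluated correlations", {
  # 4-neuron toy: rho = cor([2,1,4,3], r) - cor([4,3,2,1], r) = 0.6 - (-1)
  s <- population_session(matrix(c(1, 2, 3, 4), nrow = 1),
                          data.frame(trial_id = "t1", condition = "a",
                                     outcome = "hit"))
  tpl <- list(
    a = structure(list(condition = "a", mean_vector = c(2, 1, 4, 3),
                       n_trials = 1L), class = "condition_template"),
    b = structure(list(condition = "b", mean_vector = c(4, 3, 2, 1),
                       n_trials = 1L), class = "condition_template"))
  sp <- specificity_index(s, ab_pair(), templates = tpl)
  expect_equal(sp$trials$rho, 1.6)

  # identical templates: rho identically zero
  tpl$b$mean_vector <- tpl$a$mean_vector
  sp0 <- specificity_index(s, ab_pair(), templates = tpl)
  expect_equal(sp0$trials$rho, 0)

  # anti-correlated wrong template attains the upper bound 2 exactly
  v <- c(0.3, -1.2, 2.5, 0.7)
  tpl$a$mean_vector <- v
  tpl$b$mean_vector <- -v
  s2 <- population_session(matrix(v, nrow = 1),
                           data.frame(trial_id = "t1", condition = "a",
                                      outcome = "hit"))
  expect_equal(specificity_index(s2, ab_pair(), templates = tpl)$trials$rho, 2)
})

test_that("zero-variance trials are excluded with a reason, not imputed", {
  resp <- rbind(c(1, 2, 3), c(5, 5, 5), c(3, 1, 2), c(2, 3, 1))
  tr <- data.frame(trial_id = paste0("t", 1:4),
                   condition = c("a", "a", "b", "b"),
                   outcome = rep("hit", 4))
  s <- population_session(resp, tr)
  sp <- specificity_index(s, ab_pair())
  expect_equal(sp$excluded$trial_id, "t2")
  expect_match(sp$excluded$reason, "zero-variance trial vector")
  expect_setequal(sp$trials$trial_id, c("t1", "t3", "t4"))
})

test_that("rho is invariant under positive affine transforms of the trial vector", {
  s <- random_count_session(11)
  sp <- specificity_index(s, ab_pair())
  s_affine <- s
  s_affine$responses <- 3.7 * s$responses + 12
  s_affine$modality <- "continuous"
  tpl <- compute_templates(s)  # same templates: isolate the trial-vector transform
  sp2 <- specificity_index(s_affine, ab_pair(), templates = tpl)
  expect_equal(sp2$trials$rho, sp$trials$rho, tolerance = 1e-12)
})

test_that("leave-one-out recomputes the correct template without the scored trial", {
  s <- toy_session()
  sp <- specificity_index(s, ab_pair(), leave_one_out = TRUE)
  # trial t1 ('a'): LOO correct template is the other 'a' trial, row 2
  lam_c <- c(2, 3, 4)
  lam_w <- colMeans(s$responses[3:4, ])
  expected <- stats::cor(lam_c, s$responses[1, ]) - stats::cor(lam_w, s$responses[1, ])
  expect_equal(sp$trials$rho[sp$trials$trial_id == "t1"], expected)
  # single-trial condition cannot be left out
  one <- subset_session(s, trials = c(1, 3, 4))
  expect_error(specificity_index(one, ab_pair(), leave_one_out = TRUE),
               class = "specrel_validation_error")
})

test_that("mann_whitney_u follows the mid-rank convention and its identities", {
  u <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(u$U_X, 0)
  expect_equal(u$U, 0)
  u2 <- mann_whitney_u(1:4, 1:4)
  expect_equal(u2$U_X, 16 / 2)
  expect_equal(u2$U_X, u2$U_Y)
  u3 <- mann_whitney_u(c(1, 2, 3), c(2, 3, 4))
  expect_equal(u3$U_X, 2)  # brute-force enumeration of all 9 pairs
  expect_error(mann_whitney_u(numeric(0), 1), class = "specrel_validation_error")
  # U_X + U_Y = n_X n_Y on random inputs; agrees with the standard test statistic
  for (seed in 1:25) {
    p <- random_sample_pair(seed)
    u <- mann_whitney_u(p$x, p$y)
    expect_equal(u$U_X + u$U_Y, u$n_X * u$n_Y)
    w <- suppressWarnings(stats::wilcox.test(p$x, p$y))
    expect_equal(unname(w$statistic), u$U_X)
  }
})

test_that("rank-based A equals the pairwise oracle, including heavy ties", {
  expect_equal(vargha_delaney_A(c(5, 6), c(1, 2)), 1)
  expect_equal(vargha_delaney_A(1:5, 1:5), 0.5)
  expect_equal(vargha_delaney_A(c(1, 2, 3), c(2, 3, 4)), 2 / 9)
  expect_equal(brute_force_A(5, 1), 1)
  expect_equal(brute_force_A(1, 1), 0.5)
  for (seed in 1:200) {
    p <- random_sample_pair(seed)
    a <- vargha_delaney_A(p$x, p$y)
    expect_identical(a, brute_force_A(p$x, p$y))
    # complements to within one ulp (two independent divisions)
    expect_equal(a + vargha_delaney_A(p$y, p$x), 1, tolerance = 1e-14)
  }
})

test_that("behavioural relevance hits its anchors and is symmetric", {
  expect_equal(behavioural_relevance(c(1, 2, 3), c(10, 11, 12))$omega, 1)
  expect_equal(behavioural_relevance(1:5, 1:5)$omega, 0.5)
  expect_equal(behavioural_relevance(c(1, 2, 3), c(2, 3, 4))$omega, 7 / 9)
  for (seed in 1:50) {
    p <- random_sample_pair(seed)
    o_xy <- behavioural_relevance(p$x, p$y)$omega
    o_yx <- behavioural_relevance(p$y, p$x)$omega
    expect_identical(o_xy, o_yx)
    expect_gte(o_xy, 0.5)
    expect_lte(o_xy, 1)
  }
})

test_that("relevance below the minimum group size is flagged, not fabricated", {
  r <- behavioural_relevance(c(1), c(2, 3, 4))
  expect_false(r$defined)
  expect_identical(r$omega, NA_real_)
  expect_equal(r$n_X, 1L)
  expect_equal(r$n_Y, 3L)
})

test_that("yule_kendall skewness follows the linear-interpolation convention", {
  expect_equal(yule_kendall(1:5), 0)          # (4 + 2 - 6) / (4 - 2)
  sym <- c(-3, -1, 0, 1, 3)                    # mirror-symmetric about median
  expect_equal(yule_kendall(sym), 0)
  # hand evaluation, type-7 quantiles of {0,0,0,1,10}: Q25=0, Q50=0, Q75=1
  expect_equal(yule_kendall(c(0, 0, 0, 1, 10)), 1)
  expect_identical(yule_kendall(c(5, 5, 5, 5)), NA_real_)  # zero IQR
  expect_error(yule_kendall(c(1, 2)), class = "specrel_validation_error")
  set.seed(42)
  for (i in 1:50) {
    g <- yule_kendall(rnorm(sample(3:40, 1)))
    if (!is.na(g)) expect_lte(abs(g), 1)
  }
})

test_that("fano factor uses the unbiased variance over condition trials", {
  resp <- rbind(c(1, 2, 0), c(3, 2, 0))
  tr <- data.frame(trial_id = c("t1", "t2"), condition = "a",
                   outcome = c("hit", "miss"))
  s <- population_session(resp, tr, modality = "counts")
  ff <- fano_factor(s, "a")
  expect_equal(unname(ff[1]), 1)            # var 2 / mean 2
  expect_equal(unname(ff[2]), 0)            # constant counts
  expect_identical(unname(ff[3]), NA_real_) # zero mean flagged
  expect_error(fano_factor(subset_session(s, trials = 1), "a"),
               class = "specrel_validation_error")
})

test_that("fano factor of Poisson counts concentrates at 1", {
  set.seed(99)
  n <- 10000
  resp <- matrix(rpois(n, 5), ncol = 1)
  tr <- data.frame(trial_id = paste0("t", 1:n), condition = "a",
                   outcome = "hit")
  s <- population_session(resp, tr, modality = "counts")
  # SE of the Fano factor for Poisson is approximately sqrt(2/n)
  expect_lt(abs(fano_factor(s, "a")[[1]] - 1), 3 * sqrt(2 / n))
})
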