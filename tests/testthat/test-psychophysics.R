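# Simulated observers and the statistical analyses.

test_that("simulated reports follow the psychometric probabilities", {
  # saturated model: certain "far" reports
  m_hi <- psychometric_model(beta0 = 100, beta1 = 0, lapse_rate = 0,
                             subject_sd = 0)
  d <- experiment_design(n_subjects = 2, coherences_pct = c(50, 100),
                         trials_per_cell = 25)
  tr <- simulate_responses(m_hi, d, seed = 1)
  expect_true(all(tr$report == "far"))

  # balanced model: proportions near 0.5
  m_mid <- psychometric_model(beta0 = 0, beta1 = 0, lapse_rate = 0,
                              subject_sd = 0)
  d2 <- experiment_design(n_subjects = 1, coherences_pct = c(50, 100),
                          trials_per_cell = 2000)
  tr2 <- simulate_responses(m_mid, d2, seed = 2)
  expect_lt(abs(mean(tr2$report == "far") - 0.5), 3 * sqrt(0.25 / nrow(tr2)))

  # per-condition proportions converge to the model probabilities (n = 1e4)
  m <- psychometric_model(beta0 = -15, beta1 = 0.2, lapse_rate = 0.02,
                          subject_sd = 0)
  d3 <- experiment_design(n_subjects = 1, coherences_pct = c(60, 75, 90),
                          trials_per_cell = 10000)
  tr3 <- simulate_responses(m, d3, seed = 3)
  for (cc in c(60, 75, 90)) {
    obs <- mean(tr3$report[tr3$coherence_pct == cc] == "far")
    p <- psychometric_prob(m, cc)
    expect_lt(abs(obs - p), 2 * sqrt(p * (1 - p) / 10000) + 1e-6)
  }

  # seeded permutation: reproducible, and a genuine interleaving
  tr4 <- simulate_responses(m, d, seed = 9)
  tr5 <- simulate_responses(m, d, seed = 9)
  expect_identical(tr4, tr5)
  expect_false(all(diff(tr4$subject_id) >= 0))
})

test_that("logistic fits recover generating parameters and flag degeneracy", {
  m <- psychometric_model(beta0 = -20, beta1 = 0.25, lapse_rate = 0,
                          subject_sd = 0)
  d <- experiment_design(n_subjects = 1,
                         coherences_pct = c(50, 60, 70, 75, 80, 90, 100),
                         trials_per_cell = 100)
  tr <- simulate_responses(m, d, seed = 4)
  fit <- fit_logistic(tr)
  expect_true(fit$converged)
  expect_lt(abs(fit$coefficients[1] - -20), 3 * fit$std_errors[1])
  expect_lt(abs(fit$coefficients[2] - 0.25), 3 * fit$std_errors[2])
  expect_true(all(fit$fitted$fitted > 0 & fit$fitted$fitted < 1))
  expect_true(fit$r_squared >= 0 && fit$r_squared <= 1)

  # balanced 50/50 data: slope estimate ~ 0
  m0 <- psychometric_model(beta0 = 0, beta1 = 0, lapse_rate = 0,
                           subject_sd = 0)
  tr0 <- simulate_responses(m0, d, seed = 5)
  fit0 <- fit_logistic(tr0)
  expect_lt(abs(fit0$coefficients[2]), 3 * fit0$std_errors[2])

  # degenerate data raise errors instead of fitting silently
  one_level <- tr[tr$coherence_pct == 70, ]
  expect_error(fit_logistic(one_level), "2 distinct coherence")
  all_far <- tr
  all_far$report <- "far"
  expect_error(fit_logistic(all_far), "separation")
})

test_that("the exact binomial test matches full enumeration at n = 20", {
  # independent oracle: minimum-likelihood two-sided exact p-value
  oracle_p <- function(k, n, p0) {
    probs <- dbinom(0:n, n, p0)
    sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
  }
  for (k in 0:20) {
    expect_equal(binomial_proportions_test(k, 20, 0.5), oracle_p(k, 20, 0.5))
    expect_equal(binomial_proportions_test(k, 20, 0.3), oracle_p(k, 20, 0.3))
  }
  # closed-form spot checks and symmetry at p0 = 0.5
  expect_equal(binomial_proportions_test(1, 1, 0.5), 1)
  expect_equal(binomial_proportions_test(20, 20, 0.5), 2 * 0.5^20)
  for (k in 0:10) {
    expect_equal(binomial_proportions_test(k, 20, 0.5),
                 binomial_proportions_test(20 - k, 20, 0.5))
  }
})

test_that("the exact test's type-I error never exceeds nominal alpha", {
  # full enumeration at n = 20, p0 = 0.5
  probs <- dbinom(0:20, 20, 0.5)
  pvals <- vapply(0:20, binomial_proportions_test, numeric(1), n = 20)
  for (alpha in c(0.01, 0.05, 0.1)) {
    expect_lte(sum(probs[pvals <= alpha]), alpha)
  }
})

test_that("the chi-square normality check calibrates and has power", {
  # null behavior (a quick check; the 1000-rep calibration runs with the
  # acceptance suite)
  set.seed(6)
  ps <- replicate(200, residual_normality_chisq(rnorm(2000))$p_value)
  expect_gt(mean(ps < 0.05), 0.005)
  expect_lt(mean(ps < 0.05), 0.12)

  # heavy bimodality is rejected decisively
  bim <- c(rnorm(500, -3, 0.3), rnorm(500, 3, 0.3))
  expect_lt(residual_normality_chisq(bim)$p_value, 0.01)

  # too few residuals for valid bins -> explicit error
  expect_error(residual_normality_chisq(rnorm(15)), "too few residuals")
  expect_error(residual_normality_chisq(rep(1, 50)), "zero variance")

  # df accounts for the two estimated moments
  res <- residual_normality_chisq(rnorm(200), n_bins = 10)
  expect_identical(res$df, 7L)
  expect_identical(res$n_bins, 10L)
})

test_that("the contrast-gating experiment reproduces the report pattern", {
  sp <- small_spec(duration_s = 0.5, rng_seed = 77)
  dsg <- experiment_design(n_subjects = 6, trials_per_cell = 15)
  e2 <- run_experiment_2(spec = sp, design = dsg, seed = 7)

  # the ideal observer answers F in all six conditions
  expect_true(all(e2$io_decisions$decision == "F"))

  pr <- e2$proportions
  get <- function(cond, coh) pr$prop_far[pr$condition == cond &
                                           pr$coherence_pct == coh]
  # static surround: far percept in every arm
  for (cond in c("none", "low-surround", "low-center")) {
    expect_gt(get(cond, 100), 0.5)
  }
  # full flicker without a segmentation cue: the contextual reversal
  expect_lt(get("none", 50), 0.5)
  # a contrast cue on either region restores the far percept
  expect_gt(get("low-surround", 50), 0.5)
  expect_gt(get("low-center", 50), 0.5)

  # identical seeds give identical tables
  e2b <- run_experiment_2(spec = sp, design = dsg, seed = 7)
  expect_identical(e2$proportions, e2b$proportions)
  expect_identical(e2$trials, e2b$trials)

  # unknown condition labels are rejected at the design level
  expect_error(experiment_design(conditions = "low-background"))
})
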