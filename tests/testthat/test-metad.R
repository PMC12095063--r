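test_that("type-2 tabulation matches a hand tally and drops reference trials", {
  fx <- make_fixture("trials_micro")
  counts <- tabulate_type2(fx$input)
  expect_equal(counts$counts[, , c("low", "high")],
               fx$expected$counts[, , c("low", "high")],
               ignore_attr = TRUE)
  expect_equal(counts$n_used, fx$expected$n_used)
  expect_equal(counts$n_dropped_reference, fx$expected$n_dropped_reference)

  # a single repeated trial fills a single cell
  one <- data.frame(task = "decision", target_length = 420,
                    response = "long", confidence = "high",
                    stringsAsFactors = FALSE)[rep(1, 10), ]
  counts1 <- tabulate_type2(one)
  expect_equal(counts1$counts["long", "long", "high"], 10, ignore_attr = TRUE)
  expect_equal(sum(counts1$counts), 10)

  # simulated data: tabulated total is the decision total minus reference trials
  tr <- sim_trials(observer_params(), seed = 111)
  cts <- tabulate_type2(tr)
  dec <- tr[tr$task == "decision", ]
  expect_equal(cts$n_used, nrow(dec) - sum(dec$target_length == 400))
  expect_equal(cts$n_dropped_reference, sum(dec$target_length == 400))
})

test_that("the optimizer matches the brute-force grid search", {
  for (seed in c(121, 122, 123)) {
    arr <- random_type2_counts(seed)
    fit <- fit_meta_d(arr)
    grid <- oracle_metad_grid(arr)
    expect_lt(abs(fit$fit_log_likelihood - grid$log_lik), 1e-3)
    expect_lt(abs(fit$meta_d - grid$meta_d), 0.02)
  }
})

test_that("meta-d equals d-prime for an ideal metacognitive observer", {
  tr <- sim_trials(make_fixture("ideal_metacognition")$input, reps = 40,
                   seed = 125)
  fit <- fit_meta_d(tabulate_type2(tr))
  expect_lt(abs(fit$m_ratio - 1), 0.05)
  expect_equal(fit$log_m_ratio, log(fit$m_ratio), tolerance = 1e-12)
})

test_that("metacognitive noise lowers M-ratio; random confidence kills meta-d", {
  tr <- sim_trials(make_fixture("noisy_metacognition")$input, reps = 40,
                   seed = 127)
  noisy <- fit_meta_d(tabulate_type2(tr))
  expect_lt(noisy$m_ratio, 0.95)
  expect_gt(noisy$m_ratio, 0.3)

  rand <- tr
  set.seed(128)
  rand$confidence[rand$task == "decision"] <-
    sample(c("low", "high"), sum(rand$task == "decision"), replace = TRUE)
  fit <- fit_meta_d(tabulate_type2(rand))
  expect_lt(abs(fit$meta_d), 0.15)
})

test_that("meta-d is invariant to relabeling the stimulus classes", {
  arr <- random_type2_counts(131)
  fit <- fit_meta_d(arr)
  sw <- arr[c("long", "short"), c("long", "short"), ]
  dimnames(sw) <- dimnames(arr)
  fit_sw <- fit_meta_d(sw)
  expect_equal(fit_sw$m_ratio, fit$m_ratio, tolerance = 1e-4)
  expect_equal(fit_sw$d_prime, fit$d_prime, tolerance = 1e-10)
})

test_that("the group posterior recovers the mean log M-ratio and converges", {
  set.seed(133)
  m <- exp(rnorm(30, -0.2, 0.25))
  post <- group_mratio_posterior(m, seed = 7, n_iter = 8000L)
  expect_true(post$converged)
  expect_lt(post$rhat, 1.02)
  expect_lt(abs(mean(post$draws_mean_log_mratio) + 0.2), 0.1)

  # near-ideal subjects give a group M-ratio near 1
  m1 <- exp(rnorm(30, 0, 0.02))
  post1 <- group_mratio_posterior(m1, seed = 7, n_iter = 8000L)
  expect_lt(abs(mean(post1$draws_mean_mratio) - 1), 0.05)

  # non-positive M-ratios are excluded with a warning
  expect_warning(group_mratio_posterior(c(m, -0.1), seed = 7, n_iter = 4000L),
                 "excluded")
  expect_error(suppressWarnings(
    group_mratio_posterior(c(1, 1, -1, -1, -1), seed = 7)), ">= 5")
})

test_that("the M-ratio difference BF separates null from real differences", {
  set.seed(135)
  m_long <- exp(rnorm(30, -0.2, 0.2))
  m_short <- exp(rnorm(30, -0.2, 0.2))
  pl <- group_mratio_posterior(m_long, seed = 11, n_iter = 8000L)
  ps <- group_mratio_posterior(m_short, seed = 12, n_iter = 8000L)
  null_bf <- mratio_difference_bf(pl, ps)
  # same vector: posterior difference concentrates at zero
  self_bf <- mratio_difference_bf(pl, pl)
  expect_lte(self_bf$bf10, 1)

  m_shift <- exp(rnorm(30, -0.5, 0.2))  # about d = 1.5 on the log scale
  ps2 <- group_mratio_posterior(m_shift, seed = 13, n_iter = 8000L)
  diff_bf <- mratio_difference_bf(pl, ps2)
  expect_gt(diff_bf$bf10, null_bf$bf10)
  expect_gt(diff_bf$bf10, 3)
})
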