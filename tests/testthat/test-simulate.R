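test_that("trial records carry exactly the fields their task defines", {
  tr <- sim_trials(observer_params(), seed = 3)
  dec <- tr[tr$task == "decision", ]
  rep_ <- tr[tr$task == "reproduction", ]
  expect_true(all(!is.na(dec$response) & !is.na(dec$confidence)))
  expect_true(all(is.na(dec$reproduced_length)))
  expect_true(all(is.na(rep_$response) & is.na(rep_$confidence)))
  expect_true(all(!is.na(rep_$reproduced_length)))
  # correctness undefined exactly at the reference length
  expect_true(all(is.na(dec$correct[dec$target_length == 400])))
  expect_true(all(!is.na(dec$correct[dec$target_length != 400])))
  expect_equal(dec$correct[dec$target_length != 400],
               (dec$target_length[dec$target_length != 400] > 400) ==
                 (dec$response[dec$target_length != 400] == "long"))
})

test_that("an unbiased observer answers long half the time at the reference", {
  tr <- sim_trials(observer_params(), reps = 30, seed = 5)
  at_ref <- tr[tr$task == "decision" & tr$target_length == 400, ]
  p <- mean(at_ref$response == "long")
  expect_gt(nrow(at_ref), 1000)
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / nrow(at_ref)))
})

test_that("simulation is deterministic under a fixed seed", {
  a <- sim_trials(observer_params(perceptual_shift = 4), seed = 11)
  b <- sim_trials(observer_params(perceptual_shift = 4), seed = 11)
  expect_identical(a, b)
})

test_that("a zero-noise observer is rejected", {
  expect_error(observer_params(sensory_sd = 0), "degenerate")
  expect_error(observer_params(reproduction_slope = 0))
  expect_error(observer_params(metacognitive_noise_sd = -1))
})

test_that("perceptual vs criterion shifts dissociate the three landmarks", {
  # Muller-Lyer-like observer: all three landmarks move by -p
  ml <- sim_trials(observer_params(perceptual_shift = 10), reps = 25, seed = 21)
  expect_lt(abs(fit_decision(ml)$landmark - 390), 2)
  expect_lt(abs(fit_confidence(ml)$landmark - 390), 3)
  expect_lt(abs(fit_reproduction(ml)$landmark - 390), 2)
  # criterion-shift observer: decision and confidence move, reproduction stays
  cs <- sim_trials(observer_params(decision_criterion_shift = 10,
                                   confidence_center_shift = 5),
                   reps = 25, seed = 22)
  expect_lt(abs(fit_decision(cs)$landmark - 410), 2)
  expect_lt(abs(fit_confidence(cs)$landmark - 405), 3)
  expect_lt(abs(fit_reproduction(cs)$landmark - 400), 2)
})

test_that("trial tables round-trip through the delimited text format", {
  tr <- sim_trials(observer_params(), seed = 9)
  path <- tempfile(fileext = ".csv")
  write_trials(tr, path)
  back <- read_trials(path)
  expect_equal(back$response, tr$response)
  expect_equal(back$reproduced_length, tr$reproduced_length, tolerance = 1e-12)
  expect_equal(back$correct, tr$correct)
  # header sanity: missing columns are reported by name
  bad <- tr[, setdiff(names(tr), c("response", "confidence"))]
  path2 <- tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(read_trials(path2), "response, confidence")
})

test_that("cohort simulation respects group sizes and is reproducible", {
  tr <- simulate_cohort(n_per_group = c(muller_lyer = 3, base_rate = 2,
                                        payoff = 2), seed = 4)
  per_subject <- table(unique(tr[, c("subject_id", "bias_source")])$bias_source)
  expect_equal(as.integer(per_subject[c("muller_lyer", "base_rate", "payoff")]),
               c(3L, 2L, 2L))
  # each muller_lyer/payoff subject: 840 trials; base_rate: 1170
  n_by_subj <- table(tr$subject_id, tr$bias_source)
  expect_true(all(rowSums(n_by_subj)[unique(tr$subject_id[tr$bias_source == "base_rate"])] == 1170))
  expect_true(all(rowSums(n_by_subj)[unique(tr$subject_id[tr$bias_source == "payoff"])] == 840))
  tr2 <- simulate_cohort(n_per_group = c(muller_lyer = 3, base_rate = 2,
                                         payoff = 2), seed = 4)
  expect_identical(tr, tr2)
})
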