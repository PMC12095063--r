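test_that("d-prime and criterion follow the inverse-normal formulas", {
  m <- sdt_from_rates(0.5, 0.5)
  expect_equal(m$d_prime, 0)
  expect_equal(m$criterion_c, 0)
  # Z(HR) = 1, Z(FAR) = -1
  m <- sdt_from_rates(pnorm(1), pnorm(-1))
  expect_equal(m$d_prime, 2, tolerance = 1e-10)
  expect_equal(m$criterion_c, 0, tolerance = 1e-10)
  # whenever HR = 1 - FAR the criterion is exactly zero
  for (hr in c(0.55, 0.7, 0.9, 0.99))
    expect_equal(sdt_from_rates(hr, 1 - hr)$criterion_c, 0, tolerance = 1e-12)
})

test_that("measures match the independent inverse-normal oracle", {
  set.seed(71)
  for (i in 1:20) {
    hr <- runif(1, 0.02, 0.98)
    far <- runif(1, 0.02, 0.98)
    m <- sdt_from_rates(hr, far)
    zh <- oracle_inverse_normal(hr)
    zf <- oracle_inverse_normal(far)
    expect_lt(abs(m$d_prime - (zh - zf)), 1e-6)
    expect_lt(abs(m$criterion_c - 0.5 * (zh + zf)), 1e-6)
  }
})

test_that("swapping the signal and noise roles flips c and preserves d-prime", {
  tr <- sim_trials(observer_params(decision_criterion_shift = 8), reps = 4,
                   seed = 73)
  m <- sdt_measures(tr)
  # mirror the stimulus axis about the reference and relabel responses
  mirrored <- tr
  mirrored$target_length <- 800 - tr$target_length
  mirrored$response <- ifelse(tr$response == "long", "short", "long")
  m2 <- sdt_measures(mirrored)
  expect_equal(m2$d_prime, m$d_prime, tolerance = 1e-10)
  expect_equal(m2$criterion_c, -m$criterion_c, tolerance = 1e-10)
})

test_that("reference-length trials are excluded and edge rates corrected", {
  tr <- sim_trials(observer_params(), seed = 75)
  dec <- tr[tr$task == "decision", ]
  m <- sdt_measures(tr)
  expect_equal(m$n_signal, sum(dec$target_length > 400))
  expect_equal(m$n_noise, sum(dec$target_length < 400))
  # a perfect responder gets corrected rates strictly inside (0, 1)
  perfect <- dec
  perfect$response <- ifelse(perfect$target_length > 400, "long", "short")
  mp <- sdt_measures(perfect)
  expect_lt(mp$HR, 1); expect_gt(mp$FAR, 0)
  expect_equal(mp$HR, 1 - 1 / (2 * mp$n_signal))
  # single-class input is rejected
  expect_error(sdt_measures(dec[dec$target_length > 400, ]), "long-target")
})

test_that("participant screening applies the 4-SD and negative-d-prime rules", {
  base <- data.frame(subject_id = sprintf("s%02d", 1:20),
                     d_prime = rep(2, 20), criterion_c = rep(0.1, 20),
                     reproduction_error = rep(15, 20),
                     stringsAsFactors = FALSE)
  # identical subjects: zero SD excludes nobody
  res <- screen_participants(base)
  expect_equal(nrow(res$excluded), 0L)
  expect_length(res$kept, 20L)

  neg <- base; neg$d_prime[3] <- -0.2
  neg$d_prime[-3] <- rnorm(19, 2, 0.2)
  res <- screen_participants(neg)
  expect_true("s03" %in% res$excluded$subject_id)
  expect_true("negative_dprime" %in%
                res$excluded$reason[res$excluded$subject_id == "s03"])

  # a single 10-SD outlier in a sample large enough for its z-score to
  # exceed 4 even after it inflates the pooled SD
  out <- data.frame(subject_id = sprintf("s%02d", 1:40),
                    d_prime = rep(2, 40), criterion_c = rep(0.1, 40),
                    stringsAsFactors = FALSE)
  set.seed(77)
  out$reproduction_error <- rnorm(40, 15, 1)
  out$reproduction_error[7] <- 15 + 10 * sd(out$reproduction_error[-7])
  res <- screen_participants(out)
  expect_identical(unique(res$excluded$subject_id), "s07")
  expect_identical(unique(res$excluded$reason), "reproduction_error_outlier")
})

test_that("an unbiased observer has near-zero expected criterion", {
  tr <- sim_trials(observer_params(), reps = 25, seed = 79)
  m <- sdt_measures(tr)
  expect_lt(abs(m$criterion_c), 0.05)
  # sensitivity decreases with sensory noise
  tr_noisy <- sim_trials(observer_params(sensory_sd = 30), reps = 25, seed = 79)
  expect_gt(m$d_prime, sdt_measures(tr_noisy)$d_prime)
})
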