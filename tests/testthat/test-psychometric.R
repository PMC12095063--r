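test_that("probit fit recovers the generative PSE and is coding-invariant", {
  tr <- sim_trials(observer_params(), reps = 40, seed = 31)
  fit <- fit_decision(tr)
  expect_true(fit$quality_pass)
  expect_lt(abs(fit$landmark - 400), 1.5)
  # relabeling which response is 'success' leaves the PSE unchanged
  flipped <- tr
  flipped$response <- ifelse(flipped$response == "long", "short", "long")
  fit2 <- fit_decision(flipped)
  expect_equal(fit$landmark, fit2$landmark, tolerance = 1e-8)
})

test_that("uninformative decision data fail the quality screen without error", {
  # perfectly balanced responses at every length: zero slope
  lens <- rep(seq(370, 430, 10), each = 10)
  tr <- data.frame(task = "decision", target_length = lens,
                   response = rep(c("long", "short"), length(lens) / 2),
                   stringsAsFactors = FALSE)
  fit <- fit_decision(tr)
  expect_false(fit$quality_pass)
  # all-identical responses: landmark undefined, no exception
  tr$response <- "long"
  fit <- fit_decision(tr)
  expect_false(fit$quality_pass)
  expect_true(is.na(fit$landmark))
})

test_that("quadratic confidence fit interpolates the vertex analytically", {
  # proportions exactly on an upward parabola centered at 400
  lens <- seq(370, 430, 10)
  y <- 0.0005 * (lens - 400)^2 + 0.2   # 13/20, 8/20, 5/20, 4/20, ...
  k <- as.integer(round(y * 20))
  rows <- do.call(rbind, lapply(seq_along(lens), function(i) {
    data.frame(task = "decision", target_length = lens[i],
               confidence = c(rep("high", k[i]), rep("low", 20 - k[i])),
               stringsAsFactors = FALSE)
  }))
  fit <- fit_confidence(rows)
  expect_true(fit$quality_pass)
  expect_equal(fit$landmark, 400, tolerance = 1e-9)
  # analytic vertex equals a dense numeric minimization of the fitted curve
  co <- fit$coefficients
  num <- stats::optimize(function(x) co[["a"]] * x^2 + co[["b"]] * x + co[["c"]],
                         c(300, 500), tol = 1e-10)$minimum
  expect_equal(fit$landmark, num, tolerance = 1e-6)
  # inverted-U confidence fails the sign rule
  rows$confidence <- ifelse(rows$confidence == "high", "low", "high")
  expect_false(fit_confidence(rows)$quality_pass)
  # fewer than 3 distinct lengths is a hard error
  expect_error(fit_confidence(rows[rows$target_length < 390, ]), "3 distinct")
})

test_that("reproduction fit interpolates the reference match point", {
  lens <- rep(seq(370, 430, 10), each = 5)
  exact <- data.frame(task = "reproduction", target_length = lens,
                      reproduced_length = 40 + 0.9 * lens,
                      stringsAsFactors = FALSE)
  fit <- fit_reproduction(exact)
  expect_true(fit$quality_pass)
  expect_equal(fit$landmark, 400, tolerance = 1e-9)

  ident <- transform(exact, reproduced_length = target_length)
  expect_equal(fit_reproduction(ident)$landmark, 400, tolerance = 1e-9)

  # analytic match point equals numeric root finding on the fitted line
  set.seed(41)
  noisy <- transform(exact,
                     reproduced_length = reproduced_length + rnorm(nrow(exact), 0, 10))
  fitn <- fit_reproduction(noisy)
  co <- fitn$coefficients
  root <- stats::uniroot(function(x) co[1] + co[2] * x - 400, c(200, 600),
                         tol = 1e-10)$root
  expect_equal(fitn$landmark, root, tolerance = 1e-6)

  expect_error(fit_reproduction(exact[exact$target_length == 370, ]),
               "2 distinct")
})

test_that("observer with a perceptual shift moves the reproduction match point", {
  tr <- sim_trials(observer_params(perceptual_shift = 20), reps = 10, seed = 43)
  fit <- fit_reproduction(tr)
  expect_lt(abs(fit$landmark - 380), 2.5)
})

test_that("landmark effects use the short-minus-long convention", {
  mk <- function(landmark) {
    f <- fit_decision(sim_trials(observer_params(), reps = 2, seed = 51))
    f$landmark <- landmark
    f
  }
  expect_equal(landmark_effect(mk(400), mk(400)), 0)
  expect_equal(landmark_effect(mk(395), mk(405)), 10)
  bad <- mk(400); bad$curve_kind <- "reproduction_linear"
  expect_error(landmark_effect(mk(400), bad), "kinds differ")
  failed <- mk(400); failed$quality_pass <- FALSE
  expect_error(landmark_effect(failed, mk(400)), "quality")
})

test_that("cohort landmark effects recover the generative shift doubles", {
  set.seed(61)
  trials <- simulate_cohort(n_per_group = c(base_rate = 12), groups = "base_rate",
                            seed = 61)
  eff <- landmark_effects(fit_cohort(trials))
  dec <- eff$effect_px[eff$curve == "decision"]
  # generative decision effect is 2|c_dec| = 14 px
  expect_gt(length(dec), 8)
  expect_lt(abs(mean(dec) - 14), 2 * stats::sd(dec) / sqrt(length(dec)) + 1.5)
})
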