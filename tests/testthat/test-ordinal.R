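test_that("the model lattice enumerates 2^k labeled constraint patterns", {
  groups <- c("muller_lyer", "base_rate", "payoff")
  models <- enumerate_models(groups)
  expect_length(models, 8L)
  expect_equal(models[[1]]$label, "A")
  expect_true(all(models[[1]]$constraints == "positive_effect"))
  expect_equal(models[[8]]$label, "null")
  expect_true(all(models[[8]]$constraints == "null_effect"))
  # all patterns distinct
  pats <- sapply(models, function(m) paste(m$constraints, collapse = ""))
  expect_equal(anyDuplicated(pats), 0L)

  expect_length(enumerate_models("g1"), 2L)
  expect_error(enumerate_models(letters[1:6]))
})

test_that("the encompassing-prior identity holds against draw counting", {
  set.seed(101)
  for (d in c(0, 0.3, 0.6)) {
    x <- rnorm(35, d, 1)
    g <- group_effect_bf(x)
    res <- jzs_bf_paired(x, sided = "two", n_samples = 1e5, seed = 3)
    mass_draws <- mean(res$posterior_effect_samples > 0)
    expect_lt(abs(g$bf_ordinal_vs_unconstrained - 2 * mass_draws), 0.02 * 2)
    # BF(ordinal vs null) = encompassing ratio x unconstrained BF10
    expect_equal(g$bf_positive_vs_null,
                 g$bf_ordinal_vs_unconstrained * g$bf10_unconstrained,
                 tolerance = 1e-10)
  }
  # posterior entirely above zero doubles the unconstrained model's BF
  strong <- rnorm(50, 3, 0.5)
  g <- group_effect_bf(strong)
  expect_equal(g$bf_ordinal_vs_unconstrained, 2, tolerance = 1e-4)
  # exact null data leave the constraint uninformative
  g0 <- group_effect_bf(rep(0, 20))
  expect_equal(g0$posterior_positive_mass, 0.5, tolerance = 1e-6)
  expect_equal(g0$bf_ordinal_vs_unconstrained, 1, tolerance = 1e-5)
})

test_that("the lattice factorizes over groups and finds the right winner", {
  # all-null data: the null model wins
  eff0 <- list(g1 = rep(c(-1, 1), 10), g2 = rep(c(-2, 2), 10))
  res0 <- lattice_bf(eff0)
  expect_equal(res0$winning_label, "null")
  expect_gte(res0$bf_best_over_second, 1)

  # one group with a strong effect reduces to group_effect_bf exactly
  set.seed(103)
  x <- rnorm(40, 1, 1)
  res1 <- lattice_bf(list(only = x))
  expect_equal(res1$table$bf_over_null[res1$table$label == "A"],
               group_effect_bf(x)$bf_positive_vs_null, tolerance = 1e-10)
  expect_equal(res1$table$bf_over_null[res1$table$label == "null"], 1)

  # effect only in one of three groups: the single-effect model wins
  set.seed(104)
  eff <- list(ml = rnorm(40, 1.2, 1), ba = rnorm(40, 0, 1),
              pa = rnorm(40, 0, 1))
  res <- lattice_bf(eff)
  expect_true(res$winning_constraints[["ml"]] == "positive_effect")
  # a model's BF over null is the product of its groups' BFs
  per <- res$per_group_bf
  a_row <- res$table[res$table$label == "A", ]
  expect_equal(a_row$bf_over_null, prod(per), tolerance = 1e-10)
})

test_that("task-difference models respect sign symmetry and degenerate input", {
  set.seed(105)
  dec <- list(g1 = rnorm(30, 8, 3), g2 = rnorm(30, 2, 3))
  conf <- list(g1 = rnorm(30, 3, 3), g2 = rnorm(30, 6, 3))
  fwd <- task_difference_models(dec, conf)
  rev <- task_difference_models(conf, dec)
  # swapping tasks mirrors every pattern's score exactly
  mirror <- function(lab) {
    out <- gsub("dec>conf", "XX", lab)
    out <- gsub("conf>dec", "dec>conf", out)
    gsub("XX", "conf>dec", out)
  }
  for (i in seq_len(nrow(fwd$table))) {
    lab <- fwd$table$label[i]
    j <- which(rev$table$label == mirror(lab))
    expect_equal(fwd$table$bf_over_null[i], rev$table$bf_over_null[j],
                 tolerance = 1e-10)
  }
  # g1 has the larger decision effect, g2 the larger confidence effect
  expect_equal(unname(fwd$winning_constraints[["g1"]]), "dec_gt_conf")
  expect_equal(unname(fwd$winning_constraints[["g2"]]), "conf_gt_dec")

  # all-zero differences: the all-equal model wins
  same <- list(g1 = rnorm(20, 5, 2))
  eq <- task_difference_models(same, same)
  expect_true(all(eq$winning_constraints == "equal"))

  expect_error(task_difference_models(list(g1 = 1:5), list(g1 = 1:4)),
               "unpaired")
  expect_error(task_difference_models(list(g1 = 1:5), list(g2 = 1:5)),
               "same groups")
})

test_that("a criterion-leak observer shows a larger decision than confidence effect", {
  # base-rate-like group with c_conf = 0.5 c_dec
  trials <- simulate_cohort(n_per_group = c(base_rate = 20),
                            groups = "base_rate", seed = 107)
  eff <- landmark_effects(fit_cohort(trials))
  paired <- merge(eff[eff$curve == "decision", c("subject_id", "effect_px")],
                  eff[eff$curve == "confidence", c("subject_id", "effect_px")],
                  by = "subject_id")
  td <- task_difference_models(list(ba = paired$effect_px.x),
                               list(ba = paired$effect_px.y))
  expect_equal(unname(td$winning_constraints[["ba"]]), "dec_gt_conf")
})
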