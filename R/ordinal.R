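# Encompassing-prior ordinal model comparison. Each between-subject group
# contributes an independent one-sample problem on its per-subject effect
# scores, so the Bayes factor of a multi-group constraint pattern against
# the all-null model factorizes into per-group terms: the encompassing-prior
# BF of an ordinal (sign) constraint against the unconstrained model is the
# ratio of posterior to prior mass satisfying the constraint (prior mass =
# 1/2 for a symmetric prior), and equality constraints are the group's null.

#' Enumerate the lattice of effect/null constraint models
#'
#' Builds all 2^k models over k groups, where each group either shows a
#' positive ordinal effect (biased-to-long > biased-to-short) or no effect.
#' The all-effects model comes first (label "A") and the all-null model last
#' (label "null"); intermediate models are labeled alphabetically in
#' decreasing binary order of their effect patterns. Labels are canonical
#' bookkeeping only; tests and reports should identify models by their
#' constraint maps.
#'
#' @param groups Character vector of 1--5 group names.
#' @return A list of \code{constraint_model} objects, each a list with
#'   \code{label} and \code{constraints} (named character vector,
#'   \code{"positive_effect"} or \code{"null_effect"}).
#' @export
enumerate_models <- function(groups) {
  k <- length(groups)
  stopifnot(k >= 1L, k <= 5L)
  n_models <- 2L^k
  # masks in decreasing binary order: all-ones first, zero last
  masks <- (n_models - 1L):0L
  labels <- c("A", if (n_models > 2L) LETTERS[2:(n_models - 1L)], "null")
  lapply(seq_along(masks), function(i) {
    bits <- as.integer(intToBits(masks[i]))[k:1]
    constraints <- ifelse(bits == 1L, "positive_effect", "null_effect")
    names(constraints) <- groups
    structure(list(label = labels[i], constraints = constraints),
              class = "constraint_model")
  })
}

#' Encompassing-prior Bayes factor for one group's positive effect
#'
#' For one group's per-subject effect scores, computes the Bayes factor of
#' the sign-constrained model (standardized effect > 0) against the null,
#' via the encompassing-prior identity: BF(ordinal vs unconstrained) equals
#' the posterior mass above zero divided by the prior mass above zero (1/2
#' for the symmetric Cauchy prior), and BF(ordinal vs null) is that ratio
#' times the two-sided JZS BF of the unconstrained model.
#'
#' @param effects Per-subject effect scores for the group.
#' @param r Cauchy prior scale.
#' @return A list with \code{bf_positive_vs_null},
#'   \code{bf_ordinal_vs_unconstrained}, \code{posterior_positive_mass},
#'   \code{prior_positive_mass}, \code{bf10_unconstrained}.
#' @export
group_effect_bf <- function(effects, r = sqrt(2) / 2) {
  x <- effects
  if (any(!is.finite(x))) stop("non-finite effects", call. = FALSE)
  n <- length(x)
  if (n < 2L) stop("need at least two effect scores", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0 && mean(x) != 0) stop("zero variance in effects", call. = FALSE)
  # an all-zero vector is the scale-invariant limit of null data: t = 0
  t <- if (s == 0) 0 else mean(x) / (s / sqrt(n))
  m1 <- jzs_marginal(t, n, r)
  bf_two <- m1 / stats::dt(t, n - 1)
  mass <- jzs_marginal_positive(t, n, r) / m1
  list(bf_positive_vs_null = bf_two * mass / 0.5,
       bf_ordinal_vs_unconstrained = mass / 0.5,
       posterior_positive_mass = mass,
       prior_positive_mass = 0.5,
       bf10_unconstrained = bf_two)
}

#' Lattice Bayes-factor comparison over groups
#'
#' Scores every constraint model against the all-null baseline. Groups are
#' independent samples, so a model's BF over null is the product over its
#' positive-effect groups of the per-group sign-constrained BF (null-effect
#' groups contribute 1).
#'
#' @param effects_by_group Named list of per-subject effect vectors.
#' @param models List of models from [enumerate_models()]; defaults to the
#'   full lattice over \code{names(effects_by_group)}.
#' @param r Cauchy prior scale.
#' @return An object of class \code{model_comparison}: list with
#'   \code{table} (data.frame: label, constraint string, bf_over_null,
#'   log10_bf), \code{winning_label}, \code{winning_constraints},
#'   \code{bf_best_over_second}.
#' @export
lattice_bf <- function(effects_by_group, models = NULL, r = sqrt(2) / 2) {
  groups <- names(effects_by_group)
  if (is.null(models)) models <- enumerate_models(groups)
  for (m in models)
    if (!all(groups %in% names(m$constraints)))
      stop("model ", m$label, " is missing a constraint for some group",
           call. = FALSE)
  per_group <- vapply(effects_by_group, function(e)
    group_effect_bf(e, r = r)$bf_positive_vs_null, numeric(1))
  bf <- vapply(models, function(m) {
    pos <- names(m$constraints)[m$constraints == "positive_effect"]
    prod(per_group[pos])
  }, numeric(1))
  finish_comparison(models, bf, per_group)
}

#' @keywords internal
finish_comparison <- function(models, bf, per_group = NULL) {
  labels <- vapply(models, `[[`, character(1), "label")
  constr <- vapply(models, function(m)
    paste(names(m$constraints), m$constraints, sep = "=", collapse = "; "),
    character(1))
  ord <- order(bf, decreasing = TRUE)
  tab <- data.frame(label = labels, constraints = constr,
                    bf_over_null = bf, log10_bf = log10(bf),
                    stringsAsFactors = FALSE)
  structure(
    list(table = tab,
         winning_label = labels[ord[1]],
         winning_constraints = models[[ord[1]]]$constraints,
         bf_best_over_second = bf[ord[1]] / bf[ord[2]],
         per_group_bf = per_group),
    class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  tab <- x$table[order(x$table$bf_over_null, decreasing = TRUE), ]
  print(utils::head(data.frame(label = tab$label,
                               bf_over_null = signif(tab$bf_over_null, 4),
                               log10_bf = round(tab$log10_bf, 2)), 10),
        row.names = FALSE)
  cat(sprintf("  winner: %s (best/second BF = %.3g)\n", x$winning_label,
              x$bf_best_over_second))
  invisible(x)
}

#' Decision-vs-confidence effect-difference model comparison
#'
#' For each group, forms the per-subject difference
#' \eqn{\Delta =} decision effect \eqn{-} confidence effect and compares all
#' 3^k sign-pattern models: per group the effect on decisions is larger than
#' on confidence (\code{dec_gt_conf}, \eqn{\Delta > 0}), smaller
#' (\code{conf_gt_dec}, \eqn{\Delta < 0}) or equal (\code{equal},
#' \eqn{\Delta = 0}, the group's null). Sign constraints are scored by the
#' encompassing-prior ratio against the group's null, equal constraints
#' contribute 1, and groups multiply.
#'
#' @param decision_effects,confidence_effects Named lists of per-subject
#'   effect vectors, paired within subject (same order and length per group).
#' @param r Cauchy prior scale.
#' @return A \code{model_comparison}; model labels are pattern strings such
#'   as \code{"ml:dec>conf|ba:equal"}.
#' @export
task_difference_models <- function(decision_effects, confidence_effects,
                                   r = sqrt(2) / 2) {
  groups <- names(decision_effects)
  if (!identical(sort(groups), sort(names(confidence_effects))))
    stop("decision and confidence effect lists must cover the same groups",
         call. = FALSE)
  deltas <- lapply(groups, function(g) {
    d <- decision_effects[[g]]; cf <- confidence_effects[[g]]
    if (length(d) != length(cf))
      stop("unpaired decision/confidence effects in group ", g, call. = FALSE)
    d - cf
  })
  names(deltas) <- groups

  bf_pos <- vapply(deltas, function(x)
    group_effect_bf(x, r = r)$bf_positive_vs_null, numeric(1))
  bf_neg <- vapply(deltas, function(x)
    group_effect_bf(-x, r = r)$bf_positive_vs_null, numeric(1))

  states <- c("dec_gt_conf", "conf_gt_dec", "equal")
  combos <- expand.grid(rep(list(states), length(groups)),
                        stringsAsFactors = FALSE)
  names(combos) <- groups
  models <- lapply(seq_len(nrow(combos)), function(i) {
    constraints <- unlist(combos[i, , drop = TRUE])
    names(constraints) <- groups
    lab <- paste(groups, c(dec_gt_conf = "dec>conf", conf_gt_dec = "conf>dec",
                           equal = "equal")[constraints],
                 sep = ":", collapse = "|")
    structure(list(label = lab, constraints = constraints),
              class = "constraint_model")
  })
  bf <- vapply(models, function(m) {
    prod(vapply(groups, function(g) {
      switch(m$constraints[[g]],
             dec_gt_conf = bf_pos[[g]],
             conf_gt_dec = bf_neg[[g]],
             equal = 1)
    }, numeric(1)))
  }, numeric(1))
  finish_comparison(models, bf)
}
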