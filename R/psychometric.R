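#' @keywords internal
new_psychometric_fit <- function(curve_kind, coefficients, landmark, p_value,
                                 quality_pass, extrapolated = FALSE,
                                 n_trials = NA_integer_) {
  structure(
    list(curve_kind = curve_kind,
         coefficients = coefficients,
         landmark = landmark,
         slope_or_shape_p_value = p_value,
         quality_pass = quality_pass,
         landmark_extrapolated = extrapolated,
         n_trials = n_trials),
    class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit> %s\n", x$curve_kind))
  cat("  coefficients:", paste(signif(x$coefficients, 6), collapse = ", "), "\n")
  cat(sprintf("  landmark: %s px  (p = %.4g, quality_pass = %s%s)\n",
              ifelse(is.na(x$landmark), "NA", sprintf("%.2f", x$landmark)),
              x$slope_or_shape_p_value, x$quality_pass,
              if (isTRUE(x$landmark_extrapolated)) ", extrapolated" else ""))
  invisible(x)
}

#' Fit the decision psychometric curve and interpolate the PSE
#'
#' Maximum-likelihood probit (cumulative Gaussian) fit of the probability of
#' answering "long" against target length, from trial-level Bernoulli
#' responses. The landmark is the point of subjective equality (PSE), the
#' target length at which P("long") = P("short") = 0.5, obtained
#' analytically as -intercept/slope. The fit fails the quality screen
#' (without raising an error) when the slope is negative or not
#' significantly different from zero (Wald two-sided test at \code{alpha}),
#' which also covers degenerate inputs such as all-identical responses or
#' complete separation.
#'
#' @param trials Decision-task trial records for one subject and condition
#'   (must contain \code{target_length} and \code{response}).
#' @param alpha Significance level of the slope screen.
#' @return A \code{psychometric_fit} with \code{curve_kind}
#'   \code{"decision_probit"}; coefficients are (intercept, slope) on the
#'   probit scale.
#' @export
fit_decision <- function(trials, alpha = 0.05) {
  tr <- trials[trials$task == "decision" & !is.na(trials$response), ,
               drop = FALSE]
  if (length(unique(tr$target_length)) < 2L)
    stop("fit_decision needs >= 2 distinct target lengths", call. = FALSE)
  agg <- stats::aggregate(
    list(n_long = as.integer(tr$response == "long"),
         n = rep(1L, nrow(tr))),
    by = list(target_length = tr$target_length), FUN = sum)
  if (all(agg$n_long == 0L) || all(agg$n_long == agg$n))
    return(new_psychometric_fit("decision_probit", c(NA_real_, NA_real_),
                                NA_real_, 1, FALSE, n_trials = nrow(tr)))
  fit <- suppressWarnings(
    stats::glm(cbind(n_long, n - n_long) ~ target_length,
               family = stats::binomial(link = "probit"), data = agg))
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  slope <- co[[2]]
  p <- 2 * stats::pnorm(-abs(slope / se[[2]]))
  ok <- is.finite(p) && p < alpha && slope > 0
  pse <- if (is.finite(slope) && slope != 0) -co[[1]] / slope else NA_real_
  new_psychometric_fit("decision_probit", unname(co),
                       if (ok) pse else ifelse(is.finite(pse), pse, NA_real_),
                       p, ok,
                       extrapolated = isTRUE(is.finite(pse) && (pse < 340 || pse > 460)),
                       n_trials = nrow(tr))
}

#' Fit the confidence curve and interpolate the point of maximal uncertainty
#'
#' Ordinary least squares of the per-target-length proportion of "high"
#' confidence responses on target length and its square. The landmark is the
#' vertex \eqn{-b/(2a)} of the fitted parabola
#' \eqn{a x^2 + b x + c}: the target length eliciting the least confidence.
#' Quality requires an upward-opening parabola (\eqn{a > 0}) with the
#' quadratic coefficient significant at \code{alpha}. Vertices outside the
#' 340--460 px window are flagged as extrapolated (quality unchanged).
#'
#' @param trials Decision-task trial records with confidence for one subject
#'   and condition.
#' @param alpha Significance level of the curvature screen.
#' @return A \code{psychometric_fit} with \code{curve_kind}
#'   \code{"confidence_quadratic"}; coefficients are (a, b, c).
#' @export
fit_confidence <- function(trials, alpha = 0.05) {
  tr <- trials[trials$task == "decision" & !is.na(trials$confidence), ,
               drop = FALSE]
  lens <- unique(tr$target_length)
  if (length(lens) < 3L)
    stop("fit_confidence needs >= 3 distinct target lengths", call. = FALSE)
  agg <- stats::aggregate(list(p_high = tr$confidence == "high"),
                          by = list(target_length = tr$target_length),
                          FUN = mean)
  x <- agg$target_length
  fit <- stats::lm(p_high ~ x + I(x^2), data = agg)
  co <- stats::coef(fit)
  a <- co[[3]]; b <- co[[2]]
  sm <- summary(fit)$coefficients
  p <- if (nrow(sm) >= 3L && is.finite(sm[3, 4])) sm[3, 4] else
    as.numeric(!is.finite(a) || a <= 0)  # exact fits: sign rule decides
  ok <- is.finite(a) && a > 0 && p < alpha
  vertex <- if (is.finite(a) && a != 0) -b / (2 * a) else NA_real_
  new_psychometric_fit("confidence_quadratic", c(a = a, b = b, c = co[[1]]),
                       vertex, p, ok,
                       extrapolated = isTRUE(is.finite(vertex) &&
                                               (vertex < 340 || vertex > 460)),
                       n_trials = nrow(tr))
}

#' Fit the reproduction line and interpolate the reference match point
#'
#' Ordinary least squares of reproduced length on target length
#' (trial-level). The landmark is the target length whose predicted
#' reproduction equals the reference line:
#' \eqn{(400 - \hat\alpha)/\hat\beta}. Quality requires a positive and
#' significant slope.
#'
#' @param trials Reproduction-task trial records for one subject and
#'   condition.
#' @param reference Reference length in px.
#' @param alpha Significance level of the slope screen.
#' @return A \code{psychometric_fit} with \code{curve_kind}
#'   \code{"reproduction_linear"}; coefficients are (intercept, slope).
#' @export
fit_reproduction <- function(trials, reference = 400, alpha = 0.05) {
  tr <- trials[trials$task == "reproduction" & !is.na(trials$reproduced_length), ,
               drop = FALSE]
  if (length(unique(tr$target_length)) < 2L)
    stop("fit_reproduction needs >= 2 distinct target lengths", call. = FALSE)
  fit <- stats::lm(reproduced_length ~ target_length, data = tr)
  co <- stats::coef(fit)
  sm <- summary(fit)$coefficients
  beta <- co[[2]]
  # exact fits have zero residual variance and an undefined t-test; treat a
  # positive slope as passing in that case
  p <- if (is.finite(sm[2, 4])) sm[2, 4] else as.numeric(beta <= 0)
  ok <- is.finite(beta) && beta > 0 && p < alpha
  lm_pt <- if (is.finite(beta) && beta != 0) (reference - co[[1]]) / beta else NA_real_
  new_psychometric_fit("reproduction_linear", unname(co), lm_pt, p, ok,
                       extrapolated = isTRUE(is.finite(lm_pt) &&
                                               (lm_pt < 340 || lm_pt > 460)),
                       n_trials = nrow(tr))
}

#' Landmark effect between bias directions
#'
#' Signed difference between the landmarks fitted in the biased-to-short and
#' biased-to-long conditions, \code{landmark(short) - landmark(long)}. With
#' this convention a positive effect means behavior shifted toward the
#' biased direction (biasing toward "long" moves a landmark to shorter
#' target lengths).
#'
#' @param fit_long,fit_short \code{psychometric_fit} objects of the same
#'   curve kind from the two bias directions.
#' @return Signed effect in px.
#' @export
landmark_effect <- function(fit_long, fit_short) {
  stopifnot(inherits(fit_long, "psychometric_fit"),
            inherits(fit_short, "psychometric_fit"))
  if (fit_long$curve_kind != fit_short$curve_kind)
    stop("landmark_effect: curve kinds differ", call. = FALSE)
  if (!isTRUE(fit_long$quality_pass) || !isTRUE(fit_short$quality_pass))
    stop("landmark_effect: both fits must pass the quality screen",
         call. = FALSE)
  fit_short$landmark - fit_long$landmark
}

#' Fit all three curves for every subject x direction in a trial table
#'
#' Convenience wrapper that runs [fit_decision()], [fit_confidence()] and
#' [fit_reproduction()] per subject and bias direction and returns a tidy
#' fit table.
#'
#' @param trials A trial-record data.frame (possibly several groups).
#' @return A data.frame with one row per subject x direction x curve kind:
#'   subject, group, direction, curve kind, landmark, p-value, quality flag.
#' @export
fit_cohort <- function(trials) {
  parts <- split(trials, list(trials$subject_id, trials$bias_direction),
                 drop = TRUE)
  rows <- lapply(parts, function(sub) {
    fits <- list(decision = fit_decision(sub),
                 confidence = fit_confidence(sub),
                 reproduction = fit_reproduction(sub))
    data.frame(
      subject_id = sub$subject_id[1],
      bias_source = sub$bias_source[1],
      bias_direction = sub$bias_direction[1],
      curve = names(fits),
      landmark = vapply(fits, `[[`, numeric(1), "landmark"),
      p_value = vapply(fits, `[[`, numeric(1), "slope_or_shape_p_value"),
      quality_pass = vapply(fits, `[[`, logical(1), "quality_pass"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-subject landmark effects from a cohort fit table
#'
#' Pairs the biased-to-long and biased-to-short fits of each subject and
#' curve kind and computes \code{landmark(short) - landmark(long)}. Subjects
#' failing the quality screen in either direction are dropped for that curve
#' kind (the study's fit-quality exclusion).
#'
#' @param fit_table Output of [fit_cohort()].
#' @return A data.frame with columns \code{subject_id}, \code{bias_source},
#'   \code{curve}, \code{effect_px}.
#' @export
landmark_effects <- function(fit_table) {
  wide <- merge(
    fit_table[fit_table$bias_direction == "long",
              c("subject_id", "bias_source", "curve", "landmark", "quality_pass")],
    fit_table[fit_table$bias_direction == "short",
              c("subject_id", "bias_source", "curve", "landmark", "quality_pass")],
    by = c("subject_id", "bias_source", "curve"),
    suffixes = c("_long", "_short"))
  keep <- wide$quality_pass_long & wide$quality_pass_short &
    is.finite(wide$landmark_long) & is.finite(wide$landmark_short)
  out <- wide[keep, c("subject_id", "bias_source", "curve")]
  out$effect_px <- wide$landmark_short[keep] - wide$landmark_long[keep]
  out[order(out$bias_source, out$curve, out$subject_id), ]
}
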