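# Independent oracle implementations used to validate the main code paths.
# Each oracle deliberately avoids the primitives it checks: the inverse
# normal is a rational approximation (not qnorm), the JZS quadrature uses
# the inverse-gamma g-mixture form with a hand-rolled adaptive Simpson rule
# (not the Cauchy-on-delta form with stats::integrate), and the meta-d'
# oracle is an exhaustive grid search (not a simplex optimizer).

#' Inverse standard-normal CDF by rational approximation
#'
#' Acklam's rational approximation (absolute error below 1.2e-9 across
#' (0, 1)). Used as the independent oracle for d'/criterion computations.
#'
#' @param p Probabilities in (0, 1).
#' @return Normal quantiles.
#' @export
oracle_inverse_normal <- function(p) {
  a <- c(-3.969683028665376e+01, 2.209460984245205e+02,
         -2.759285104469687e+02, 1.383577518672690e+02,
         -3.066479806614716e+01, 2.506628277459239e+00)
  b <- c(-5.447609879822406e+01, 1.615858368580409e+02,
         -1.556989798598866e+02, 6.680131188771972e+01,
         -1.328068155288572e+01)
  cc <- c(-7.784894002430293e-03, -3.223964580411365e-01,
          -2.400758277161838e+00, -2.549732539343734e+00,
          4.374664141464968e+00, 2.938163982698783e+00)
  d <- c(7.784695709041462e-03, 3.224671290700398e-01,
         2.445134137142996e+00, 3.754408661907416e+00)
  p_low <- 0.02425
  x <- numeric(length(p))
  lo <- p < p_low
  hi <- p > 1 - p_low
  mid <- !lo & !hi
  if (any(mid)) {
    q <- p[mid] - 0.5
    r <- q * q
    x[mid] <- (((((a[1] * r + a[2]) * r + a[3]) * r + a[4]) * r + a[5]) * r + a[6]) * q /
      (((((b[1] * r + b[2]) * r + b[3]) * r + b[4]) * r + b[5]) * r + 1)
  }
  if (any(lo)) {
    q <- sqrt(-2 * log(p[lo]))
    x[lo] <- (((((cc[1] * q + cc[2]) * q + cc[3]) * q + cc[4]) * q + cc[5]) * q + cc[6]) /
      ((((d[1] * q + d[2]) * q + d[3]) * q + d[4]) * q + 1)
  }
  if (any(hi)) {
    q <- sqrt(-2 * log(1 - p[hi]))
    x[hi] <- -(((((cc[1] * q + cc[2]) * q + cc[3]) * q + cc[4]) * q + cc[5]) * q + cc[6]) /
      ((((d[1] * q + d[2]) * q + d[3]) * q + d[4]) * q + 1)
  }
  x
}

#' Adaptive Simpson quadrature
#'
#' Plain recursive adaptive Simpson integration on a finite interval; the
#' brute-force integrator behind [oracle_jzs_bf()].
#'
#' @param f Integrand (vectorized or scalar).
#' @param a,b Interval ends.
#' @param tol Absolute tolerance.
#' @param max_depth Recursion cap.
#' @return The integral estimate.
#' @export
simpson_adaptive <- function(f, a, b, tol = 1e-10, max_depth = 60L) {
  simp <- function(fa, fm, fb, a, b) (b - a) / 6 * (fa + 4 * fm + fb)
  rec <- function(a, b, fa, fm, fb, whole, tol, depth) {
    m <- (a + b) / 2
    lm <- (a + m) / 2; rm <- (m + b) / 2
    flm <- f(lm); frm <- f(rm)
    left <- simp(fa, flm, fm, a, m)
    right <- simp(fm, frm, fb, m, b)
    if (depth <= 0L || abs(left + right - whole) <= 15 * tol)
      return(left + right + (left + right - whole) / 15)
    rec(a, m, fa, flm, fm, left, tol / 2, depth - 1L) +
      rec(m, b, fm, frm, fb, right, tol / 2, depth - 1L)
  }
  m <- (a + b) / 2
  fa <- f(a); fm <- f(m); fb <- f(b)
  rec(a, b, fa, fm, fb, simp(fa, fm, fb, a, b), tol, max_depth)
}

#' Brute-force JZS Bayes factor (g-mixture form)
#'
#' Independent quadrature oracle for the two-sided JZS BF10: integrates the
#' Zellner-Siow representation, in which the Cauchy prior on the
#' standardized effect is an inverse-gamma(1/2, r^2/2) scale mixture of
#' normals, over the mixing variable g (mapped to (0, 1) via
#' g = u/(1 - u)), using [simpson_adaptive()].
#'
#' @param t Observed t statistic.
#' @param n Sample size.
#' @param r Cauchy prior scale.
#' @param tol Quadrature tolerance.
#' @return The two-sided BF10.
#' @export
oracle_jzs_bf <- function(t, n, r = sqrt(2) / 2, tol = 1e-12) {
  nu <- n - 1
  integrand <- function(u) {
    g <- u / (1 - u)
    jac <- 1 / (1 - u)^2
    val <- (1 + n * g)^(-0.5) *
      (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2) *
      r / sqrt(2 * pi) * g^(-1.5) * exp(-r^2 / (2 * g)) * jac
    if (!is.finite(val)) 0 else val
  }
  num <- simpson_adaptive(integrand, 1e-12, 1 - 1e-12, tol = tol)
  num / (1 + t^2 / nu)^(-(nu + 1) / 2)
}

#' Brute-force meta-d' grid search
#'
#' Exhaustive grid oracle for [fit_meta_d()]: for every meta-d' value on a
#' regular grid the two type-2 criteria decouple across response sides, so
#' each side's criterion is grid-searched independently and the best joint
#' log-likelihood is returned.
#'
#' @param counts A \code{type2_counts} object or 2x2x2 array (edge-corrected
#'   the same way as the fit under test).
#' @param meta_d_range Range of meta-d' values searched.
#' @param resolution Grid step for meta-d' and the criteria.
#' @param crit_halfwidth Half-width of the criterion offset grids.
#' @param refine If TRUE (default), a second exhaustive pass at
#'   \code{resolution/100} around the coarse optimum removes the grid
#'   discretization error from the reported maximum (the refinement is still
#'   a pure grid evaluation, never an optimizer).
#' @return List with \code{meta_d}, \code{c2_short}, \code{c2_long},
#'   \code{log_lik}.
#' @export
oracle_metad_grid <- function(counts, meta_d_range = c(-1, 5),
                              resolution = 0.01, crit_halfwidth = 5,
                              refine = TRUE) {
  arr <- if (inherits(counts, "type2_counts")) counts$counts else counts
  if (any(arr == 0)) arr <- arr + 0.5
  t1 <- metad_type1(arr)
  c_prime <- t1$c1 / t1$d_prime

  pass <- function(md_grid, off_grid_s, off_grid_l) grid_pass(
    arr, c_prime, md_grid, off_grid_s, off_grid_l)

  md_grid <- seq(meta_d_range[1], meta_d_range[2], by = resolution)
  off_grid <- seq(resolution, crit_halfwidth, by = resolution)
  best <- pass(md_grid, off_grid, off_grid)
  if (refine) {
    res2 <- resolution / 100
    md2 <- seq(best$meta_d - resolution, best$meta_d + resolution, by = res2)
    mk_off <- function(off) seq(max(off - resolution, res2),
                                off + resolution, by = res2)
    best <- pass(md2,
                 mk_off(c_prime * best$meta_d - best$c2_short),
                 mk_off(best$c2_long - c_prime * best$meta_d))
  }
  best
}

#' @keywords internal
grid_pass <- function(arr, c_prime, md_grid, off_grid_s, off_grid_l) {
  clamp <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)
  best <- list(log_lik = -Inf)
  for (md in md_grid) {
    mc1 <- c_prime * md
    mu <- c(-md / 2, md / 2)
    p_rs <- stats::pnorm(mc1 - mu)       # P(resp short | stim)
    p_rl <- 1 - p_rs
    # short-response side: c2s = mc1 - off
    ph_s <- outer(mu, off_grid_s, function(m, o) stats::pnorm(mc1 - o - m))
    ll_s <- colSums(
      arr[, "short", "high"] * log(clamp(ph_s / p_rs)) +
        arr[, "short", "low"] * log(clamp(1 - ph_s / p_rs)))
    # long-response side: c2l = mc1 + off
    ph_l <- outer(mu, off_grid_l, function(m, o) 1 - stats::pnorm(mc1 + o - m))
    ll_l <- colSums(
      arr[, "long", "high"] * log(clamp(ph_l / p_rl)) +
        arr[, "long", "low"] * log(clamp(1 - ph_l / p_rl)))
    i_s <- which.max(ll_s); i_l <- which.max(ll_l)
    ll <- ll_s[i_s] + ll_l[i_l]
    if (ll > best$log_lik)
      best <- list(meta_d = md, c2_short = mc1 - off_grid_s[i_s],
                   c2_long = mc1 + off_grid_l[i_l], log_lik = ll)
  }
  best
}

#' Deterministic test fixtures
#'
#' Factory for the micro-fixtures and canonical observer settings used in
#' the test suite. Each fixture returns its input data together with an
#' \code{expected} map of assertion values.
#'
#' Available fixtures: \code{"design_counts"} (printed trial-count totals),
#' \code{"sdt_symmetric"} (HR = 1 - FAR, expected c = 0),
#' \code{"trials_micro"} (16 hand-written decision trials with hand-tallied
#' type-2 counts), \code{"ml_observer"}, \code{"base_rate_observer"},
#' \code{"payoff_observer"} (canonical generative settings with closed-form
#' landmarks), \code{"ideal_metacognition"} and \code{"noisy_metacognition"}
#' (observers with zero / positive metacognitive noise).
#'
#' @param name Fixture name.
#' @return A list with \code{input} and \code{expected}.
#' @export
make_fixture <- function(name) {
  switch(
    name,
    design_counts = list(
      input = list(ml = build_design("muller_lyer", "long"),
                   br = build_design("base_rate", "long"),
                   po = build_design("payoff", "short")),
      expected = list(ml_total = 420L, ml_decision = 280L,
                      ml_reproduction = 140L, br_decision = 390L,
                      br_reproduction = 195L, br_total = 585L,
                      po_penalty_long = 5L, po_penalty_short = 1L)),
    sdt_symmetric = list(
      input = list(HR = 0.8413447, FAR = 0.1586553),
      expected = list(criterion_c = 0, d_prime_approx = 2)),
    trials_micro = {
      tr <- data.frame(
        subject_id = "micro",
        bias_source = "muller_lyer", bias_direction = "long",
        task = "decision",
        target_length = c(370, 370, 380, 390, 410, 410, 420, 430,
                          370, 390, 410, 430, 400, 400, 420, 380),
        response = c("short", "short", "long", "short", "long", "short",
                     "long", "long", "short", "long", "long", "long",
                     "long", "short", "short", "short"),
        confidence = c("high", "low", "low", "high", "high", "low", "high",
                       "high", "high", "low", "low", "high", "low", "high",
                       "low", "high"),
        reproduced_length = NA_real_, correct = NA,
        stringsAsFactors = FALSE)
      tr$correct <- ifelse(tr$target_length == 400, NA,
                           (tr$target_length > 400) == (tr$response == "long"))
      # hand tally over the 14 non-reference trials:
      # stim short (370x3, 380x2, 390x2): resp short-high 4, short-low 1,
      #   long-low 2, long-high 0
      # stim long (410x3, 420x2, 430x2): resp short-high 0, short-low 2,
      #   long-low 1, long-high 4
      expected_counts <- array(
        0, dim = c(2, 2, 2),
        dimnames = list(stimulus = c("short", "long"),
                        response = c("short", "long"),
                        confidence = c("low", "high")))
      expected_counts["short", "short", "high"] <- 4
      expected_counts["short", "short", "low"] <- 1
      expected_counts["short", "long", "low"] <- 2
      expected_counts["short", "long", "high"] <- 0
      expected_counts["long", "short", "high"] <- 0
      expected_counts["long", "short", "low"] <- 2
      expected_counts["long", "long", "low"] <- 1
      expected_counts["long", "long", "high"] <- 4
      list(input = tr,
           expected = list(counts = expected_counts, n_used = 14L,
                           n_dropped_reference = 2L))
    },
    ml_observer = list(
      input = observer_params(perceptual_shift = 12),
      expected = list(pse = 388, vertex_center = 388, match = 388)),
    base_rate_observer = list(
      input = observer_params(decision_criterion_shift = -7,
                              confidence_center_shift = -3.5),
      expected = list(pse = 393, vertex_center = 396.5, match = 400)),
    payoff_observer = list(
      input = observer_params(decision_criterion_shift = -10,
                              confidence_center_shift = -5),
      expected = list(pse = 390, vertex_center = 395, match = 400)),
    ideal_metacognition = list(
      input = observer_params(metacognitive_noise_sd = 0),
      expected = list(m_ratio = 1, tolerance = 0.05)),
    noisy_metacognition = list(
      input = observer_params(metacognitive_noise_sd = 10),
      expected = list(m_ratio_below = 1)),
    stop("unknown fixture: ", name, call. = FALSE)
  )
}
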