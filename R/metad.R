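# Meta-d' for a binary-confidence two-choice design (Maniscalco & Lau style
# maximum likelihood). The meta-level observer shares the type-1 observer's
# relative criterion (c' = c/d' is preserved) and has one type-2 criterion
# per response side; meta-d' is the type-1 sensitivity this ideal observer
# would need to produce the observed confidence-accuracy mapping.

#' Tabulate type-2 counts from decision trials
#'
#' Builds the 2 (stimulus class: short/long) x 2 (response) x 2 (confidence)
#' count table used by [fit_meta_d()]. Trials at the reference length are
#' dropped (they belong to neither stimulus class).
#'
#' @param trials Decision trial records with confidence.
#' @param reference Reference length in px.
#' @return An object of class \code{type2_counts}: a named list of 3-d array
#'   \code{counts[stimulus, response, confidence]} plus \code{n_used} and
#'   \code{n_dropped_reference}.
#' @export
tabulate_type2 <- function(trials, reference = 400) {
  tr <- trials[trials$task == "decision" & !is.na(trials$response) &
                 !is.na(trials$confidence), , drop = FALSE]
  if (!nrow(tr)) stop("no decision trials with confidence", call. = FALSE)
  dropped <- sum(tr$target_length == reference)
  tr <- tr[tr$target_length != reference, , drop = FALSE]
  if (!nrow(tr)) stop("no classifiable trials (all at reference length)",
                      call. = FALSE)
  stim <- factor(ifelse(tr$target_length > reference, "long", "short"),
                 levels = c("short", "long"))
  resp <- factor(tr$response, levels = c("short", "long"))
  conf <- factor(tr$confidence, levels = c("low", "high"))
  counts <- table(stimulus = stim, response = resp, confidence = conf)
  structure(list(counts = unclass(counts), n_used = nrow(tr),
                 n_dropped_reference = dropped),
            class = "type2_counts")
}

#' @export
print.type2_counts <- function(x, ...) {
  cat(sprintf("<type2_counts> %d trials (%d reference-length trials dropped)\n",
              x$n_used, x$n_dropped_reference))
  print(x$counts)
  invisible(x)
}

#' @keywords internal
metad_type1 <- function(counts) {
  # counts: array [stimulus, response, confidence]
  n_long_S2 <- sum(counts["long", "long", ])
  n_S2 <- sum(counts["long", , ])
  n_long_S1 <- sum(counts["short", "long", ])
  n_S1 <- sum(counts["short", , ])
  hr <- n_long_S2 / n_S2
  far <- n_long_S1 / n_S1
  zh <- stats::qnorm(hr); zf <- stats::qnorm(far)
  list(d_prime = zh - zf, criterion_c = 0.5 * (zh + zf),
       # decision-axis location of the type-1 criterion (stimulus means at
       # -d'/2 and +d'/2); the reported criterion c is its mirror image
       c1 = -0.5 * (zh + zf))
}

#' @keywords internal
metad_condprob <- function(meta_d, c2_short, c2_long, meta_c1) {
  # conditional confidence probabilities given stimulus and response
  mu <- c(short = -meta_d / 2, long = meta_d / 2)
  out <- array(NA_real_, dim = c(2, 2, 2),
               dimnames = list(stimulus = c("short", "long"),
                               response = c("short", "long"),
                               confidence = c("low", "high")))
  for (s in c("short", "long")) {
    p_resp_short <- stats::pnorm(meta_c1 - mu[[s]])
    p_resp_long <- 1 - p_resp_short
    p_high_short <- stats::pnorm(c2_short - mu[[s]])
    p_high_long <- 1 - stats::pnorm(c2_long - mu[[s]])
    out[s, "short", "high"] <- p_high_short / p_resp_short
    out[s, "short", "low"] <- 1 - out[s, "short", "high"]
    out[s, "long", "high"] <- p_high_long / p_resp_long
    out[s, "long", "low"] <- 1 - out[s, "long", "high"]
  }
  out
}

#' @keywords internal
metad_loglik <- function(meta_d, c2_short, c2_long, counts, c_prime) {
  meta_c1 <- c_prime * meta_d
  if (!(c2_short <= meta_c1 && meta_c1 <= c2_long)) return(-Inf)
  p <- metad_condprob(meta_d, c2_short, c2_long, meta_c1)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(counts * log(p))
}

#' Maximum-likelihood meta-d' and M-ratio
#'
#' Computes type-1 d' and criterion from the count table (after edge
#' correction), then finds the meta-level sensitivity meta-d' and one type-2
#' criterion per response side maximizing the likelihood of the confidence
#' counts conditional on stimulus and response, holding the meta observer's
#' relative criterion fixed at c' = c/d'. M-ratio is meta-d'/d' (1 = ideal
#' metacognition).
#'
#' @param counts A \code{type2_counts} object (or the bare 2x2x2 array).
#' @param edge_correction If TRUE (default) add 0.5 to every cell when any
#'   cell is zero.
#' @return An object of class \code{meta_d_result}: list with
#'   \code{d_prime}, \code{type1_criterion}, \code{meta_d}, \code{m_ratio},
#'   \code{log_m_ratio}, \code{type2_criteria} (short/long sides),
#'   \code{fit_log_likelihood}, \code{converged}.
#' @export
fit_meta_d <- function(counts, edge_correction = TRUE) {
  arr <- if (inherits(counts, "type2_counts")) counts$counts else counts
  stopifnot(length(dim(arr)) == 3L, all(dim(arr) == 2L))
  if (edge_correction && any(arr == 0)) arr <- arr + 0.5
  t1 <- metad_type1(arr)
  d <- t1$d_prime
  if (!is.finite(d) || d == 0)
    stop("type-1 d' is zero or undefined; meta-d' not identifiable",
         call. = FALSE)
  c_prime <- t1$c1 / d

  # parametrization enforcing c2_short <= meta_c1 <= c2_long
  nll <- function(par) {
    meta_d <- par[1]
    meta_c1 <- c_prime * meta_d
    ll <- metad_loglik(meta_d, meta_c1 - exp(par[2]), meta_c1 + exp(par[3]),
                       arr, c_prime)
    -ll
  }
  init <- c(d, log(0.5), log(0.5))
  opt <- stats::optim(init, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  # polish with a second start at a conservative point if needed
  opt2 <- stats::optim(c(0.5 * d, log(0.25), log(0.25)), nll,
                       method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-10))
  if (opt2$value < opt$value) opt <- opt2
  meta_d <- opt$par[1]
  meta_c1 <- c_prime * meta_d
  structure(
    list(d_prime = d,
         type1_criterion = t1$criterion_c,
         meta_d = meta_d,
         m_ratio = meta_d / d,
         log_m_ratio = if (meta_d / d > 0) log(meta_d / d) else NA_real_,
         type2_criteria = c(short = meta_c1 - exp(opt$par[2]),
                            long = meta_c1 + exp(opt$par[3])),
         fit_log_likelihood = -opt$value,
         converged = opt$convergence == 0),
    class = "meta_d_result")
}

#' @export
print.meta_d_result <- function(x, ...) {
  cat(sprintf("<meta_d_result> d' = %.3f, meta-d' = %.3f, M-ratio = %.3f (logLik %.2f)\n",
              x$d_prime, x$meta_d, x$m_ratio, x$fit_log_likelihood))
  invisible(x)
}

#' Group-level posterior for mean M-ratio
#'
#' Simplified group model: per-subject log M-ratio is given a Normal
#' likelihood with unknown group mean and SD, a Normal(0, 5^2) prior on the
#' mean and a half-Cauchy(0, 1) prior on the SD, sampled by random-walk
#' Metropolis with 4 chains of 20,000 iterations, a thinning interval of 2
#' and the first quarter of each chain discarded as warmup (during which the
#' proposal scale adapts). Convergence requires the potential scale
#' reduction statistic of the group mean to be below 1.02.
#'
#' Subjects with non-positive M-ratio (undefined log) are excluded with a
#' warning.
#'
#' @param metad_results List of \code{meta_d_result} objects, or a numeric
#'   vector of per-subject M-ratios.
#' @param seed Integer seed.
#' @param n_iter,n_chains,thin Sampler settings.
#' @return An object of class \code{mratio_posterior}: list with
#'   \code{draws_mean_log_mratio}, \code{draws_mean_mratio} (exp of the
#'   former), \code{rhat}, \code{converged}, \code{subject_log_mratio},
#'   \code{n_excluded}.
#' @export
group_mratio_posterior <- function(metad_results, seed = 1L,
                                   n_iter = 20000L, n_chains = 4L,
                                   thin = 2L) {
  m <- if (is.numeric(metad_results)) metad_results else
    vapply(metad_results, `[[`, numeric(1), "m_ratio")
  bad <- !is.finite(m) | m <= 0
  if (any(bad))
    warning(sum(bad), " subject(s) with non-positive M-ratio excluded from the group model")
  y <- log(m[!bad])
  if (length(y) < 5L)
    stop("group_mratio_posterior needs >= 5 subjects with positive M-ratio",
         call. = FALSE)

  log_post <- function(mu, log_sigma) {
    sigma <- exp(log_sigma)
    sum(stats::dnorm(y, mu, sigma, log = TRUE)) +
      stats::dnorm(mu, 0, 5, log = TRUE) +
      stats::dcauchy(sigma, 0, 1, log = TRUE) + log(2) +
      log_sigma  # Jacobian of the log transform
  }

  set.seed(as.integer(seed))
  warmup <- n_iter %/% 4L
  keep_idx <- seq(warmup + 1L, n_iter, by = thin)
  draws <- matrix(NA_real_, length(keep_idx), n_chains)
  for (ch in seq_len(n_chains)) {
    mu <- mean(y) + stats::rnorm(1, 0, stats::sd(y))
    ls <- log(stats::sd(y)) + stats::rnorm(1, 0, 0.5)
    lp <- log_post(mu, ls)
    step <- c(stats::sd(y) / sqrt(length(y)) * 2.4, 0.35)
    acc <- 0L
    kk <- 0L
    for (it in seq_len(n_iter)) {
      prop_mu <- mu + stats::rnorm(1, 0, step[1])
      prop_ls <- ls + stats::rnorm(1, 0, step[2])
      lp_prop <- log_post(prop_mu, prop_ls)
      if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
        mu <- prop_mu; ls <- prop_ls; lp <- lp_prop; acc <- acc + 1L
      }
      if (it <= warmup && it %% 500L == 0L) {
        rate <- acc / it
        step <- step * exp(rate - 0.30)  # aim near the RW optimum
      }
      if (it > warmup && (it - warmup - 1L) %% thin == 0L) {
        kk <- kk + 1L
        draws[kk, ch] <- mu
      }
    }
  }
  rh <- rhat(draws)
  structure(
    list(draws_mean_log_mratio = as.vector(draws),
         draws_mean_mratio = exp(as.vector(draws)),
         rhat = rh,
         converged = is.finite(rh) && rh < 1.02,
         subject_log_mratio = y,
         n_excluded = sum(bad)),
    class = "mratio_posterior")
}

#' @export
print.mratio_posterior <- function(x, ...) {
  cat(sprintf("<mratio_posterior> mean M-ratio %.3f [%.3f, %.3f], R-hat %.4f (%s)\n",
              mean(x$draws_mean_mratio),
              stats::quantile(x$draws_mean_mratio, 0.025),
              stats::quantile(x$draws_mean_mratio, 0.975),
              x$rhat, if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Potential scale reduction statistic (split chains)
#'
#' @param draws Matrix of posterior draws, one column per chain.
#' @return The split-chain R-hat.
#' @export
rhat <- function(draws) {
  n <- nrow(draws) %/% 2L
  halves <- cbind(draws[seq_len(n), , drop = FALSE],
                  draws[seq_len(n) + n, , drop = FALSE])
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Bayes factor for an M-ratio difference between bias directions
#'
#' Forms posterior draws of the standardized difference in group mean log
#' M-ratio between the biased-to-long and biased-to-short conditions
#' (difference of group-mean draws divided by the pooled subject-level SD of
#' log M-ratio, a Cohen's d scale) and applies the Savage-Dickey density
#' ratio with a Cauchy(0, r) prior. Set \code{scale = "raw"} to standardize
#' the difference in mean M-ratio instead.
#'
#' @param posterior_long,posterior_short \code{mratio_posterior} objects.
#' @param r Cauchy prior scale.
#' @param scale \code{"log"} (default) or \code{"raw"}.
#' @return A \code{savage_dickey_result} with an extra element
#'   \code{effect_size_draws}.
#' @export
mratio_difference_bf <- function(posterior_long, posterior_short,
                                 r = sqrt(2) / 2, scale = c("log", "raw")) {
  scale <- match.arg(scale)
  if (scale == "log") {
    dl <- posterior_long$draws_mean_log_mratio
    ds <- posterior_short$draws_mean_log_mratio
    yl <- posterior_long$subject_log_mratio
    ys <- posterior_short$subject_log_mratio
  } else {
    dl <- posterior_long$draws_mean_mratio
    ds <- posterior_short$draws_mean_mratio
    yl <- exp(posterior_long$subject_log_mratio)
    ys <- exp(posterior_short$subject_log_mratio)
  }
  n <- min(length(dl), length(ds))
  sd_pooled <- sqrt(((length(yl) - 1) * stats::var(yl) +
                       (length(ys) - 1) * stats::var(ys)) /
                      (length(yl) + length(ys) - 2))
  d_draws <- (dl[seq_len(n)] - ds[seq_len(n)]) / sd_pooled
  out <- savage_dickey(d_draws, prior_scale = r,
                       theta_label = paste0("mratio_diff_", scale))
  out$effect_size_draws <- d_draws
  out
}
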