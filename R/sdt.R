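#' Signal-detection sensitivity and criterion
#'
#' Computes hit rate, false-alarm rate, d' and criterion c from decision
#' trials. Correct "long" responses are hits and correct "short" responses
#' correct rejections, so targets longer than the reference are the signal
#' class. Trials at the reference length are excluded (they belong to
#' neither class). Rates of exactly 0 or 1 are edge-corrected to
#' \eqn{1/(2N)} and \eqn{1 - 1/(2N)} with \eqn{N} the trial count of that
#' class. Formulas: \eqn{d' = Z(HR) - Z(FAR)} and
#' \eqn{c = \frac{1}{2}(Z(HR) + Z(FAR))} with \eqn{Z} the standard-normal
#' quantile function, so c = 0 whenever HR = 1 - FAR.
#'
#' @param trials Decision trial records (columns \code{target_length},
#'   \code{response}).
#' @param reference Reference length in px.
#' @return An object of class \code{sdt_measures}: list with
#'   \code{n_signal}, \code{n_noise}, \code{HR}, \code{FAR}, \code{d_prime},
#'   \code{criterion_c}.
#' @export
sdt_measures <- function(trials, reference = 400) {
  tr <- trials[trials$task == "decision" & !is.na(trials$response) &
                 trials$target_length != reference, , drop = FALSE]
  sig <- tr$target_length > reference
  n_signal <- sum(sig)
  n_noise <- sum(!sig)
  if (n_signal == 0L || n_noise == 0L)
    stop("sdt_measures: need at least one long-target and one short-target trial",
         call. = FALSE)
  hr <- sum(tr$response[sig] == "long") / n_signal
  far <- sum(tr$response[!sig] == "long") / n_noise
  hr <- min(max(hr, 1 / (2 * n_signal)), 1 - 1 / (2 * n_signal))
  far <- min(max(far, 1 / (2 * n_noise)), 1 - 1 / (2 * n_noise))
  sdt_from_rates(hr, far, n_signal, n_noise)
}

#' @rdname sdt_measures
#' @param HR,FAR Edge-corrected rates in (0, 1).
#' @param n_signal,n_noise Class trial counts (bookkeeping only).
#' @export
sdt_from_rates <- function(HR, FAR, n_signal = NA_integer_,
                           n_noise = NA_integer_) {
  stopifnot(HR > 0, HR < 1, FAR > 0, FAR < 1)
  zh <- stats::qnorm(HR)
  zf <- stats::qnorm(FAR)
  structure(
    list(n_signal = n_signal, n_noise = n_noise, HR = HR, FAR = FAR,
         d_prime = zh - zf, criterion_c = 0.5 * (zh + zf)),
    class = "sdt_measures")
}

#' @export
print.sdt_measures <- function(x, ...) {
  cat(sprintf("<sdt_measures> HR = %.3f, FAR = %.3f, d' = %.3f, c = %.3f\n",
              x$HR, x$FAR, x$d_prime, x$criterion_c))
  invisible(x)
}

#' Participant screening
#'
#' Applies the study's participant exclusion rules to a per-subject measure
#' table: a subject is excluded when their criterion, d' or mean absolute
#' reproduction error falls outside four standard deviations from the grand
#' sample mean (pooled across bias-source groups), or when their d' is below
#' zero. When a measure has zero variance across the sample, that measure
#' excludes nobody.
#'
#' @param measures A data.frame with one row per subject and columns
#'   \code{subject_id}, \code{d_prime}, \code{criterion_c},
#'   \code{reproduction_error} (mean absolute error in px; may be NA to skip
#'   that screen for all subjects).
#' @param n_sd Width of the outlier band in standard deviations.
#' @return A list with \code{kept} (character vector of subject ids),
#'   \code{excluded} (data.frame with \code{subject_id} and \code{reason};
#'   one row per violated rule).
#' @export
screen_participants <- function(measures, n_sd = 4) {
  stopifnot(nrow(measures) >= 2L)
  reasons <- list()
  flag_outliers <- function(x, label) {
    if (all(is.na(x))) return(invisible(NULL))
    m <- mean(x, na.rm = TRUE)
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) return(invisible(NULL))
    bad <- which(!is.na(x) & abs(x - m) > n_sd * s)
    for (i in bad)
      reasons[[length(reasons) + 1L]] <<- data.frame(
        subject_id = measures$subject_id[i], reason = label,
        stringsAsFactors = FALSE)
    invisible(NULL)
  }
  flag_outliers(measures$criterion_c, "criterion_outlier")
  flag_outliers(measures$d_prime, "dprime_outlier")
  if ("reproduction_error" %in% names(measures))
    flag_outliers(measures$reproduction_error, "reproduction_error_outlier")
  neg <- which(!is.na(measures$d_prime) & measures$d_prime < 0)
  for (i in neg)
    reasons[[length(reasons) + 1L]] <- data.frame(
      subject_id = measures$subject_id[i], reason = "negative_dprime",
      stringsAsFactors = FALSE)
  excluded <- if (length(reasons)) do.call(rbind, reasons) else
    data.frame(subject_id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  list(kept = setdiff(measures$subject_id, unique(excluded$subject_id)),
       excluded = excluded)
}

#' Per-subject screening measures from a trial table
#'
#' Pools both bias directions per subject (the outlier screen operates on the
#' grand sample) and returns d', criterion and the mean absolute reproduction
#' error used by [screen_participants()].
#'
#' @param trials A trial-record data.frame.
#' @return A data.frame with one row per subject.
#' @export
subject_measures <- function(trials) {
  ids <- unique(trials$subject_id)
  out <- lapply(ids, function(sid) {
    sub <- trials[trials$subject_id == sid, , drop = FALSE]
    m <- sdt_measures(sub)
    rep_tr <- sub[sub$task == "reproduction" & !is.na(sub$reproduced_length), ]
    rep_err <- if (nrow(rep_tr)) {
      pred <- rep_tr$reproduced_length - rep_tr$target_length
      mean(abs(pred))
    } else NA_real_
    data.frame(subject_id = sid,
               bias_source = sub$bias_source[1],
               d_prime = m$d_prime, criterion_c = m$criterion_c,
               reproduction_error = rep_err, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
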