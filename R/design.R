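#' Build the trial-count design for one bias source and direction
#'
#' Constructs the per-target-length presentation counts of the line-length
#' experiment. Seven target lengths (370--430 px in steps of 10) are judged
#' against a 400 px reference. In the \code{muller_lyer} and \code{payoff}
#' conditions every target appears 40 times in the decision/confidence task
#' and 20 times in the reproduction task (280 + 140 trials per bias
#' direction). In the \code{base_rate} condition the prevalent category
#' (matching the bias direction) appears 120, 90 and 60 times going from the
#' target farthest from the reference to the closest; the non-prevalent
#' targets and the 400 px target appear 30 times each (390 decision trials),
#' and every reproduction count is half its decision count (195 trials).
#' Incorrect responses cost 1 point except in the payoff condition, where the
#' response opposite to the bias direction carries a 5-point penalty.
#'
#' @param bias_source One of \code{"muller_lyer"}, \code{"base_rate"},
#'   \code{"payoff"}.
#' @param bias_direction One of \code{"long"}, \code{"short"}.
#' @return An object of class \code{condition_design}: a list with
#'   \code{bias_source}, \code{bias_direction}, \code{target_lengths},
#'   \code{reference_length}, \code{decision_counts},
#'   \code{reproduction_counts} (named integer vectors, names are target
#'   lengths), \code{penalty_incorrect_long}, \code{penalty_incorrect_short}.
#' @examples
#' d <- build_design("base_rate", "long")
#' sum(d$decision_counts)      # 390
#' sum(d$reproduction_counts)  # 195
#' @export
build_design <- function(bias_source = c("muller_lyer", "base_rate", "payoff"),
                         bias_direction = c("long", "short")) {
  bias_source <- match.arg(bias_source)
  bias_direction <- match.arg(bias_direction)

  target_lengths <- seq(370L, 430L, by = 10L)
  reference <- 400L
  nm <- as.character(target_lengths)

  if (bias_source == "base_rate") {
    dec <- rep(30L, 7L)
    names(dec) <- nm
    # prevalent category: targets on the biased side, 120/90/60 from the
    # farthest length to the closest
    if (bias_direction == "long") {
      dec[c("430", "420", "410")] <- c(120L, 90L, 60L)
    } else {
      dec[c("370", "380", "390")] <- c(120L, 90L, 60L)
    }
    rep_counts <- dec %/% 2L
  } else {
    dec <- rep(40L, 7L)
    rep_counts <- rep(20L, 7L)
    names(dec) <- names(rep_counts) <- nm
  }

  if (bias_source == "payoff") {
    # the response opposite to the bias direction is punished more
    if (bias_direction == "short") {
      pen_long <- 5L; pen_short <- 1L
    } else {
      pen_long <- 1L; pen_short <- 5L
    }
  } else {
    pen_long <- pen_short <- 1L
  }

  structure(
    list(
      bias_source = bias_source,
      bias_direction = bias_direction,
      target_lengths = target_lengths,
      reference_length = reference,
      decision_counts = dec,
      reproduction_counts = rep_counts,
      penalty_incorrect_long = pen_long,
      penalty_incorrect_short = pen_short
    ),
    class = "condition_design"
  )
}

#' @export
print.condition_design <- function(x, ...) {
  cat(sprintf("<condition_design> %s / biased-to-%s\n", x$bias_source, x$bias_direction))
  cat(sprintf("  decision trials: %d, reproduction trials: %d\n",
              sum(x$decision_counts), sum(x$reproduction_counts)))
  cat(sprintf("  penalties (incorrect long/short): %d/%d\n",
              x$penalty_incorrect_long, x$penalty_incorrect_short))
  invisible(x)
}

#' Build a randomized trial schedule from a condition design
#'
#' Expands the design counts into one row per trial and applies a
#' seed-reproducible random permutation. Only the marginal counts of the
#' original experiment are preserved; the mini-block structure of the
#' original procedure is not modeled.
#'
#' @param design A \code{condition_design} from [build_design()].
#' @param seed Integer seed for the permutation.
#' @return A data.frame with columns \code{target_length} (integer px) and
#'   \code{task} (\code{"decision"} or \code{"reproduction"}), one row per
#'   trial.
#' @export
build_schedule <- function(design, seed = 1L) {
  stopifnot(inherits(design, "condition_design"))
  target <- c(rep(design$target_lengths, times = design$decision_counts),
              rep(design$target_lengths, times = design$reproduction_counts))
  task <- c(rep("decision", sum(design$decision_counts)),
            rep("reproduction", sum(design$reproduction_counts)))
  set.seed(as.integer(seed))
  idx <- sample.int(length(target))
  data.frame(target_length = target[idx], task = task[idx],
             stringsAsFactors = FALSE)
}
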