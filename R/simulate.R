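#' Generative SDT observer parameters
#'
#' Bundles the parameters of the signal-detection observer used to generate
#' synthetic trials. The observer forms a percept
#' \eqn{x = L + p + \epsilon}, \eqn{\epsilon \sim N(0, \sigma^2)}, where
#' \eqn{L} is the target length and \eqn{p} a signed perceptual shift
#' (positive = lines look longer, as with inward Muller-Lyer fins). It
#' answers "long" when \eqn{x \ge R + c_{dec}} (reference \eqn{R} = 400 px;
#' \eqn{c_{dec}} a signed decision-criterion shift, negative = liberal
#' toward "long"). Confidence is "high" when the percept is far from a
#' confidence center: \eqn{|x - (R + c_{conf})| \ge \max(\tau + \eta, 0)}
#' with \eqn{\eta \sim N(0, \sigma_m^2)} redrawn per trial; \eqn{\sigma_m}
#' is metacognitive noise that degrades M-ratio below 1. Reproductions are
#' \eqn{y = \alpha + \beta (L + p) + \epsilon_r},
#' \eqn{\epsilon_r \sim N(0, \sigma_r^2)}.
#'
#' Closed-form landmarks (the test oracle for the whole pipeline):
#' decision PSE \eqn{= R + c_{dec} - p}; confidence-uncertainty center
#' \eqn{= R + c_{conf} - p}; reproduction match point
#' \eqn{= (R - \alpha)/\beta - p}.
#'
#' @param perceptual_shift Signed perceptual shift \eqn{p} in px.
#' @param decision_criterion_shift Signed criterion shift \eqn{c_{dec}} in px.
#' @param confidence_center_shift Signed confidence-center shift
#'   \eqn{c_{conf}} in px.
#' @param sensory_sd Sensory noise \eqn{\sigma > 0} in px.
#' @param confidence_halfwidth Half-width \eqn{\tau \ge 0} of the
#'   low-confidence band in px.
#' @param metacognitive_noise_sd Trial-to-trial SD \eqn{\sigma_m \ge 0} of
#'   the confidence threshold in px.
#' @param reproduction_intercept,reproduction_slope,reproduction_sd
#'   Reproduction mapping \eqn{\alpha} (px), \eqn{\beta > 0}, and noise
#'   \eqn{\sigma_r \ge 0} (px).
#' @return An object of class \code{observer_params}.
#' @export
observer_params <- function(perceptual_shift = 0,
                            decision_criterion_shift = 0,
                            confidence_center_shift = 0,
                            sensory_sd = 15,
                            confidence_halfwidth = 18,
                            metacognitive_noise_sd = 10,
                            reproduction_intercept = 0,
                            reproduction_slope = 1,
                            reproduction_sd = 20) {
  if (!is.numeric(sensory_sd) || sensory_sd <= 0)
    stop("degenerate observer: sensory_sd must be > 0", call. = FALSE)
  if (reproduction_slope <= 0)
    stop("reproduction_slope must be > 0", call. = FALSE)
  if (confidence_halfwidth < 0 || metacognitive_noise_sd < 0 || reproduction_sd < 0)
    stop("all noise SDs and the confidence half-width must be >= 0", call. = FALSE)
  structure(
    list(perceptual_shift = perceptual_shift,
         decision_criterion_shift = decision_criterion_shift,
         confidence_center_shift = confidence_center_shift,
         sensory_sd = sensory_sd,
         confidence_halfwidth = confidence_halfwidth,
         metacognitive_noise_sd = metacognitive_noise_sd,
         reproduction_intercept = reproduction_intercept,
         reproduction_slope = reproduction_slope,
         reproduction_sd = reproduction_sd),
    class = "observer_params"
  )
}

#' Simulate trials from an SDT observer
#'
#' Generates one trial record per schedule row under the generative model
#' described in [observer_params()]. Decision trials carry a response
#' ("short"/"long"), a binary confidence ("low"/"high") and, except at the
#' reference length where correctness is undefined, a correctness flag.
#' Reproduction trials carry only the reproduced length.
#'
#' @param params An \code{observer_params} object.
#' @param design A \code{condition_design} (supplies the reference length and
#'   condition labels).
#' @param schedule A schedule data.frame from [build_schedule()] (or any
#'   data.frame with \code{target_length} and \code{task} columns).
#' @param subject_id Subject label stored in the output.
#' @param seed Integer seed.
#' @return A data.frame of trial records with columns \code{subject_id},
#'   \code{bias_source}, \code{bias_direction}, \code{task},
#'   \code{target_length}, \code{response}, \code{confidence},
#'   \code{reproduced_length}, \code{correct}. Fields that do not apply to a
#'   task are \code{NA}.
#' @export
simulate_trials <- function(params, design, schedule, subject_id = "s01",
                            seed = 1L) {
  stopifnot(inherits(params, "observer_params"),
            inherits(design, "condition_design"))
  if (!all(c("target_length", "task") %in% names(schedule)))
    stop("schedule must have target_length and task columns", call. = FALSE)
  set.seed(as.integer(seed))

  n <- nrow(schedule)
  R <- design$reference_length
  L <- schedule$target_length
  is_dec <- schedule$task == "decision"

  percept <- L + params$perceptual_shift + rnorm(n, 0, params$sensory_sd)

  response <- rep(NA_character_, n)
  confidence <- rep(NA_character_, n)
  reproduced <- rep(NA_real_, n)
  correct <- rep(NA, n)

  if (any(is_dec)) {
    x <- percept[is_dec]
    resp_long <- x >= R + params$decision_criterion_shift
    response[is_dec] <- ifelse(resp_long, "long", "short")
    thr <- pmax(params$confidence_halfwidth +
                  rnorm(sum(is_dec), 0, params$metacognitive_noise_sd), 0)
    confidence[is_dec] <- ifelse(
      abs(x - (R + params$confidence_center_shift)) >= thr, "high", "low")
    Ld <- L[is_dec]
    corr <- ifelse(Ld == R, NA,
                   (Ld > R) == resp_long)
    correct[is_dec] <- corr
  }
  if (any(!is_dec)) {
    Lr <- L[!is_dec]
    reproduced[!is_dec] <- params$reproduction_intercept +
      params$reproduction_slope * (Lr + params$perceptual_shift) +
      rnorm(sum(!is_dec), 0, params$reproduction_sd)
  }

  data.frame(subject_id = subject_id,
             bias_source = design$bias_source,
             bias_direction = design$bias_direction,
             task = schedule$task,
             target_length = L,
             response = response,
             confidence = confidence,
             reproduced_length = reproduced,
             correct = correct,
             stringsAsFactors = FALSE)
}

#' Default cohort observer parameters for one bias source and direction
#'
#' Canonical generative settings reproducing the study's qualitative
#' dissociation. The Muller-Lyer manipulation is modeled as a pure
#' perceptual shift (p = +/-12 px, criterion and confidence center
#' untouched); base rate and payoff as pure decisional shifts (c_dec = -/+7
#' and -/+10 px) of which half leaks into the confidence center
#' (c_conf = 0.5 c_dec). Signs follow the convention that biasing toward
#' "long" moves all affected landmarks toward shorter target lengths.
#'
#' @param bias_source,bias_direction Condition labels as in [build_design()].
#' @return An \code{observer_params} object.
#' @export
cohort_params <- function(bias_source = c("muller_lyer", "base_rate", "payoff"),
                          bias_direction = c("long", "short")) {
  bias_source <- match.arg(bias_source)
  bias_direction <- match.arg(bias_direction)
  sgn <- if (bias_direction == "long") 1 else -1
  p <- 0; cdec <- 0
  if (bias_source == "muller_lyer") {
    p <- sgn * 12
  } else {
    shift <- if (bias_source == "base_rate") 7 else 10
    cdec <- -sgn * shift
  }
  observer_params(perceptual_shift = p,
                  decision_criterion_shift = cdec,
                  confidence_center_shift = 0.5 * cdec)
}

#' Simulate a full between-subject cohort
#'
#' Simulates \code{n_per_group} subjects in each requested bias-source group,
#' each completing both bias directions with the exact trial counts of
#' [build_design()]. Between-subject heterogeneity is added as Gaussian
#' jitter on the subject's perceptual/criterion shifts (the confidence-center
#' leak ratio is preserved within subject), and mild jitter on sensory and
#' reproduction parameters.
#'
#' @param n_per_group Named or unnamed integer vector of group sizes; if
#'   unnamed, applies to \code{groups} in order. Default is the pooled
#'   two-experiment sample of the study (52 Muller-Lyer, 85 base rate,
#'   67 payoff).
#' @param groups Character vector of bias sources to simulate.
#' @param seed Integer master seed; all per-subject seeds derive from it.
#' @param subject_sd Between-subject SD (px) of the subject-level shift
#'   parameters.
#' @return A single trial-record data.frame (rows from all subjects).
#' @export
simulate_cohort <- function(n_per_group = c(muller_lyer = 52, base_rate = 85,
                                            payoff = 67),
                            groups = c("muller_lyer", "base_rate", "payoff"),
                            seed = 1L, subject_sd = 3) {
  if (is.null(names(n_per_group)))
    names(n_per_group) <- groups
  set.seed(as.integer(seed))
  out <- vector("list", 0L)
  k <- 0L
  for (g in groups) {
    n_g <- n_per_group[[g]]
    for (i in seq_len(n_g)) {
      sid <- sprintf("%s_%02d", abbreviate(g, 2), i)
      # subject-level deviations shared across directions where they encode
      # stable traits (sensory noise, reproduction mapping), independent per
      # direction for the manipulated shifts
      sigma_i <- exp(rnorm(1, log(15), 0.12))
      tau_i <- max(rnorm(1, 18, 2), 4)
      sm_i <- max(rnorm(1, 10, 2), 0)
      alpha_i <- rnorm(1, 0, 5)
      beta_i <- max(rnorm(1, 1, 0.04), 0.5)
      sr_i <- exp(rnorm(1, log(20), 0.12))
      for (dir in c("long", "short")) {
        base <- cohort_params(g, dir)
        p_i <- base$perceptual_shift +
          if (g == "muller_lyer") rnorm(1, 0, subject_sd) else 0
        cdec_i <- base$decision_criterion_shift +
          if (g != "muller_lyer") rnorm(1, 0, subject_sd) else 0
        pars <- observer_params(
          perceptual_shift = p_i,
          decision_criterion_shift = cdec_i,
          confidence_center_shift = 0.5 * cdec_i * (g != "muller_lyer"),
          sensory_sd = sigma_i,
          confidence_halfwidth = tau_i,
          metacognitive_noise_sd = sm_i,
          reproduction_intercept = alpha_i,
          reproduction_slope = beta_i,
          reproduction_sd = sr_i)
        des <- build_design(g, dir)
        seeds <- sample.int(2147483646L, 2L)
        sch <- build_schedule(des, seed = seeds[1])
        k <- k + 1L
        out[[k]] <- simulate_trials(pars, des, sch, subject_id = sid,
                                    seed = seeds[2])
      }
    }
  }
  do.call(rbind, out)
}

#' Write / read trial-record tables
#'
#' Trial tables are stored as comma-separated text with a header row
#' (\code{subject_id, bias_source, bias_direction, task, target_length,
#' response, confidence, reproduced_length, correct}); inapplicable fields
#' are empty.
#'
#' @param trials A trial-record data.frame.
#' @param path File path.
#' @return \code{read_trials} returns the trial-record data.frame.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  required <- c("subject_id", "bias_source", "bias_direction", "task",
                "target_length", "response", "confidence",
                "reproduced_length")
  missing <- setdiff(required, names(tr))
  if (length(missing))
    stop("trial table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (col in c("response", "confidence"))
    tr[[col]][!is.na(tr[[col]]) & tr[[col]] == ""] <- NA_character_
  if (!"correct" %in% names(tr)) {
    tr$correct <- ifelse(tr$target_length == 400, NA,
                         (tr$target_length > 400) == (tr$response == "long"))
  }
  tr
}
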