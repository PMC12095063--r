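# shared simulation helpers for the test suite

# simulate `reps` copies of a condition's schedule for one observer
sim_trials <- function(params, bias_source = "muller_lyer",
                       bias_direction = "long", reps = 1L, seed = 1L) {
  des <- build_design(bias_source, bias_direction)
  sch <- build_schedule(des, seed = seed)
  if (reps > 1L)
    sch <- do.call(rbind, replicate(reps, sch, simplify = FALSE))
  simulate_trials(params, des, sch, seed = seed + 1L)
}

# random but well-behaved 2x2x2 confidence count tables
random_type2_counts <- function(seed) {
  set.seed(seed)
  arr <- array(stats::rpois(8, 25) + 1, dim = c(2, 2, 2),
               dimnames = list(stimulus = c("short", "long"),
                               response = c("short", "long"),
                               confidence = c("low", "high")))
  # guarantee clear type-1 sensitivity so meta-d' is identifiable
  arr["long", "long", ] <- arr["long", "long", ] + 30
  arr["short", "short", ] <- arr["short", "short", ] + 30
  arr
}
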