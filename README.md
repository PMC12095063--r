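# confbias

Does confidence in a perceptual decision track what the observer actually
*experiences*, or does it also absorb plainly non-perceptual information such
as category prevalence or asymmetric penalties? `confbias` implements the
complete inference chain needed to answer that question for a line-length
categorisation experiment with three bias manipulations — the Müller–Lyer
illusion (perceptual), a 3:1 base-rate manipulation, and a 5:1 payoff
manipulation (both decisional) — each applied in a bias-to-long and a
bias-to-short direction, with a controlled-reproduction task as the
bias-independent benchmark of subjective experience.

It is aimed at psychophysicists and metacognition researchers who want a
tested, fully scripted version of this analysis style, plus a generative
observer for power analysis and method validation.

## What it computes

For trial tables (simulated or ingested as CSV) the package provides:

* **Psychometric landmarks** per subject × condition: the point of
  subjective equality from a probit fit, PSE = −â/b̂; the point of maximal
  uncertainty from a quadratic fit to the proportion of high-confidence
  responses, vertex = −b/2a; and the reproduction match point from a linear
  fit, (400 − α̂)/β̂ — with the fit-quality screens (significant,
  correctly-signed governing coefficient) applied as exclusions.
* **Signal detection**: d′ = Z(HR) − Z(FAR), c = ½(Z(HR) + Z(FAR)) with
  edge correction, plus the 4-SD outlier and negative-d′ participant
  screens.
* **JZS Bayes factors**: one- or two-sided paired t-tests under a
  Cauchy(0, 0.707) prior on the standardized effect, with Cohen's d, 95%
  credible intervals and deterministic posterior sampling; Savage–Dickey
  density-ratio BFs for point nulls.
* **Encompassing-prior ordinal model comparison**: all 2^k effect/null
  constraint patterns over the bias-source groups scored against the
  all-null model (the Bayes factor of a sign constraint is the posterior /
  prior mass ratio under the unconstrained model), and the 3^k
  decision-vs-confidence pattern comparison.
* **Metacognitive efficiency**: maximum-likelihood meta-d′ and M-ratio per
  subject (validated against an exhaustive grid search), a group-level
  posterior for mean M-ratio by MCMC with R-hat monitoring, and a
  Savage–Dickey test of the bias-direction difference.
* A **generative SDT observer** whose perceptual shift p, criterion shift
  c_dec and confidence-center shift c_conf move the three landmarks by
  closed forms (PSE = R + c_dec − p, vertex = R + c_conf − p,
  match = (R − α)/β − p), the exact trial schedules of the design, and a
  **sequential optional-stopping** recruitment simulator.

## Worked example

```r
library(confbias)
report <- run_full(analysis_config(seed = 1))
print(report)
```

```
<bias_report>
Bayes-factor t-tests (landmark(short) - landmark(long)):
         task bias_source  n mean_effect_px     bf10 cohens_d cri_low cri_high
     decision   base_rate 84           13.4 9.80e+36     2.70    11.0     15.6
     decision muller_lyer 52           24.1 3.20e+35     5.17    19.0     28.6
     decision      payoff 67           20.4 3.08e+36     3.59    16.4     23.9
   confidence   base_rate 76            5.9 9.04e+19     1.61     4.6      7.1
   confidence muller_lyer 21           21.3 4.50e+11     4.17    13.7     27.6
   confidence      payoff 60            9.1 1.04e+24     2.46     7.1     10.9
 reproduction   base_rate 84            0.2 1.95e-01     0.06    -0.5      0.8
 reproduction muller_lyer 52           23.7 2.77e+31     4.25    18.6     28.2
 reproduction      payoff 67            0.4 3.44e-01     0.12    -0.4      1.2
decision lattice winner: A (best/second = 3.2e+35)
confidence lattice winner: A (best/second = 4.5e+11)
reproduction lattice winner: F (best/second = 2.9)
task-difference winner: base_rate:dec>conf|muller_lyer:equal|payoff:dec>conf
base_rate: M-ratio long 0.748 / short 0.757, difference BF10 = 0.184
muller_lyer: M-ratio long 0.796 / short 0.814, difference BF10 = 0.258
payoff: M-ratio long 0.767 / short 0.781, difference BF10 = 0.223
```

Reading the output: every bias manipulation shifts decisions
(13–24 px effects, decisive BFs) and confidence (6–21 px), but only the
Müller–Lyer manipulation shifts the reproduction benchmark (24 px vs ~0 px
and BF10 < 1/3 in the other groups) — confidence "leaks" decisional bias.
The lattice winners say the same in model-comparison form: the all-effects
pattern wins for decisions and confidence, while for reproduction the
winning pattern has an effect *only* in the Müller–Lyer group (model labels
are positional bookkeeping; the winner's constraint map is what matters).
The task-difference winner shows the non-perceptual groups biasing
decisions more strongly than confidence. Group M-ratios sit near 0.75–0.81
(imperfect metacognition), and the bias-direction difference BFs all favor
the null — the generator's metacognitive noise is direction-symmetric, so
no efficiency difference is the correct answer here.

Curve-level tools are available directly, e.g.

```r
tr  <- simulate_trials(observer_params(perceptual_shift = 15),
                       design   = build_design("muller_lyer", "long"),
                       schedule = build_schedule(build_design("muller_lyer", "long"), 1))
fit_decision(tr)      # probit PSE near 385 = 400 - 15
```

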