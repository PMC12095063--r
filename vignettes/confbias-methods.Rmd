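---
title: "Separating perceptual and decisional bias in confidence reports: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating perceptual and decisional bias in confidence reports: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confbias)
```

## The scientific problem

When people categorise a noisy stimulus, a shift in their responses can come
from two very different places: the stimulus can genuinely *look* different
(a perceptual change, as with the Müller–Lyer illusion), or the observer can
simply adopt a different answering policy (a decisional change, as when one
category is more frequent or errors are punished asymmetrically). Confidence
ratings are often treated as a window on subjective experience. `confbias`
implements a full inference chain for asking whether that is true: if
confidence uniquely tracked experience, only perceptual manipulations should
move confidence; if decisional biases "leak" into confidence, all
manipulations should.

The package covers three tasks on the same stimuli (horizontal lines of
370–430 px judged against a 400 px reference):

* **decision/confidence** — binary shorter/longer categorisation with a
  binary high/low confidence rating;
* **controlled reproduction** — reproducing the perceived length, used as a
  bias-independent benchmark of subjective experience.

Three between-subject bias sources are modeled, each with two within-subject
bias directions (toward "long" or "short"): a Müller–Lyer arrowhead
manipulation (perceptual), a 3:1 base-rate manipulation, and a 5:1
asymmetric payoff manipulation (both decisional).

## The generative observer

The synthetic-data generator (`observer_params()`, `simulate_trials()`) is a
signal-detection observer with separately controllable perceptual and
decisional stages. On each trial with target length $L$:

$$x = L + p + \varepsilon,\qquad \varepsilon \sim N(0, \sigma^2)$$

* **Decision**: answer "long" iff $x \ge R + c_{dec}$, with $R = 400$ px.
* **Confidence**: answer "high" iff $|x - (R + c_{conf})| \ge
  \max(\tau + \eta, 0)$, $\eta \sim N(0, \sigma_m^2)$ redrawn per trial.
* **Reproduction**: $y = \alpha + \beta (L + p) + \varepsilon_r$,
  $\varepsilon_r \sim N(0, \sigma_r^2)$.

The perceptual shift $p$ enters all three observables; the criterion shift
$c_{dec}$ enters only the decision; the confidence-center shift $c_{conf}$
enters only confidence. This is the minimal model in which the three
psychometric landmarks have distinct closed forms,

$$\mathrm{PSE} = R + c_{dec} - p,\qquad
  \mathrm{vertex} = R + c_{conf} - p,\qquad
  \mathrm{match} = (R - \alpha)/\beta - p,$$

which serve as the test oracle for the entire pipeline: a Müller–Lyer-like
observer ($p \ne 0$, $c_{dec} = c_{conf} = 0$) moves all three landmarks by
$-p$, while a criterion-shift observer ($p = 0$) moves the PSE and the
confidence vertex but leaves the reproduction match point untouched — the
headline dissociation.

### Default parameter values and why

| parameter | default | rationale |
|---|---|---|
| $\sigma$ (sensory noise) | 15 px | yields overall $d' \approx 2.3$ over the ±30 px stimulus range, a typical psychophysical regime |
| $\tau$ (confidence half-width) | 18 px | makes high/low confidence usage roughly balanced (~53% high), as the task's block feedback encouraged |
| $\sigma_m$ (metacognitive noise) | 10 px | produces M-ratio ≈ 0.75–0.85, the sub-ideal efficiency typical of perceptual metacognition |
| $\alpha, \beta, \sigma_r$ (reproduction) | 0, 1, 20 px | unbiased reproduction with realistic trial-to-trial scatter |
| $p$ (Müller–Lyer) | ±12 px | reproduction effect $2p = 24$ px, the size of the observed Müller–Lyer reproduction effect |
| $c_{dec}$ (base rate / payoff) | ∓7 / ∓10 px | decision effects of 14 and 20 px, matching the observed ordering (payoff > base rate) |
| $c_{conf}$ | $0.5\,c_{dec}$ | the partial "leak" of decisional bias into confidence; half-leak makes decision effects larger than confidence effects in non-perceptual groups |

Signs follow a single convention throughout: biasing toward "long" moves
landmarks toward *shorter* target lengths, and the per-subject **landmark
effect** is `landmark(short) − landmark(long)`, so a positive effect always
means behavior shifted toward the biased direction.

The default cohort sizes (52 Müller–Lyer, 85 base rate, 67 payoff) are the
pooled two-experiment samples on which the ordinal model comparison operates;
between-subject heterogeneity is Gaussian jitter (SD 3 px) on the subject's
shift parameters plus mild log-normal jitter on the noise parameters.

### Trial schedules

`build_design()` reproduces the exact presentation counts: 40 decision and
20 reproduction presentations of each of the seven lengths in the
Müller–Lyer and payoff conditions (280 + 140 trials per direction); in the
base-rate condition the prevalent category is presented 120/90/60 times from
the farthest length to the closest, all other lengths 30 times (390
decision trials), with reproduction counts exactly half (195).
`build_schedule()` preserves these marginal counts under a seeded random
permutation; the original mini-block structure and counterbalancing are not
modeled because every analysis in the chain uses only the marginal counts.

## The analysis chain

### Psychometric curves and landmarks

Per subject × bias direction (`fit_decision()`, `fit_confidence()`,
`fit_reproduction()`):

* **PSE** — maximum-likelihood probit (cumulative Gaussian) of P("long")
  on target length; PSE $= -\hat a/\hat b$. The fit-quality screen is a
  two-sided Wald test of the slope at $\alpha = 0.05$ plus a positive-sign
  requirement; degenerate inputs (all-identical responses, complete
  separation) fail the screen rather than raising errors.
* **Point of maximal uncertainty** — ordinary least squares of the
  per-length proportion of "high" responses on $(x, x^2)$; the landmark is
  the vertex $-b/2a$, screened for $a > 0$ and significance. Fitting
  per-length proportions (not trial-level binary regression) matches how
  such confidence curves are conventionally summarised and plotted.
* **Reproduction match point** — OLS of reproduced length on target length;
  the landmark is $(400 - \hat\alpha)/\hat\beta$, screened for a positive,
  significant slope.

All landmarks are analytic inversions of the fitted curves; tests verify
they agree with numeric grid minimisation/root finding to $10^{-6}$ px.
Vertices outside 340–460 px are flagged as extrapolated. A subject enters a
task's group analysis only if both directions pass the screen.

### Signal detection and participant screening

`sdt_measures()` treats correct "long" responses as hits:
$d' = Z(\mathrm{HR}) - Z(\mathrm{FAR})$ and
$c = \tfrac12(Z(\mathrm{HR}) + Z(\mathrm{FAR}))$. Reference-length trials
belong to neither class and are excluded; rates of 0 or 1 are corrected to
$1/2N$ and $1 - 1/2N$. `screen_participants()` excludes subjects whose
criterion, $d'$ or mean absolute reproduction error falls outside ±4 SD of
the grand (pooled across groups) mean, and anyone with $d' < 0$; zero-SD
samples exclude nobody.

### JZS Bayes factors

`jzs_bf_paired()` computes the Jeffreys–Zellner–Siow t-test: a
Cauchy$(0, r)$ prior on the standardized effect $\delta$ with the default
$r = 0.707$, marginal likelihood by adaptive quadrature of the noncentral-t
density against the prior. The one-sided BF multiplies the two-sided BF by
twice the posterior mass above zero (equivalently, truncating the prior).
Posterior summaries come from a deterministic 4096-point grid of the
$\delta$ posterior on ±10 with trapezoidal accumulation; draws are
inverse-CDF samples, and credible intervals are central 95% intervals mapped
to the pixel scale through the sample SD (an HDI variant is available via
`interval = "hdi"`; for these unimodal posteriors the two nearly coincide).

`savage_dickey()` implements the density-ratio Bayes factor for a point
null: prior density at zero ($1/\pi r$ for the Cauchy) divided by a
Gaussian-kernel (Silverman bandwidth) estimate of the posterior density at
zero. Note the orientation: prior/posterior is BF$_{10}$ — evidence *for*
an effect grows as the posterior vacates zero. When the posterior sits so
far from zero that the kernel estimate underflows, the density is floored at
the smallest representable double and the reported BF is an
underflow-limited bound.

### Ordinal (encompassing-prior) model comparison

Each between-subject group reduces to a one-sample problem on its
per-subject effect scores, so constraint models factorize over groups. For
a sign constraint (effect > 0) the encompassing-prior identity gives
BF(ordinal vs unconstrained) = posterior mass above zero / prior mass above
zero (= 1/2 for the symmetric prior); equality constraints are the group's
null. `lattice_bf()` scores all $2^k$ effect/null patterns against the
all-null baseline by multiplying per-group BFs; `task_difference_models()`
applies the same machinery to per-subject differences between decision and
confidence effects with three states per group (dec > conf, conf > dec,
equal), $3^k$ models in all. Model letters ("A" … "null") are canonical
bookkeeping labels in decreasing binary order of the effect patterns; code
and tests identify models by their constraint maps, never by letter.

This factorized formulation replaces a joint-design model fitted in
external software: with between-subject groups and within-subject
difference scores the likelihood separates exactly, and using the
deterministic grid posterior (rather than MCMC) removes Monte-Carlo noise
from the Bayes factors.

### Metacognitive efficiency

`fit_meta_d()` is a maximum-likelihood meta-d′ for the binary-confidence
design: type-1 $d'$ and criterion come from the (edge-corrected) counts; the
meta-level observer keeps the relative criterion $c' = c/d'$ fixed and has
one type-2 criterion per response side; meta-d′ and the two criteria
maximise the multinomial likelihood of confidence conditional on stimulus
and response (Nelder–Mead from two starts, verified against an exhaustive
grid search). M-ratio = meta-d′/d′ equals 1 for a metacognitively ideal
observer and falls below 1 as $\sigma_m$ grows; $\sigma_m = 0$ recovers
M-ratio = 1 within ±0.05 at $10^4$ trials per class.

The group stage deliberately simplifies the hierarchical MCMC model of the
original analysis tool: per-subject MLE log M-ratios get a Normal likelihood
with unknown mean and SD, a $N(0, 5^2)$ prior on the mean and half-Cauchy(1)
on the SD, sampled by random-walk Metropolis with the original sampler
settings (4 chains × 20,000 iterations, thinning 2; first quarter as
adaptive warmup) and a split-chain $\hat R < 1.02$ convergence requirement.
This preserves the inferential structure (group posterior → Savage–Dickey
on the standardized direction difference, log scale by default with a raw
option) while remaining fully testable at desk scale.

### Sequential optional stopping

`sequential_stopping_sim()` reproduces the recruitment rule: start at 30
subjects, test, stop when BF$_{10} > 3$ or $< 0.3$, otherwise add 5, up to a
cap. With a true $d = 2$ essentially every replicate stops at the first
look; under the null most replicates reach the lower threshold.

## What the generator does and does not emulate

It emulates: the exact trial-count designs, the three-way dissociation
(perceptual shift vs criterion shift vs confidence leak), imperfect
metacognition, balanced confidence usage, between-subject heterogeneity, and
the asymmetric stimulus prevalence of the base-rate condition. It does not
emulate: sequential/criterion drift within a session, lapses, reaction
times, mini-block structure, feedback-driven learning, or any relation
between the payoff matrix and the observer beyond a static criterion shift.
Passing tests therefore show that the *inference chain* recovers the truth
of this observer class — not that real observers are this observer.

One negative result is worth flagging: the observer's metacognitive noise
is direction-symmetric, and simulation confirms that fitted M-ratio shows
no bias-direction asymmetry in any group (including base rate, where an
asymmetry has been reported empirically). A criterion shift interacting
with asymmetric stimulus prevalence is therefore *not* sufficient to
produce an apparent efficiency difference in this measurement chain —
whatever drives such empirical effects lies outside this observer class.

## Numerical choices

* JZS integrals: `stats::integrate` at `rel.tol = 1e-11`; validated to
  $10^{-6}$ relative against an independent inverse-gamma mixture
  representation integrated with a hand-rolled adaptive Simpson rule.
* Grid posterior: 4096 points on ±10, trapezoidal CDF (the
  left-Riemann version loses ~3% on tail masses of order 0.04).
* Inverse normal oracle: Acklam's rational approximation (≤ ~3e-9 absolute
  error), independent of `qnorm`.
* Meta-d′ grid oracle: exhaustive 0.01-resolution search (criteria decouple
  across response sides given meta-d′, making it cheap) plus a second
  exhaustive pass at 1/100 the step around the coarse optimum so that grid
  discretization does not mask optimizer error at the $10^{-3}$ comparison
  level.
* Edge corrections: $1/2N$ rate clamping for type-1 rates; +0.5 to all
  eight cells of a type-2 table containing a zero.
* Degenerate inputs: all-zero effect vectors are treated as the
  scale-invariant limit $t = 0$ (the constraint machinery stays defined);
  zero-variance non-zero data are rejected.
* All randomness flows from explicit integer seeds; reruns are
  bit-identical.

## Problem sizes used in the validation suite

The packaged tests exercise landmark recovery at ~$10^5$ simulated decision
trials per observer, oracle comparisons on 20–100 random instances each,
100-replicate cohort studies at the pooled group sizes (52/85/67), and
200-replicate stopping simulations — sizes chosen so the whole suite runs
on a laptop in minutes while keeping Monte-Carlo error well inside each
assertion's tolerance.

## Known limitations

* **Quadratic vertex bias.** The point of maximal uncertainty is the vertex
  of an OLS parabola through seven fixed lengths. Because the true
  confidence curve is not a parabola, the vertex estimate has an asymptotic
  bias that grows as the true center departs from the middle of the
  stimulus grid (about −0.8 px at a 5 px offset under the default
  observer). This is a property of the quadratic summary itself; effects
  (short-minus-long differences) cancel most of it by symmetry.
* **Match-point ratio bias.** The reproduction landmark
  $(400-\hat\alpha)/\hat\beta$ is a ratio estimator; with the base-rate
  design's asymmetric leverage its per-direction bias does not cancel in
  the effect, leaving a ~+0.1 px spurious mean effect in the base-rate
  group (delta-method prediction $2(\bar x - 400)\mathrm{Var}(\hat\beta)$,
  matching simulation). It is far below the ~2.7 px subject-level noise,
  but over many subjects it measurably inflates the rate at which a
  one-sided Bayes factor in a truly-null group drifts above 1.
* **Null-group winner rates.** Even under a perfect null, a one-sided JZS
  BF exceeds 1 on ~4–7% of samples (n 35–85). The probability that the
  perceptual-only model wins the reproduction lattice in any one cohort is
  therefore bounded near (1−q)² ≈ 0.87–0.91, and a 100-replicate study
  fluctuates around that value.
* The group M-ratio model is a simplification of the hierarchical original;
  subject-level estimation noise is not propagated into the group SD.
* Binary confidence only; response-conditional meta-d′ and >2 confidence
  levels are out of scope.

## A worked run

```{r, eval = FALSE}
report <- run_full(analysis_config(seed = 5))
print(report)
```

This simulates the full default cohort, screens it, fits ~1,200 curves,
and prints the Bayes-factor table, the per-task lattice winners, the
decision-vs-confidence pattern, and the per-group M-ratio comparison. See
the README for the printed output and its reading.
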