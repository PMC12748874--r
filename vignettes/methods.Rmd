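---
title: "Models and methods: credit assignment, active disambiguation and controllability inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disambig)
```

## The credit-assignment problem

Two agents jointly produce a single outcome. On each trial the participant
plays a short game, a (fictive) other player plays the same game unseen, and
one feedback score is shown:

$$\mathrm{feedback}_t = \mathrm{self}_t \cdot c + \mathrm{other}_t \cdot (1 - c),$$

where $c \in [0,1]$ is the participant's control over the outcome and the two
performance scores live on a 0–100 scale. The participant must infer, from
this single ambiguous number, how good they are, how good the other is, and
how much control they have. The task decomposes the problem over three phase
types per block: a *Self-Other* phase (control instructed; self and other
unknown), a few *Self-only* trials (full control, feedback = own score), and
a *Control-Other* phase (self known from the preceding Self-only trials;
control and a new other unknown). Four blocks of 16 + 4 + 16 trials give 144
trials.

*Active disambiguation* (AD) is the behavioural lever: by deliberately
performing terribly, the participant forces their own score to zero, so the
feedback reveals $\mathrm{other}\cdot(1-c)$ alone. Comparing feedback with
and without one's own contribution identifies control:

$$c = \frac{\mathrm{feedback}_{\text{normal}} - \mathrm{feedback}_{\text{AD}}}{\mathrm{self}}.$$

With a normal feedback of 44, an AD feedback of 4 and a self level of 50,
`infer_control_point(44 - 4, 50)` returns exactly 0.8, and the implied other
level is $4/(1-0.8) = 20$.

## The Bayesian observer models

Three sequential observers are fit to a phase's feedback sequence. All share
the same priors and updating; they differ only in what they assume about AD
trials:

* **Active** — knows which trials are AD and models their feedback as
  $\mathcal{N}(\mathrm{other}(1-c),\ \sigma_\mathrm{other}(1-c))$, and normal
  feedback as
  $\mathcal{N}(\mathrm{self}\cdot c + \mathrm{other}(1-c),\
  \sqrt{\sigma_\mathrm{self}^2c^2 + \sigma_\mathrm{other}^2(1-c)^2})$.
* **Ignorant** — treats every trial, including AD trials, as normal.
* **Passive** — knows which trials are AD but discards them.

Priors follow the rating semantics: the mean parameters are Gaussians centred
on the first-trial ratings with SD 30 (0.3 for control) — wide enough that
the central 90% interval of the initial self belief spans 98.70 score units —
and the performance variabilities $\sigma_\mathrm{self}, \sigma_\mathrm{other}$
have half-normal(5) priors. In the Self-Other phase control is clamped to the
instructed level; in the Control-Other phase the self level is clamped to its
known value with $\sigma_\mathrm{self} = 5$. From the 12th trial of a phase
the other player's level changes unannounced, and the observer re-estimates
the other as a new player: the other's prior is re-centred on the most recent
posterior mean with the SD reset to 30 (the least-informative choice
consistent with "a new other"; the joint dependence between the other and the
remaining parameters is dropped at the reset).

### Inference backend

`fit_learner()` uses a deterministic dense-grid filter. The joint posterior
lives on a product grid — scores in steps of 2 on 0–100, control in steps of
0.02 on 0–1, and 8 sigma points on a uniform grid over $[1, 18]$ weighted by
the half-normal prior density — and each trial multiplies in one likelihood
term. Because the likelihood factorises over trials, this is identical to
refitting the model to trials $1..t$ at every $t$. Bounded grids implement
the constraint that estimates live on their supports (truncation by support,
not post-hoc clipping). Numerical choices worth knowing:

* The sigma support's lower bound of 1 keeps the likelihood bounded
  (feedback is displayed at integer resolution, so sub-unit performance
  variability is not identifiable); the brute-force oracle used in the tests
  integrates over the same support, since the support is part of the model.
* Likelihood SDs are floored at 0.5 score units, which guards the degenerate
  corner $c = 1$ on AD trials.
* Credible intervals are central posterior-quantile intervals from the grid
  marginals (linear CDF interpolation between grid points); tests compare
  posterior means against a $\ge 200$-points-per-dimension brute-force
  summation and agree within 2% of each parameter's range.
* A passive fit whose usable-trial set is empty (an all-AD prefix) reports
  its prior summaries with a `prior_only` flag rather than failing.

The scalar per-trial **uncertainty** is the mean credible-interval width over
what is being learnt: $(\mathrm{CI}_\mathrm{self} +
\mathrm{CI}_\mathrm{other})/2$ in Self-Other,
$(100\,\mathrm{CI}_\mathrm{control} + \mathrm{CI}_\mathrm{other})/2$ in
Control-Other (control widths rescaled to score units). For Self-only trials,
used only by the simulator's AD policy, the self width stands in.

## The synthetic cohort

`simulate_participant()` wraps an Active learner in a behavioural shell:

* **Ratings** are the current posterior means plus truncated-Gaussian
  read-out noise (SD 5 score units, 0.05 for control by default); first-trial
  ratings are gut feelings (mid-scale with SD 15 for new quantities, the
  carried belief for known ones) and seed the priors, as the rating semantics
  require.
* **AD policy**: each trial is an AD trial with probability
  $\mathrm{clip}(b + g\,u/100,\ 0,\ 1)$, where $u$ is the current
  uncertainty; on Self-only trials the probability is multiplied by 0.15,
  since AD is uninformative there. The defaults ($b = 0.05$, $g = 0.65$) were
  calibrated once so the cohort reproduces the task's observed regime —
  roughly a quarter of paired-phase trials are AD against ~3% of Self-only
  trials — and then frozen.
* **Game performance**: objective errors are half-normal (scale 10 error
  units); errors beyond the AD threshold (4 scale units) score zero and are
  flagged AD, while smaller errors map through a decreasing logistic whose
  scale is calibrated by numerical integration so the expected non-AD score
  equals the scheduled self level. The mapping keeps the trial ranking of
  errors while pinning the mean to the schedule.
* The other player's trial score is $\mathcal{N}(\text{level},\ 6.5)$
  truncated to 0–100.
* Cohorts draw per-agent parameters from uniform ranges
  (`cohort_params_prior()`), and the post-session debrief item — the
  reported per-game AD count — is the true count plus rounded Gaussian noise,
  floored at zero.

One master seed derives independent per-participant streams, and identical
seeds give bit-identical tables.

### The canonical schedule

`default_schedule()` fixes the true levels for every simulated participant
(a within-participant design). Its values follow the design principle that
the schedule must decorrelate the quantities being inferred:

* self levels $\{40, 60\}$ are crossed 2×2 with Control-Other control
  $\{0.25, 0.75\}$, so the control-per-feedback-difference slope is observed
  at both self levels — this is what identifies the *feedback difference ×
  inverse self* interaction that separates the three learners;
* Control-Other other levels are chosen so the mean normal-trial feedback
  implies the same mid-scale control signal in every block; a learner that
  ignores AD trials therefore gains no block-level control information from
  normal feedback alone, which is exactly the contrast the learner comparison
  needs;
* other levels jump by at least 20 points at the unannounced change on the
  12th trial of each paired phase.

`generate_schedule()` produces randomized schedules under structural
constraints instead, for sensitivity analyses; identifiability of the
learner-comparison contrast is only guaranteed for the canonical design.

## Behavioural measures and regressions

`derive_measures()` adds the estimated feedback (ratings combined through the
feedback rule, with the instructed control standing in during Self-Other),
the total prediction error $\mathrm{tPE} = \mathrm{feedback} -
\widehat{\mathrm{feedback}}$ and its unique linear split
$\mathrm{sPE} = \mathrm{tPE}\cdot c$, $\mathrm{oPE} = \mathrm{tPE}(1-c)$
(so $\mathrm{sPE} + \mathrm{oPE} = \mathrm{tPE}$ holds exactly), rating
errors and accuracies (error normalised by the largest error possible at the
true level; control errors enter summed errors ×100 in Control-Other),
rating updates, lagged AD indicators, the normal-minus-AD feedback
difference on switch trials, and $\mathrm{inverse\ self} =
\ln(1/\mathrm{self\ rating})$ with ratings floored at 1 (a rating of 0 is
legal; $\ln(1/0)$ is not).

All regressions z-score the outcome and every predictor — including binary
indicators — on the analysed subset after trial selection, so coefficients
are standardized betas. The registry (`fit_trialwise_regression()`) covers
credit assignment (rating updates on the previous trial's tPE, control and
their interaction; kept when the previous trial is a normal Self-Other trial,
since the lagged tPE is undefined otherwise), and the uncertainty and
summed-rating-error models with AD indicators lagged one and two trials,
trial number, the other-change indicator and phase.

`fit_control_inference()` is the learner-discriminating analysis: on
Control-Other switch trials, the next trial's control estimate is regressed
on the feedback difference, inverse self, their interaction, and the previous
control. The deterministic default fits per participant and t-tests each term
across participants; `hierarchical = TRUE` fits one lme4 random-slope model
instead (the mixed model replaces a Bayesian hierarchical fit; with the weak
priors involved the read-out is equivalent at this scale). Participants with
fewer than 3 usable switch trials are excluded. For model-based runs
(`variant_control_series()`), only the *outcome* series comes from the
refitted variant; the regressors stay at the observed ratings, so all
variants face an identical design — using a variant's own converged series as
the previous-control regressor would let the lag term absorb the structural
effect entirely.

## ROI time-course machinery

The imaging-side tools operate on already-extracted ROI time series.
`synth_bold()` builds boxcar regressors from z-scored event values, convolves
them with a canonical double-gamma HRF (response peak 6 s, undershoot 16 s,
undershoot ratio 6), samples at the repetition time (default 1.36 s) and adds
white noise. `epoch_and_upsample()` normalises the series, upsamples ×20 with
cubic splines and cuts −2 to +15 s windows (edge events without full windows
are dropped and counted). `timepoint_glm()` fits an independent OLS at every
upsampled timepoint with a constant plus z-scored regressors, giving one beta
time course per term; the seven registered designs (`roi_design()`) encode
the trial selections — e.g. the direction-split feedback-difference terms on
Control-Other switch trials, whose *sum* contrast reads out order-independent
(normal-minus-AD) coding and whose *difference* contrast reads out
order-dependent (current-minus-previous) coding.

`loo_peak_test()` selects, for each participant, the peak of the
leave-one-out mean absolute beta time course within 4–10 s (the absolute
value handles negative effects such as control updates; flat windows take the
earliest point with a warning), extracts the held-out participant's beta
there, and t-tests the extracted values against zero.

### A known limitation of the leave-one-out read-out

The leave-one-out selection removes first-order selection bias: the held-out
series never influences its own read-out time, so each extracted value has
expectation zero under the null (the suite's leakage test permutes a held-out
series and checks its peak time is unchanged). It does not, however, make the
subsequent one-sample t-test exactly calibrated: participant $i$'s data still
enters the other $n-1$ participants' selection averages, all leave-one-out
averages nearly coincide, and the extracted values end up positively
correlated. A one-sample t-test on positively correlated, zero-mean values is
anti-conservative: the acceptance suite measures the null rejection rate of
the full epoch→GLM→read-out pipeline over 500 white-noise replicates and
finds it several times the nominal $\alpha = 0.05$, while a fixed,
data-independent read-out time is exactly calibrated. The suite states the
calibrated-[0.03, 0.07] expectation and fails it honestly; treat the procedure's p-values as descriptive and prefer
pre-registered read-out times when calibration matters.

## What the simulations do and do not show

Problem sizes used throughout the tests: 30-agent cohorts on the canonical
144-trial schedule for the cohort-level properties; 50 replicate phases for
parameter recovery (the measured mean absolute errors sit several-fold
inside the ±0.1 control / ±8 score-unit acceptance bands); 500 null
replicates for the read-out calibration study; 20 seeds of the full
synthesise→epoch→fit→read-out loop for sign recovery.

The generator reproduces the task's structure, the AD regime, the learner
separation, and the uncertainty/error dynamics around AD trials. It does not
emulate everything about real raters. In particular, agents are noisy-optimal
Bayesians: with a realistic AD rate they resolve the self/other/control
ambiguity, so their component-rating accuracy improves *more* over a phase
than their estimated-feedback accuracy — the opposite of human raters, whose compensating errors in the
latent attributions persist while their feedback tracking improves. The
initial estimated feedback is also near-ceiling here, because mid-scale gut
ratings combine into a mid-scale expectation while the canonical schedule
keeps feedback mid-scale by design. Passing cohort tests therefore certify
the pipeline and the learner comparison, not human-likeness of every
accuracy-trajectory contrast. Reaction times, per-game visual AD criteria
(a single error threshold stands in for them) and end-of-block teammate
choices are out of scope.
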