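---
title: "Modelling dynamic self-esteem from social-evaluation feedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dynamic self-esteem from social-evaluation feedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esteemdyn)
```

## The scientific problem

State self-esteem — how good you feel about yourself right now — reacts to
social feedback, and it reacts most strongly to feedback you did not expect.
`esteemdyn` treats momentary self-esteem as the read-out of a learning
process: people hold expectations about how likely different groups of
others are to approve of them, update those expectations from prediction
errors, and feel better or worse in proportion to an exponentially decaying
sum of those errors. The package implements that account end to end on a
probabilistic social-evaluation task, together with everything needed to
test it without human data: a task generator, generative agents, likelihood
machinery, synthetic cohorts with coupled symptom scales, and a canonical
correlation analysis that extracts a trans-diagnostic "interpersonal
vulnerability" dimension.

## The task and its constraints

A session has 184 trials in three blocks. Each trial shows one of 184
unique raters (sex-balanced) and a color cue identifying the rater's group;
the four groups approve on 85/70/30/15% of their feedback trials. Each
group contributes 40 feedback trials (so approvals are exactly 34/28/12/6)
and 6 no-feedback trials, giving 80 approvals, 80 disapprovals and 24
no-feedback outcomes per session. Self-esteem probes follow 78 trials, at
inter-probe gaps of 2 or 3 trials (fifty 2s, twenty-eight 3s — the gaps
tile the 184 trials exactly). Cue order is constrained: no color more than
twice in a row, and no color absent for more than 7 trials. `build_session()`
satisfies these constraints by sequential sampling with forced placements
at recurrence deadlines and seeded restarts (capped at 10,000); because the
constraints are loose, a handful of restarts suffices in practice.

Design choices where the task description leaves room:

* **No-feedback trials** are split 6 per group, keeping cue exposure equal.
* **The recurrence clock is anchored at the session start** (a virtual
  occurrence at trial 0), so every color must also *first* appear within 7
  trials. Without this anchor a color can legally be absent for dozens of
  opening trials, which contradicts the intent of continuous cue exposure.
* **Blocks** are 62/61/61 trials; outcome proportions are exact per session
  and only approximate per block.
* **Modelable probes**: fitting uses ratings "preceded by choices". The
  session's first probe is excluded, then the first remaining probe of
  every block (block 1's being the session's second probe) — four
  exclusions, leaving 74 of 78 probes. The rule is deterministic and
  configurable; it reflects the view that a probe straddling a session or
  block boundary has no immediately preceding evaluative context.

## The model family

All models share the exponential-kernel rating model: at a probe following
trial $t$,

$$\text{esteem}(t) = w_0 + w_1 \sum_{j \le t} \gamma^{\,t-j}\, \mathrm{SPE}_j + \epsilon,
\qquad \epsilon \sim N(0, \sigma),$$

with $\mathrm{SPE}_j = \mathrm{SF}_j - \mathrm{ESV}_j$ and feedback coded
$+1/-1/0$. Expectations evolve by $\mathrm{ESV} \leftarrow \mathrm{ESV} +
\eta\,\mathrm{SPE}$ on revealed-feedback trials, and choices follow the
biased softmax $\pi_L = \mathrm{logistic}((\mathrm{ESV} +
\mathrm{ESV}_0)/T)$. The variants:

| id | description | likelihood | k |
|----|-------------|-----------|---|
| M1 | learning + response bias | choices + ratings | 9 |
| M2 | learning, no bias | choices + ratings | 8 |
| M3 | no learning, correct initial beliefs ($2p-1$) | choices + ratings | 6 |
| M4 | M1 + separate expectation kernel ($w_2$) | choices + ratings | 10 |
| M5 | no learning, free initial beliefs | ratings only | 6 |
| M6 | outcome valence only (kernel over SF) | ratings only | 4 |

M3 is listed elsewhere with seven parameters; with learning off and the
initial expectations fixed, only six parameters ($w_0, w_1, \sigma,
\mathrm{ESV}_0, T, \gamma$) are actually free, and the package counts — and
penalises in BIC — what it actually fits.

Parameter conventions and further choices:

* **Rating scale**: self-esteem ratings live on $[0, 1]$ (visual-analogue
  endpoints), which matches the magnitudes of the default baseline
  ($w_0 = 0.73$) and noise ($\sigma = 0.08$). Expected social values live
  on the $[-1, 1]$ feedback-coding scale, so M3's "correct" initial beliefs
  are $2p - 1 = (0.7, 0.4, -0.4, -0.7)$.
* **No-feedback trials** produce $\mathrm{SPE} = -\mathrm{ESV}$ (feedback
  coded 0), which enters the self-esteem kernel but does **not** update
  expectations: an undisclosed opinion carries no information about a
  rater's disposition. Choices still occur — and enter the likelihood — on
  those trials.
* **Missed trials** are dropped entirely: no choice term, no kernel
  contribution, no learning update; the kernel index runs over non-missed
  trials in session order.
* **Simulation truncates** ratings to $[0, 1]$, but the likelihood uses the
  untruncated Gaussian density, matching the additive-noise reading of the
  generative equation. With $\sigma \approx 0.08$ and predictions well
  inside the interval the difference is negligible; at extreme parameters
  the likelihood is mildly misspecified relative to the simulator.
* In M4 the package keeps $w_1$ on the prediction-error kernel in every
  model and gives the separate expectation kernel its own weight $w_2$.

The recursion $S_t = \gamma S_{t-1} + \mathrm{SPE}_t$ implements the kernel
sum; `kernel_states(..., method = "sum")` exposes the explicit form, and
the two agree to $10^{-12}$ (tested on 1,000 random sequences).

## Fitting

`fit_esteem()` maximises the joint log-likelihood — Bernoulli over
non-missed choices plus Gaussian log-density over the 74 modelable ratings
($n = 258$ observations for M1–M4; ratings only, $n = 74$, for M5/M6) —
with flat priors. Bounded parameters are optimised through transforms
(logit for $\eta, \gamma$; log for $\sigma, T$, floored at $10^{-6}$);
initial expectations and the weights are unconstrained. Optimisation is
BFGS with relative tolerance $10^{-8}$ from 10 seeded restarts (the first
from the default parameter point, the rest uniform over plausible ranges);
the best restart wins and disagreement above $10^{-3}$ in log-likelihood
raises a multimodality warning. Goodness of fit is reported as squared
Pearson correlations (ratings and choices separately) and the rating MSE;
the definition of $r^2$ is a convention choice, stated here because
variance-explained alternatives differ when predictions are biased.

Parameter recovery under the default generative conditions (40 subjects
drawn from the default means/SDs, truncated at the stated bounds) returns
group-mean estimates of $w_0, w_1, \eta, \gamma, \mathrm{ESV}_0$ within one
generative SD of the generating means — the test suite measures this; it
is a group-level guarantee, not a per-subject one. Individual-level
identifiability is genuinely limited: with slow learning, a response bias
and shifted initial beliefs trade off almost perfectly in the choice
channel.

That trade-off matters for model selection. The BIC sanity check (true
model wins within its likelihood family) is run under a generating regime
where the bias is identifiable — learning fast enough ($\eta = 0.15$) to
anchor late-session expectations to the feedback coding, tight rating noise
($\sigma = 0.05$), moderate temperature — because under very slow learning
the 8-parameter no-bias model mimics the 9-parameter model to within less
than the BIC penalty, and BIC then correctly prefers it. A selection test
in that regime would measure the penalty arithmetic, not the machinery.

## Synthetic cohorts

`draw_cohort()` draws each parameter independently from a truncated
Gaussian around its default mean (baseline 0.73 (0.16), SPE weight 0.04
(0.03), noise SD 0.08 (0.04), learning rate 0.04 (0.08), forgetting 0.66
(0.35), bias 0.42 (0.25), temperature 0.12 (0.35), initial-belief average
0.64 (0.24) and range 0.34 (0.29)). Truncation bounds — $\eta, \gamma \in
[0,1]$, $\sigma, T \in (0.005, 2]$, $w_0 \in [0,1]$, others mean $\pm 4$ SD
— are a design choice; truncation shifts some means (the truncated mean of
$w_0$ is 0.711, not 0.730), which the tests account for analytically.
Initial beliefs are drawn as average and range and converted to the
group-1/group-4 values with clipping to $[-1, 1]$.

A latent standard-normal **vulnerability factor** can shift parameter means
via a coupling vector; the default sign pattern lowers baseline self-esteem
and average initial beliefs and raises the SPE weight and the initial-belief
range. Eleven symptom scales load on the same factor — self-evaluation
scales negatively, interpersonal-sensitivity/anxiety/depression scales
positively — with unit total variance, so generated scores are already
z-scaled. Loading magnitudes (0.3–0.8) are plausibility choices, set once.
What the generator does **not** emulate: empirical parameter covariance
beyond the single shared factor, item-level questionnaire structure,
test–retest error, missing data, and any dependence of missedness on state.
Passing tests therefore show the pipeline is correct and calibrated, not
that real cohorts satisfy the one-factor structure.

## Behavioural summaries

`esteem_change_by_condition()` computes probe-to-probe rating changes and
attributes each to the most recent revealed-feedback trial in the window
(configurable to all intervening trials): the group × valence cell means
reproduce the expectation signature — the largest increases after approval
from the least approving group, the largest decreases after disapproval
from the most approving group. `valence_partial_correlation()` pools
transitions across subjects (per-subject pooling available), correlates
changes with outcome valence, residualises on valence by least squares and
correlates the residuals with the pre-outcome expectation; on
prediction-error agents the valence correlation is positive and the
partialled expectation correlation negative.

## Canonical correlation analysis

`cca_preprocess()` replaces the two initial-belief parameters with their
average and range, log-transforms parameter columns failing a Shapiro–Wilk
normality screen at $\alpha = 0.05$ (offset $10^{-6} - \min$ when needed;
the screen is a convention choice), and z-scores all columns.
`esteem_cca()` solves the standard eigenproblem, reports Wilks' lambda with
Rao's F approximation per dimension, rescales weights so every canonical
variate has unit variance, and fixes each dimension's sign so the trait
self-esteem coefficient is negative — "higher score = more vulnerable" is
then reproducible, where raw CCA is sign-arbitrary. Subject scores are the
symptom-block variate, following the view of the vulnerability dimension as
a re-weighting of symptoms maximally aligned with the computational
parameters. With blocks of 9 and 11 variables the solution is data-hungry;
the function warns when $n < 5 \times$ the larger block, and the planted
cohort's implied first canonical correlation has a closed form
(`planted_canonical_correlation()`) that is exact when the coupled
parameters' bounds are wide enough for truncation to be negligible — the
recovery tests widen exactly those bounds for that reason.

## Event regressors

`export_event_regressors()` emits the parametric modulators of two
event-related GLM layouts: expectations at choice onset, prediction errors
at feedback onset and ratings at probe onset; or inferred self-esteem at
choice (pre-feedback kernel state) and feedback (post-feedback state) plus
ratings. Modulators are z-scored within session; constant modulators are
dropped with a warning. Onsets are trial indices — the package has no
scanner timing; supply a timing map downstream for second-based events.

## Problem sizes and numerical conventions

The shipped tests use 40 subjects for parameter recovery, 10 per cohort for
model comparison, 30 (≈2,200 pooled transitions) for the behavioural
signature, 250 for planted-CCA recovery and 300 replicates of $n = 60$ for
null calibration — sizes at which every targeted property is comfortably
resolvable on a single CPU. Degenerate inputs are handled explicitly:
zero-variance ratings make $r^2$ `NA` with a warning rather than an error,
constant columns are refused by the z-scorer with the column named,
temperature and noise SDs must be strictly positive, and session
construction fails with the violated constraint named when a design is
infeasible. Sub-seeds for cohort members are derived deterministically from
the master seed, so every pipeline stage is bit-reproducible given
`(inputs, config, seed)`.

## Known limitations

Individual-subject estimates of weakly identified parameters (bias,
initial beliefs, temperature under near-deterministic choice) should be
interpreted at the group level. The likelihood ignores rating truncation.
Only the single-factor symptom structure is generated, so CCA tests cannot
detect misbehaviour specific to multi-factor symptom spaces. Hierarchical
(random-effects) fitting, Bayesian posteriors and alternative information
criteria are out of scope.
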