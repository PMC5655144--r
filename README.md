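# esteemdyn

Computational modelling of **dynamic self-esteem during social evaluation**,
for researchers in computational psychiatry and social neuroscience.

In the underlying task a participant faces 184 strangers ("raters") sorted
into four color-cued groups that approve of 85%, 70%, 30% and 15% of
profiles. On each trial the participant predicts whether the rater liked
them, then sees approval, disapproval, or (on 24 trials) no feedback; every
2–3 trials they rate their momentary self-esteem on a visual-analogue scale
(78 ratings per session). `esteemdyn` implements the full analysis pipeline
around that task with no external data: session generation, a six-model
family of generative agents, joint maximum-likelihood fitting with BIC model
comparison, synthetic cohorts with symptom scales, model-free behavioural
summaries, a canonical correlation analysis linking parameters to symptoms,
and export of trial-by-trial event regressors.

## The model

Expectations about approval from group *k* (**expected social value**,
ESV) follow Rescorla–Wagner learning from **social approval prediction
errors** (SPE), with feedback coded +1 / −1 / 0:

    SPE_t        = SF_t − ESV_t
    ESV_k,t+1    = ESV_k,t + η · SPE_t          (revealed feedback only)
    π_L          = 1 / (1 + exp(−(ESV + ESV0) / T))

where `η` is a learning rate, `ESV0` a response bias (the persistent
willingness to predict being liked), and `T` a decision temperature. State
self-esteem is an exponentially decaying sum of recent prediction errors:

    Self-esteem(t) = w0 + w1 · Σ_{j≤t} γ^(t−j) · SPE_j + ε,   ε ~ N(0, σ)

with baseline `w0`, update weight `w1` and forgetting factor `γ`. Initial
expectations for groups 1 and 4 are free parameters; groups 2 and 3 are
spaced equally in between. Model variants drop learning (M3, M5), the bias
(M2), add a separate expectation kernel (M4), or reduce to outcome valence
only (M6); M5/M6 are fitted to ratings alone. Fits are compared by
`BIC = ln(n)·k − 2·ln(L̂)`, summed over subjects.

## Worked example

```r
library(esteemdyn)
session <- build_session(session_config(), seed = 1)
agent   <- agent_params()     # group-level default parameters
sim     <- simulate_agent(session, agent, model = "M1", seed = 2)
fit     <- fit_esteem(sim$record, model = "M1", n_restarts = 10, seed = 3)
fit
#> Self-esteem model fit (M1)
#>   logLik 59.15 on k = 9 parameters, n = 258 observations; BIC -68.324
#>   r2 ratings 0.287, r2 choices 0.331, mse 0.00692
#>   parameters:
#>          w0          w1       sigma       gamma         eta        esv0
#>       0.786       0.041       0.083       0.736       0.006      -0.290
#> temperature   esv1_init   esv4_init
#>       0.038       0.758       0.501
```

The fit maximises the joint likelihood of 184 predictions and 74 modelable
self-esteem ratings (`n = 258`). `r2 ratings` is the squared correlation
between model-predicted and observed self-esteem; `mse` is the mean squared
rating error; the recovered `w1 = 0.041` and `gamma = 0.736` say this
synthetic subject's self-esteem moved about 0.04 rating-scale units per
unit prediction error, with each error's influence decaying by roughly a
quarter per trial. `plot(fit)` overlays the predicted trajectory on the
observed ratings; `compare_models(records, c("M1","M2","M3","M4"))`
tabulates summed BICs across a cohort; `esteem_cca()` links fitted
parameters to symptom scales and returns Wilks'-lambda inference and
subject vulnerability scores.

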