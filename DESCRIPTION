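Package: esteemdyn
Title: Dynamic Self-Esteem from Social-Evaluation Feedback
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling moment-to-moment self-esteem during a
    probabilistic social-evaluation task. Generates task sessions with four
    rater groups of differing approval probability, simulates agents whose
    approval expectations follow Rescorla-Wagner learning and whose state
    self-esteem is an exponentially decaying sum of social approval
    prediction errors, fits a six-model family by joint maximum likelihood
    over choices and self-esteem ratings with BIC model comparison, builds
    synthetic cohorts with symptom scales coupled to a latent vulnerability
    factor, computes model-free behavioural summaries, links model
    parameters to symptom scores by canonical correlation analysis with
    Wilks' lambda inference, and exports trial-by-trial event regressors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
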