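Package: prognet
Title: Generative Progression Modelling of Chronic Disease from
    Longitudinal Diagnosis Codes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits a three-layer generative model of chronic-disease
    progression to longitudinal ICD-10 encounter records: a forward-only
    continuous-time Markov jump process over latent disease stages, a set
    of irreversible stage-conditioned complication onset chains, and a
    noisy-or Bayesian network linking active complications to observed
    diagnosis codes.  Expert "anchor" codes prune the observation network
    to one parent per anchored code, which shrinks the activation-layer
    parameter count and pins the identity of each complication category.
    Parameters are learned by Monte Carlo EM with blocked Gibbs sampling;
    the package also provides maximum a posteriori trajectory inference
    for individual patients, synthetic-cohort generation from a fitted
    model, and retrospective complication statistics over generated
    cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
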