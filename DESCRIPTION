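Package: rtbisurv
Title: Bayesian Latent Class Analysis for Recurrent Traumatic Brain Injury
    Surveillance in Administrative Claims
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate administrative-claims surveillance case
    definitions for recurrent traumatic brain injury (rTBI) without a gold
    standard. Implements a synthetic claims-stream generator with latent
    recurrence, four ICD/billing-based case definitions applied over a
    7-365 day post-index window, a two-class Bayesian latent class model
    fitted by Gibbs sampling with data augmentation (optional logistic sex
    covariate on the latent prevalence), propagation of upstream
    incident-cohort uncertainty by refitting across predicted cohorts and
    pooling posterior draws, posterior predictive checks of pairwise
    case-definition agreement, prior-sensitivity analysis, and closed-form
    derived quantities: predictive values, Rogan-Gladen adjusted incidence,
    and crude and adjusted median time to recurrence.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    coda
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
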