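Package: disambig
Title: Social Credit Assignment, Active Disambiguation and Controllability Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how agents assign credit for shared outcomes to
    themselves, to other agents, and to their level of control. Implements the
    generative rules of a joint-performance task (control-weighted feedback,
    logistic performance mapping, active-disambiguation semantics, block/phase
    schedules), an agent-based synthetic cohort simulator, three sequential
    Bayesian observer models (Active, Ignorant and Passive learners) fitted by a
    deterministic dense-grid filter with credible-interval uncertainty read-outs,
    the derived behavioural measures and trial-wise regressions (prediction-error
    decomposition into self and other portions, uncertainty and rating-error
    effects of active disambiguation, feedback-difference control inference), and
    ROI time-course GLM machinery (double-gamma HRF synthesis, epoching with
    cubic-spline upsampling, per-timepoint OLS, leave-one-out peak tests).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
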