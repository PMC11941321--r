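Package: cogwell
Title: Quantum-Well Modelling of Cognitive Activity Under Information Influence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the cognitive activity of an individual as an information
    image oscillating in a one-dimensional finite potential well. Provides
    closed-form state functions inside and outside the well, a
    Gaussian-windowed cosine pulse representing an external information
    influence of a second modality, numerical integration of the
    self-oscillatory equations of motion with a regularized barrier impulse
    and exit-threshold detection, parameter sweeps and univariate slices of
    the perturbed state function, least-squares parameter fitting by local
    descent and by adaptive discrete grid search with random multi-start,
    and a seeded synthetic emulation of a multimodal affective-rating (SAM
    valence) experiment for end-to-end testing of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
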