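Package: chromafill
Title: Opponent-Channel Color Perception with Poisson Filling-In and
    Spiking Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models color perception as the weighted combination of low-pass
    single-opponent channel responses and surfaces filled in from double-opponent
    (chromatic edge) responses. Filling-in is the steady-state Poisson equation
    driven by the discrete Laplacian of the stimulus, solved by an exact sparse
    solver, by explicit iteration, or by a recurrent spiking neural network built
    on Neural Engineering Framework principles. Includes a single-scale
    non-logarithmic Retinex baseline, generators for the synthetic stimuli used to
    characterize the model (uniform squares, color-assimilation grids, tinted
    scenes), spatial activation-profile extraction, and CIE 1976 u'v' chromaticity
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
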