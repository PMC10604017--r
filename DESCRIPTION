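Package: ramanmf
Title: NMF Unmixing and Model Selection for Raman Hyperspectral Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Unmixes Raman hyperspectral maps of immobilized-enzyme systems
    with a ladder of non-negative matrix factorization (NMF) models fitted by
    multiplicative updates under the Frobenius norm. Each resolved component
    spectrum is scored against a reference spectral library by cosine
    similarity, and the optimal model order is selected by explicit
    data-driven criteria: every species present must be resolved, the
    assigned similarities must be highest, and among near-equivalent models
    the most parsimonious one is preferred. Includes the full preprocessing
    chain used for Raman maps (asymmetric least-squares baseline removal,
    Savitzky-Golay smoothing, non-negativity clipping, min-max
    normalization), reconstruction of concentration profiles into
    per-species chemical images, a ground-truthed synthetic scene generator
    for validation, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    signal,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
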