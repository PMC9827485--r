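Package: hemoscore
Title: Cytologic Hemosiderin Scoring and Annotator Agreement for Equine
    Pulmonary Hemorrhage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the total hemosiderin score (THS) used to diagnose
    exercise-induced pulmonary hemorrhage (EIPH) from iron-stained
    bronchoalveolar lavage cytology. Implements THS computation and the
    diagnostic cut-off, point-annotation matching and grade
    standardization against a reference annotation set, variance-component
    decomposition of interobserver error in a fully crossed slide-by-rater
    design with intraclass correlations and error-reduction summaries, an
    80% diagnostic uncertainty interval around the cut-off, consensus and
    diagnostic-accuracy summaries, rank correlations with bronchoalveolar
    lavage chemistry, a synthetic-study generator (slides, biased
    annotators, chemistry, rendered iron-stained images), and a rule-based
    cell detection and grading stage for rendered images.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    clue,
    lme4,
    EBImage,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
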