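Package: engageEEG
Title: Engagement-State EEG Analysis with Synthetic Driving-Task Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of an EEG engagement-state analysis
    pipeline contrasting active manual control with passive replay viewing
    under two task-complexity levels. Provides a synthetic multichannel EEG
    generator with planted, parameterised condition effects and coherent
    inter-regional coupling; deterministic preprocessing (re-referencing,
    zero-phase FIR filtering, epoching, baseline correction, leakage-safe
    normalisation); a toy-geometry distributed minimum-norm inverse with
    dSPM noise normalisation, loose orientation and depth weighting;
    band-power, ERD/ERS, correlation and magnitude-squared-coherence
    metrics; Daubechies-4 wavelet sub-band features with pairwise
    coefficient coherence; purged grouped cross-validation,
    leave-one-subject-out evaluation and cross-mode transfer with a
    random-forest classifier; and a statistical layer with t-tests,
    Cohen's d, Benjamini-Hochberg FDR families, bootstrap confidence
    intervals and Fisher's p-value combination.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    Biobase,
    S4Vectors,
    SummarizedExperiment,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'engageEEG-package.R'
    'AllClasses.R'
    'accessors.R'
    'utils.R'
    'classify.R'
    'features.R'
    'inverse.R'
    'io.R'
    'oscillations.R'
    'stats.R'
    'preprocess.R'
    'simulate.R'
    'pipeline.R'
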