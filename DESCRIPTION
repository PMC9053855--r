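Package: sinpipe
Title: Analysis Pipeline for Intracranial Speech-in-Noise Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Re-implements, over synthetic data with known ground truth, the
    analysis chain of a human intracranial speech-in-noise study:
    high-gamma Hilbert-envelope extraction from multichannel iEEG,
    spectrotemporal receptive field (STRF) estimation by normalized reverse
    correlation with cross-validated regularization and sparseness,
    corticocortical evoked potential (CCEP) connectivity mapping with
    N1-based directed graphs and shortest-path information flow,
    speech/nonspeech population discriminability via Kruskal-stress
    multidimensional scaling and per-site t scores, and behavioral scoring
    of stimulation versus sham trials (keyword intelligibility and mean
    opinion score with Wilcoxon rank-sum comparisons). Includes generators
    for every input the pipeline consumes so all stages are testable
    without patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    vegan
Config/testthat/edition: 3
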