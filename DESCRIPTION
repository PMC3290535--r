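Package: nucleofit
Title: Model-Based Nucleosome Positioning from Stranded Short-Read Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts nucleosome positions from MNase-Seq or sonicated
    ChIP-Seq single-end read data. Candidate genomic regions are segmented
    from stranded 5' read positions and, within each region, forward and
    reverse read positions are modelled as a bidirectional mixture of
    Student-t (4 df) densities whose component centers carry a
    Gaussian-Markov-random-field spatial prior encouraging regular
    nucleosome spacing; fragment lengths and read-position variances carry
    Normal-Gamma priors. Models are fitted by an EM/MAP algorithm with an
    exact tridiagonal solve for the spatially coupled center update, the
    number of nucleosomes is chosen by a penalized log-likelihood, and
    calls are scored, control-normalized, assigned empirical false
    discovery rates, and screened by an adaptive negative-binomial
    low-density filter. Downstream utilities classify transcription-factor
    binding sites by nucleosome modality, build occupancy profiles, and
    benchmark callers with read subsampling and truncated ROC/AUC curves.
    A seeded generative simulator reproduces the model's data-generating
    process for testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    Rsamtools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: NucleosomePositioning, ChIPSeq, Epigenetics, Sequencing,
    Bayesian, PeakDetection
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'config.R'
    'downstream.R'
    'evaluate.R'
    'io.R'
    'model.R'
    'nucleofit-package.R'
    'postprocess.R'
    'preprocess.R'
    'pipeline.R'
    'simulate.R'
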