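Package: PolrScreen
Title: Differential Interaction Scoring and Occupancy Profiling for RNA
    Polymerase Complexes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@polrscreen.org",
           role = c("aut", "cre"))
Description: Statistical pipeline for probing the biogenesis of multi-subunit
    RNA polymerases with affinity-purification mass spectrometry (AP-MS) and
    ChIP sequencing. Implements spectral-count differential-interaction
    scoring for a bait shared between two polymerase complexes (bait
    normalization, noise imputation of zero counts, empty-vector based
    high-confidence interactor filtering, paired ratio t-tests with
    Benjamini-Hochberg correction and dual significance gates) and
    TSS-anchored, promoter-class-stratified aggregate occupancy profiles
    with input subtraction for comparing wild-type and mutant subunit
    binding over Pol III target genes and an rDNA control. Ships a
    synthetic-data generator emulating both assay types so the full pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, ChIPSeq, Coverage, Software
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
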