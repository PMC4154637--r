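Package: pep2path
Title: Mass-Spectrometry-Guided Genome Mining of Peptidic Natural Products
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Matches mass-spectrometry-derived peptide sequence tags to the
    biosynthetic gene clusters that encode them. For nonribosomal peptides
    (NRPs), a Bayesian log-likelihood score compares each (possibly
    degenerate) tag position against adenylation-domain substrate
    specificity predictions (Stachelhaus code identity plus nested SVM
    class calls) over every assembly-line configuration, contiguous
    alignment and tag orientation of every cluster in a database, with a
    colinearity index to aid interpretation. For ribosomally synthesized
    and post-translationally modified peptides (RiPPs), degenerate tags are
    matched against six-frame translations of genome sequences with a
    sliding window. Includes tag parsing from amino-acid strings or
    mass-shift lists, database construction, merging and taxonomic
    filtering, seeded synthetic-data generators with planted ground truth,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Software, Proteomics, MassSpectrometry, GenomeAnnotation
RoxygenNote: 7.3.3
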