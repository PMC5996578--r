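Package: neuropeptidome
Title: Neuropeptide Precursor Discovery and In Silico Prohormone Processing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discovery of neuropeptide precursor genes in transcriptome
    assemblies of molluscan nerve ganglia, and downstream characterisation
    of their peptide products. Provides six-frame translation and
    getorf-style open-reading-frame extraction, a translated local-alignment
    homology screen against a panel of known precursors, de novo candidate
    classification from signal-peptide, basic cleavage-site, C-terminal
    amidation and cysteine-pattern criteria, an in silico prohormone
    processing engine releasing mature peptides with amidation and
    pyroglutamate annotations, a declarative peptide-family rulebook with
    position-frequency summaries, modification-aware matching of mass
    spectrometry peptide observations, and Nei-Gojobori (NG86) Ka/Ks
    selection-pressure analysis. A seeded synthetic-transcriptome generator
    with a ground-truth manifest makes the whole pipeline testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
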