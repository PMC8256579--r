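Package: gptSpectra
Title: Mutation Spectrum Analysis for gpt delta Transgenic Rodent Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for reporter-gene mutation data from the gpt
    delta transgenic rodent assay: calls mutations in 6-thioguanine-resistant
    colony sequences by global alignment against the gpt coding sequence,
    left-aligns indels in homopolymer runs, classifies events into the six
    strand-normalized base-substitution classes plus indel categories with
    CpG/GpG/A-run context, computes mutant and clonally corrected independent
    mutation frequencies, builds per-group spectrum and A-run tables, calls
    mutation hotspots by multi-animal support, and compares groups with exact
    Fisher and Tukey-Kramer statistics. A synthetic-assay generator emulates
    the group design, titers, weighted spectra and within-animal clonal
    expansion of such studies so the whole pipeline runs without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Software, Genetics, SomaticMutation, Alignment
RoxygenNote: 7.3.3
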