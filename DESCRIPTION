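Package: karyoprobe
Title: In-Silico Design and Modelling of FISH-Based Karyotyping Probes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building fluorescence in situ hybridization (FISH)
    karyotyping systems from genome assemblies, modelled on the common bean
    (Phaseolus vulgaris) system. Selects chromosome-specific single- or
    low-copy BAC clones from end-sequence alignment tables (identity,
    coverage, orientation and insert-span criteria, repeat-content
    screening), discovers chromosome-specific satellite monomer variants by
    k-mer window profiling against a consensus, designs short oligo probes
    with genome-wide mismatch-tolerant specificity counts, assembles
    multi-fluorophore probe cocktails, and models multi-channel karyotype
    signal maps to compute chromosome distinguishability and compare
    karyotypes across accessions and species. A seeded synthetic-genome
    generator with planted satellite arrays and BAC libraries provides
    ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
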