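Package: mispredqc
Title: Consistency-Rule Quality Control for Predicted Protein Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Flags likely gene-prediction errors in sets of predicted
    protein sequences by checking each protein's annotated features
    against eleven consistency rules (the MisPred rules): obligatory
    extracellular, cytoplasmic and nuclear Pfam domains versus secretory
    signal peptides, signal anchors and transmembrane helices; domain
    size integrity; interchromosomal chimerism of the encoding exons;
    GPI-anchor logic; and known domain architectures. Provides parsers
    for the standard output formats of the upstream predictors (HMMER3
    domtblout, SignalP, PrediSi-style tables, TMHMM, Phobius, DGPI-style
    tables, BLAT PSL), a consensus membrane-topology layer, loaders for
    the three reference registries the rules depend on, a deterministic
    synthetic-corpus generator with planted conflicts for end-to-end
    testing, and tidy per-protein and corpus-level reporting with
    ggplot2 graphics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
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
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
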