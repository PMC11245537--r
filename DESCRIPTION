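Package: repab
Title: Integrated B-Cell Receptor Repertoire and Serum Antibody Proteomics
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantifying B-cell receptor (BCR) repertoire features
    from bulk and single-cell AIRR Rearrangement tables: unweighted V-gene
    usage with pairwise Pearson correlation, CDR3 amino-acid Jaccard overlap,
    Hill-number evenness profiles, and light-chain coherence. Supports
    cumulative merging of single-cell technical replicates to study sampling
    depth, and maps serum antibody peptides from bottom-up mass spectrometry
    to personalized BCR reference databases for clonotype identification,
    clonal-rank and class-switch annotation, and single- and paired-chain
    V(D)J sequence reconstruction. A seeded synthetic generator produces
    repertoires, paired-chain single-cell data, serum samples, in-silico
    protease digests, contaminants and decoys so the whole pipeline can be
    exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
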