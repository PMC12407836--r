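Package: crispanel
Title: Off-Target Site Integration, Amplicon Panel Design and Base-Edit
    Quantification for CRISPR Editors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates CRISPR off-target cut-site nominations from empirical
    assays (dsODN-marking/GUIDE-seq-style) and in-silico prediction tools into
    a single ranked, annotated candidate list for targeted amplicon panels.
    Nominated positions are clustered by greedy proximity, re-aligned to the
    sgRNA spacer with support for DNA and RNA bulges and PAM prioritization,
    scored by per-source Z-standardization and a user-editable criterion
    weight table, and tiered into a panel. Base-editing outcomes at nominated
    protospacers are quantified per position from aligned amplicon reads or
    pileups, with SNP masking against no-editor controls and
    replicate-supported truth sets. Method-comparison statistics (Bray-Curtis
    dissimilarity, principal coordinate analysis, top-k rank concordance,
    precision/recall, exact 2x2 tests) and a seeded synthetic-data generator
    with planted ground truth are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    GenomicRanges,
    IRanges,
    methods,
    purrr,
    readr,
    rlang,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
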