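Package: coampscan
Title: Coverage-Based Inference of Co-Amplified Sex-Chromosome Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers Y-chromosome gene amplification and X/Y gene
    co-amplification from male versus female genomic read coverage over a
    peptide reference. Computes windowed read depth per peptide, normalized
    median male/female coverage ratios and Y-amplification calls; detects
    X-linked duplicates of the parent coding sequence from nucleotide
    alignment hit tables; assigns genomic scaffolds to Muller elements by
    gene content and classifies them as X-linked, autosomal or Y-linked
    from coverage ratios, flagging neo-sex (X-autosome fusion) elements;
    combines the evidence into co-amplified gene calls with Y copy-number
    estimates and exact enrichment tests; and screens stranded testis
    expression data for antisense transcription and endo-siRNA production.
    A seeded synthetic-data generator provides ground-truth cohorts with
    the Poisson copy-number depth structure the callers assume, so the
    whole pipeline is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    withr
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
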