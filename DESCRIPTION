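Package: mtmeth
Title: Mitochondrial DNA CpG Methylation Analysis from Nanopore Per-Read Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for mitochondrial DNA CpG methylation measured by
    nanopore single-molecule sequencing. Classifies per-read, per-CpG-group
    log-likelihood ratios into methylated/unmethylated/ambiguous calls, aggregates
    them into per-site methylation frequencies with split-group, strand and
    base-caller pass/fail stratification, corrects frequencies using the
    false-positive rate estimated from an unmethylated long-range PCR amplicon
    control, filters putative NUMT reads by alignment length, annotates CpG sites
    with mitochondrial genes, and runs the cohort comparisons (Mann-Whitney U,
    Spearman correlation). Includes a seeded synthetic-data generator emulating
    per-read methylation-call tables with known ground truth, dilution series,
    amplicon controls, NUMT contaminants and qscore-methylation coupling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    dplyr,
    readr,
    tibble,
    tidyr,
    withr,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
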