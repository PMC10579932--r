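Package: methylgraft
Title: Whole-Genome Bisulfite Methylome Profiling and Windowed DMR Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for whole-genome bisulfite sequencing (WGBS)
    methylome analysis in non-model invertebrates, built around a
    control-versus-treatment (e.g. pre- versus post-grafting) design.
    Computes weighted methylation levels in CG, CHG and CHH contexts from
    per-cytosine call tables, profiles methylation across gene features
    (upstream 2 kb, first/internal/last exons and introns, downstream 2 kb)
    and regulatory tracks (CpG islands, repeats), tabulates 7-mer sequence
    preference around methylated cytosines, detects differentially
    methylated regions (DMRs) by windowed two-group Fisher exact testing
    with iterative merging of interdependent windows, assigns DMRs to genes
    (gene body and promoter), performs hypergeometric term enrichment of
    DMR-associated genes, and analyses bisulfite-sequencing-PCR (BSP)
    clones against a reference amplicon with conversion-rate QC and
    lollipop summaries. A fully deterministic synthetic-methylome
    generator with planted DMRs provides ground truth for end-to-end
    validation without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
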