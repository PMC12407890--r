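Package: clonotracer
Title: Clonal Barcode Calling and Allelic-Imbalance Analysis for Barcoded
    Kras G12D Single-Cell Lineage Tracing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-cell lineage tracing with synonymous-mutation
    barcodes engineered into the Kras G12D allele. Covers design and sampling
    of the degenerate barcode library over a codon window, simulation of
    targeted 10x-style amplicon reads with ground truth, per-molecule barcode
    calling from paired FASTQ (cell barcode/UMI parsing, linked-adapter
    trimming, semi-global edit-distance matching), per-cell UMI collapsing
    with directional edit-distance barcode merging, dominant-clone assignment
    and allelic-state classification, paired Kdm8 transcript genotyping with
    zero imputation and bimodal positivity calling, and clone-by-state
    analytics (Sankey link tables, clone sharing between lesions, exact
    two-sided Fisher enrichment tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
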