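Package: polyacall
Title: Polyadenylation Site Identification, Usage Quantification and apaQTL Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Identifies polyadenylation (PAS) sites and quantifies polyadenylation
    site usage (PAU) from long-read alignments carrying non-templated polyA tails
    and from 3'-end-sequencing read coverage. Soft-clipped tails are classified by
    length and adenosine composition, internally primed (misprimed) reads are
    removed by genomic flank scanning, cleavage events are aggregated into
    100-nt PAS windows with per-gene usage compositions, and 3'-Seq peaks are
    called by convolution with the second derivative of a Gaussian. Includes
    positional hexamer and GT-content quality control with Fisher enrichment
    tests, cross-method benchmarking (site matching, Sum|dPAU| error, ROC/AUC,
    proximal/distal shift statistics), a cis apaQTL scan with inverse-normal
    quantile normalization, principal-component confounder removal, direct
    permutation FDR and Storey pi1 sharing estimation, and a synthetic-data
    generator that plants ground-truth PAS sites, polyA tails, mispriming
    decoys, coverage peaks and genotype-linked usage shifts for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
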