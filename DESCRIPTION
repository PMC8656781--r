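Package: methseas
Title: Differential DNA Methylation Analysis of Paired Tumor-Normal
    Samples with CpG Island and MicroRNA Gene Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of paired tumor/normal DNA methylation
    array data: beta-value computation from methylated/unmethylated
    intensities, probe filtering (sex chromosomes, SNP proximity,
    non-unique mapping), sequence-based CpG island detection with
    shore/shelf/open-sea neighborhood classification, functional gene
    region annotation (TSS200/TSS1500/UTR/exon/body), per-site paired
    Wilcoxon signed-rank testing with Westfall-Young step-down maxT
    family-wise error control, hyper/hypomethylation direction calls,
    signed fold-change candidate selection for microRNA genes,
    chromosome-by-region cross-tabulation, and hypergeometric pathway
    over-representation analysis. Includes a synthetic-data generator
    producing genomes with planted CpG islands, gene models, probe
    manifests and paired beta matrices with known ground truth, so the
    full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    fgsea,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
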