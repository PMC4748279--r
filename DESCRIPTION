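Package: lincnet
Title: Functional Annotation of lincRNAs via Competing Endogenous RNA Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers competing endogenous RNA (ceRNA) networks from
    miRNA-target tables and expression matrices, and uses them to
    functionally annotate long intergenic non-coding RNAs (lincRNAs).
    RNA pairs sharing significantly many miRNA regulators (hypergeometric
    upper-tail test) and showing significant positive Spearman correlation
    become network edges; dense communities are mined with a from-scratch
    implementation of the MCODE molecular-complex detection algorithm;
    communities and lincRNAs are annotated by GO over-representation with a
    three-tier fallback rule (community term, neighbor enrichment, neighbor
    majority); differentially expressed hub lincRNAs are reported as key
    lincRNAs. Includes a synthetic-data generator that plants known ceRNA
    modules so the whole pipeline can be validated against ground truth,
    plus lincRNA candidate filtering and transcript feature summaries from
    GTF/FASTA input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    yaml,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
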