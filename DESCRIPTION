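Package: nlrarch
Title: Domain Architecture Analysis of Plant NLR Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide analysis of nucleotide-binding leucine-rich-repeat
    (NLR) plant resistance proteins from InterProScan domain annotations.
    Mines candidate NLRs by tracked InterPro accessions (NB-ARC and four
    LRR entries), classifies proteins into nine architecture classes
    (N, CN, TN, L, CL, TL, NL, CNL, TNL) from the presence of NB-ARC,
    LRR, coiled-coil and TIR domains, counts exact domain co-occurrence
    combinations (UpSet-style), computes per-group unique-domain sets with
    unions, intersections and exclusivity, embeds aligned sequences by
    difference scores and classical metric multidimensional scaling, and
    summarizes chromosome-window gene density. Includes a seeded synthetic
    proteome generator with planted architectures and motifs so the whole
    pipeline is testable offline, plus packaged summary tables for nine
    Fabaceae species.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
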