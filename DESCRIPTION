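Package: pasurveil
Title: PA-Seq Analysis of Adenylated RNA Surveillance Substrates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pipeline for polyadenylation-site sequencing (PA-seq) analysis of
    nuclear RNA surveillance substrates in knockdown-versus-control designs.
    Simulates paired-end PA-seq libraries over a toy genome with planted
    ground-truth adenylation sites, demultiplexes and orients TTT-tagged
    3'-end mates, maps read pairs with a mismatch-tolerant k-mer mapper,
    tallies strand-aware single-nucleotide adenylation sites with
    internal-priming (templated adenosine) filtering and reads-per-million
    normalization, calls adenylation peaks by Gaussian kernel density with a
    narrow-peak classification, and performs differential adenylation
    analysis including pri-miRNA 5' leader detection at Drosha cleavage
    sites, snoRNA 3'-end offset profiles, and rRNA 5'ETS processing-site
    quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    data.table,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
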