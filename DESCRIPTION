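Package: codonscope
Title: Codon Usage Bias Analysis for Transcriptome Coding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for codon usage bias analysis of transcriptome-scale
    coding sequence (CDS) sets. Computes nucleotide composition and silent-site
    statistics (GC1/2/3, GC3s, A3s/T3s/G3s/C3s), relative synonymous codon usage
    (RSCU), Wright's effective number of codons (ENc) with the expected-ENc curve,
    the codon adaptation index (CAI), codon bias index (CBI) and frequency of
    optimal codons (Fop); identifies optimal codons from RSCU differences between
    high- and low-bias gene sets with chi-square support; counts duplex codon
    (codon pair) preferences and compares them across species; estimates Ka, Ks
    and omega for ortholog pairs with a Nei-Gojobori (1986) estimator; and runs
    correspondence analysis, correlation matrices, cross-species RSCU clustering
    and PCA. Includes a seeded synthetic-transcriptome generator with tunable
    GC3-ending bias, expression coupling and planted divergence, so the whole
    pipeline is exercisable end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
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
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
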