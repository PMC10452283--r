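Package: orthosnp
Title: Cross-Species Coding-Sequence Conservation and Human Disease SNP Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for evaluating mammalian model organisms against the
    human genome at the coding-sequence (CDS) level. Identifies CDSs conserved
    between human and five model species (rhesus macaque, marmoset, pig, mouse,
    rat) via identity- and coverage-filtered best-hit local alignment, aligns
    each conserved ortholog group across all six species, projects human SNP
    catalog positions through the gapped alignments with major-allele matching,
    classifies disease-associated SNPs as conserved or species-specific across
    24 disease categories, and derives a concatenation-based neighbor-joining
    phylogeny and human-referenced synteny maps. Includes a synthetic-data
    generator that evolves six-species orthologous CDS sets along a known tree
    with planted SNP and disease catalogs, so the whole pipeline can be run and
    validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
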