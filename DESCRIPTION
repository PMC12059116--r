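Package: phygrow
Title: Hybrid Codon-Usage and Phylogenetic Prediction of Microbial Maximum Growth Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts microbial maximum growth rates (expressed as doubling
    times in hours) from genome sequences and a reference phylogeny. A
    codon-usage-bias regression (MILC of annotated ribosomal proteins against
    the genome-wide background, optionally temperature-corrected) is combined
    with phylogenetic trait prediction (nearest-neighbour averaging and
    Brownian-motion best linear unbiased prediction) through a logistic gate
    trained to weight whichever component is expected to perform better for a
    given query. Includes phylogenetically blocked cross-validation for
    honest evaluation across phylogenetic distances, Blomberg's K and Pagel's
    lambda phylogenetic-signal statistics, and a fully seeded synthetic-data
    generator (Yule trees, traits with tunable phylogenetic signal, and
    codon-biased coding sequences) so the whole pipeline can be exercised
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    picante,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
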