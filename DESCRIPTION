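Package: treestab
Title: Stability and Reproducibility Statistics for Gene-Family Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bootstrap statistics for judging how trustworthy an inferred
    phylogeny of a duplicated gene family is. Builds neighbor-joining trees on
    p-distances (the NJp method), computes per-branch bootstrap support (Pb),
    the stability (Ps) of a clade's rooted subtree topology, and the
    reproducibility (Pr) of topologies between two paralogous gene families
    related by gene or genome duplication. Includes a Jukes-Cantor sequence
    simulator for generating duplicated-family test fixtures and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    optparse,
    phangorn,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
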