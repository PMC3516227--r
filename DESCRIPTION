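Package: mosaicTE
Title: Detecting Horizontal Transfer of DNA Transposons from Mosaic
    Phylogenetic Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting horizontal transfer of Tc1/mariner-type
    DNA transposons between host lineages, such as the repeated exchange
    of a Tc1 transposase element between lampreys and teleost fishes.
    Implements the full desk analysis: harvesting element copies by
    similarity search, greedy assembly of overlapping fragments,
    majority-rule consensus construction, open-reading-frame annotation
    and codon-excision peptide deduction for disrupted copies, alignment
    filtering, neighbor-joining and GTR+Gamma likelihood phylogenetics
    with constrained-topology Kishino-Hasegawa/RELL tests, bootstrap
    support, identity-distribution grouping of element families,
    Nei-Gojobori Ka/Ks neutrality checks, Dollo parsimony loss counting
    under vertical transmission, and nesting-based transfer calls. A
    simulator of transposable-element family evolution on a host tree
    (proliferation bursts, neutral decay, injected horizontal transfers
    with known ground truth) provides the validation substrate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    ggplot2,
    jsonlite,
    phangorn,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
SystemRequirements: mafft
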