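Package: crocmhc
Title: MHC Class II Amplicon Validation, Selection and Trans-Species
    Polymorphism Analysis for Crocodylians
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing clonal amplicon sequences of MHC class II
    alpha and beta exons across crocodylian species. Implements clone-read
    consensus building and artifact filtering (PCR point errors, chimeras,
    near-redundant singletons), Klein-style variant naming, open-reading-frame
    annotation and pseudogene calling, trans-species polymorphism detection
    and tallying by genus, Nei-Gojobori synonymous/nonsynonymous counting with
    codon-based Z-tests, site-wise Bayesian dN/dS estimation under an
    NY98-style codon model, recombination screening (max-chi-square and
    triplet scans, Watterson theta and composite-likelihood rho), distance
    phylogenetics (model selection by pruning likelihood, neighbor joining,
    nonparametric bootstrap, RELL-based expected likelihood weights, clade
    diagnostic sites), a clone-sampling coverage model, and a multigene-family
    amplicon simulator with full ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    digest,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
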