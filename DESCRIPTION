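Package: tandemr
Title: Simulation of Tandem Mass-Isotopomer Distributions in Atom-Mapped
    Metabolic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Efficient simulation of tandem mass-isotopomer (MS/MS)
    distributions of metabolite fragment pairs at isotopic steady state,
    given an atom-mapped metabolic network model, a flux vector and the
    isotopomer distributions of media metabolites.  A minimal set of
    metabolite fragment pairs is identified by recursive network
    traversal, grouped into strongly connected components, topologically
    ordered, and solved as a cascade of small linear flux-balance
    systems in which condensation reactions enter through Cauchy
    products of fragment-pair distributions.  Brute-force isotopomer and
    cumomer oracles are included for validation, together with shipped
    toy and methionine-metabolism fixtures and seeded random network
    generators for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
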