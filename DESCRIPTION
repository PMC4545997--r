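Package: caronet
Title: Evolution of Carotenoid Metabolic Networks on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing how robustness (redundant dietary
    pathways) and elaboration (metabolic pathway elongation) trade off
    in avian carotenoid metabolic networks evolving on a phylogeny.
    Builds per-species minimum and maximum metabolic networks from
    compound inventories, computes metabolic distances and
    neighbour-joining phylogenies, compares trees by Robinson-Foulds
    distance, evaluates knockout robustness and biochemical scope
    expansion, runs degree-preserving null models, fits two-state
    gain/loss models to reconstruct ancestral networks, and simulates
    network evolution on birth-death trees, including a dietary-rescue
    generative mode.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
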