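Package: apoRecon
Title: Ancestral Reconstruction of the Eukaryotic Apoptosis Machinery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs the gene content of the last eukaryotic common
    ancestor (LECA) for the core apoptosis machinery from protein-family
    phylogenetics. Curates profile alignments (HMM-style match/insert column
    handling, redundancy and novelty filters, profile merging), infers
    neighbor-joining gene trees with bootstrap support from Poisson-corrected
    protein distances, classifies each family's origin relative to eubacteria
    and archaea, detects paralog divergences that predate eukaryogenesis, and
    reconstructs ancestral presence across the eukaryotic supergroups by
    Dollo parsimony and an explicit multi-supergroup parsimony rule.
    Simulators for gene-content evolution, protein sequence evolution and
    endosymbiotic transfer scenarios provide ground truth for every stage,
    and curated presence/absence matrices for the apoptotic DNases,
    caspases/metacaspases, OMI/HTRA proteases, AIF oxidoreductases and
    apoptosis inhibitors are bundled.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    Biostrings,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
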