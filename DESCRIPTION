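Package: matmine
Title: Mining Mating-Type Loci and Pheromone Genes from Fungal Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rule-based discovery and annotation of fungal mating genes from
    genome assemblies. Implements terminal CAAX/CPAX prenylation-motif
    screening for a-factor pheromone candidates, a processing-site grammar
    (KEX1/2 and STE13) for annotating mature repeats in alpha-factor
    pro-pheromones, six-frame translated local-alignment homology search
    with microsynteny anchoring, MAT-locus assembly and thallism
    classification (heterothallism, primary homothallism, mating-type
    switching by inversion or deletion, and HMG-only strategies),
    hydropathy-based seven-transmembrane receptor quality control, RPKM
    expression summaries, and two-state Markov ancestral-state
    reconstruction of mating strategy on a fixed phylogeny. A synthetic
    genome simulator with planted ground truth supports end-to-end
    validation of every detector.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
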