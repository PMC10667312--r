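Package: ScrambleDisome
Title: Simulation and Analysis of SCRaMbLE Rearrangements in Disomic Synthetic Yeast
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying aneuploidy relief by Cre/loxPsym recombination
    (SCRaMbLE) on a synthetic yeast chromosome carried in a disomic background.
    Provides a segment-level model of a loxPsym-partitioned chromosome, a
    calibrated simulator of deletion/inversion/duplication/circularization
    events under centromere-plus-marker selection, generation of
    sequencing-style evidence (segment depths, junctions, wild-type:synthetic
    read ratios) with the circular-molecule recovery bias, reconstruction of
    rearranged structures from evidence by Eulerian traversal of a segment
    adjacency graph, minimal-event parsimony decomposition, fitness estimators
    (colony-size growth recovery, sliding-window doubling time), a
    chromosome-wide deletion-versus-fitness association scan, and gene-dosage /
    environmental-stress-response expression scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, StructuralVariation, CopyNumberVariation, GeneExpression, Sequencing
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'structure.R'
    'events.R'
    'utils.R'
    'simulate.R'
    'evidence.R'
    'segment-map.R'
    'expression.R'
    'fitness.R'
    'reconstruct.R'
    'pipeline.R'
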