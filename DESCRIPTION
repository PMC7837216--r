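Package: eif2bquant
Title: Quantitative Analysis of eIF2B Conformational States, Ligand
    Binding Kinetics, and Antagonistic Allostery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify conformational differences between
    multi-chain eIF2B complex structures (rigid-body superposition,
    helix-axis rotation, ligand-pocket deformation metrics computed
    from mmCIF or PDB coordinate files), to fit the standard regression
    models used for nucleotide-exchange and ligand-binding assays
    (exponential decays, biphasic association/dissociation, saturation
    binding, four-parameter logistic dose-response), and to simulate an
    equilibrium linkage model in which ISRIB binding at one site
    antagonizes phosphorylated-eIF2 binding at two coupled regulatory
    sites.  A synthetic-data generator produces coordinate fixtures with
    known injected motions and signal traces with known parameters, so
    the whole pipeline can be validated without downloading structures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
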