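Package: RetroMHCII
Title: Reversed-Peptide Template Generation for MHC Class II Complexes
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Converts canonically bound peptides in peptide-MHC class II
    structures into chemically valid reversed (C-terminus to N-terminus)
    peptide templates by exact coordinate geometry: backbone carbonyl and
    amide mirroring through alpha-carbon midpoints, terminal-group
    reconstruction, D-to-L chirality correction, proline ring rebuilding and
    a restrained bonded-geometry regularizer that holds the MHC receptor
    fixed. Includes receptor-frame Kabsch superposition with binding-core
    ligand RMSD, automated geometry quality control, an ideal-geometry
    peptide fixture builder, and batch construction of reversed-template
    databases from PDB files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: StructuralPrediction, Proteomics, ThirdPartyClient, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cli.R'
    'evaluation.R'
    'fixtures.R'
    'geometry.R'
    'regularizer.R'
    'reversal.R'
    'utils-atoms.R'
    'structure-io.R'
    'template-db.R'
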