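Package: samcliff
Title: Activity Cliffs Formed by Single-Atom Modifications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Systematic identification of activity cliffs produced by
    single-atom modifications of bioactive compounds. Curates ChEMBL-style
    compound-activity tables to high-confidence potency data (pKi/pIC50),
    enumerates analog pairs distinguished by a single atom replacement
    (N-C, O-C, N-O, S-O) or by a single heteroatom positional walk, calls
    activity cliffs at a configurable (default 100-fold) potency
    difference, and associates cliffs with X-ray complex structures by
    canonical-SMILES ligand matching against local PDB mapping tables.
    Includes a synthetic benchmark generator with planted analog pairs and
    cliffs, and an exhaustive brute-force oracle certifying the indexed
    pair enumeration. Molecule standardization and canonical SMILES are
    computed with OpenBabel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
SystemRequirements: OpenBabel (>= 3.0), 'obabel' on the PATH
Config/testthat/edition: 3
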