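Package: plgicmap
Title: Binding-Site Mapping and Conformational Analysis of Pentameric
    Ligand-Gated Ion Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for structure-based analysis of ligand binding sites in
    pentameric ligand-gated ion channels (Cys-loop receptors).  Reads
    experimental coordinate files, derives residue-level correspondences
    between homologous chains from an annotated master alignment or by
    sequence-independent secondary-structure matching, performs Kabsch
    least-squares superposition with RMSD bookkeeping at domain, subunit
    and pentamer granularity, detects ligand-contact residues and
    classifies bound ligands into a ten-class binding-site taxonomy,
    transfers annotated sites across structures with steric-occlusion
    scoring, quantifies pocket geometry across conformational states, and
    clusters oligomer conformations.  A synthetic pentamer generator with
    planted ground truth makes every stage testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
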