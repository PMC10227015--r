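Package: dckdesign
Title: Structure-Guided Analog Design and Assay Analysis for a dCK
    Inhibitor Campaign
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a dictionary-driven, structure-guided hit-to-lead
    campaign around a seed inhibitor of deoxycytidine kinase (dCK).
    Implements combinatorial analog enumeration from a generic
    modification dictionary (functional groups, decorated 3- to
    6-membered rings, C/O/N spacers), substructure and physicochemical
    filtering, template-constrained 3D pose evaluation (common-substructure
    mapping, least-squares superposition, van der Waals clash and torsion
    strain scoring), analysis of the campaign's assay readouts (thermal
    shift melting temperatures, coupled-assay velocities, four-parameter
    logistic IC50 with a technical censoring floor, one- and two-site
    isothermal titration calorimetry), and a structure-activity ledger
    with fold-change arithmetic and decision-tree export. Synthetic data
    generators with recorded ground truth support every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    minpack.lm,
    jsonlite,
    yaml,
    bio3d,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
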