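Package: ucdreg
Title: Unique-Structure Chemical Compound Registration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale chemical registration system built around a
    molecule/substance/batch hierarchy. Structures arrive as SMILES or MDL
    molfiles (V2000/V3000 with enhanced stereochemistry collections), are
    standardized and neutralized under a fixed rule set, and are made unique
    at the neutral-structure level through a tautomer-insensitive,
    stereo-group-aware canonical key. Salts and hydrates are modelled at the
    substance level with automatic theoretical-mass arithmetic; batches flow
    through a two-stage submission/registration workflow with role-based
    access, batch reassignment, cascade archiving and a complete audit
    trail. Exact, substructure and similarity search, bulk SDF import and
    export, and physicochemical property calculation (Lipinski and
    lead-like indicators) round out the toolkit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
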