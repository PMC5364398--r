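Package: DNTPore
Title: Trajectory Analysis of Membrane-Spanning DNA Nanotube Pores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for molecular-dynamics trajectories of
    membrane-spanning DNA nanotubes (DNTs): HOLE-style largest-inscribed-sphere
    pore radius profiling and conductance prediction, radial density and
    bilayer-thickness profiles, lipid order parameters, radial distribution
    functions, lumen ion selectivity, lipid-groove residence times, tilt and
    centre-of-mass displacement analyses, steered-MD force-barrier extraction,
    and partitioned r.m.s.d. Includes an idealized six-helix-bundle DNT model
    builder and a synthetic trajectory generator with known ground truth so
    every analysis stage can be exercised without running MD.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'DNTPore-package.R'
    'accessors.R'
    'dialects.R'
    'selection.R'
    'membrane_profiles.R'
    'dynamics.R'
    'io.R'
    'model_builder.R'
    'synthetic_traces.R'
    'synthetic_membrane.R'
    'pore_profile.R'
    'pipeline.R'
    'utils.R'
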