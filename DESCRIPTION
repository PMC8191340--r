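Package: ionsite
Title: Ion Binding-Site Discovery from Trajectories and Proton Flux from pH Traces
Version: 0.1.0
Authors@R:
    person("Ionsite", "Developers", email = "ionsite@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for locating substrate/ion binding sites in
    membrane-transporter permeation cavities from molecular-dynamics-style
    trajectories, and for quantifying proton/base flux from intracellular pH
    recordings. Provides region-based ion occupancy, residence-time and
    entry-event statistics, per-residue ion contact frequencies, voxelized
    ion density maps with grid free energy (GFE) conversion and
    overlap-coefficient map comparison, density-based binding-site detection,
    buffer-capacity and flux calculations with Dunnett many-to-one group
    comparisons, and seeded synthetic-data generators (Markov-state and
    Brownian ion trajectories, pH traces) with closed-form ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    mvtnorm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
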