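Package: poregate
Title: Pore Hydration and Lipid-Mediated Hydrophobic Gating Analysis for
    Ion-Channel Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for molecular-simulation studies of
    hydrophobic gating in ion channels. Profiles the pore radius along the
    permeation axis (inscribed-sphere algorithm, with or without lipid atoms),
    scores water and lipid-tail occupancy of a deep-pore analysis volume
    (sharp and Fermi-smoothed counters), classifies wet/dry hydration states,
    measures pore-lining helix tilt angles, estimates hydration free-energy
    profiles from restrained-sampling mean forces by thermodynamic
    integration with block-average errors, and reweights metadynamics traces
    of a lipid-density collective variable. Ships a synthetic-data module
    that generates channel-like fixtures, restrained-sampling series and
    metadynamics traces with known ground truth, so every estimator can be
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
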