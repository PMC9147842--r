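Package: MicroswitchMD
Title: Contact-Based Analysis of GPCR Activation Microswitches in MD Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies activation-microswitch rearrangements of G-protein-coupled
    receptors (GPCRs) along molecular-dynamics coordinate ensembles. Implements
    per-frame residue-residue contact scores (RRCS) with a piecewise-linear
    distance kernel bounded by 3.23 and 4.63 Angstrom and a backbone-exclusion
    rule for sequence-adjacent residues; van-der-Waals contact detection
    (Bondi radii plus a 0.25 Angstrom slack) and average contact fractions over
    replicate trajectories; a global-effect metric comparing apo and
    ligand-bound contact-fraction profiles over gain and loss residue-pair sets;
    ligand-distance and occupancy-cloud probes and a simplified axis-sweep
    channel-bottleneck estimator with a water-permissiveness criterion;
    Ballesteros-Weinstein residue-label bookkeeping; and a deterministic
    synthetic-trajectory generator with analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    bio3d,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
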