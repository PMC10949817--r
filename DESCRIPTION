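Package: gjdock
Title: Stabilization Centers, Hydrogen Bonds and Pore Geometry of Connexin
    Hemichannel Docking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing toolkit for molecular-dynamics trajectories of
    connexin hemichannels and gap-junction channels. Detects stabilization
    centers (long-range residue contact hubs) per frame and aggregates their
    stability over a run, classifies interactions as intra-subunit,
    inter-subunit or trans-gap-junction, applies categorized geometric
    hydrogen-bond detectors (trans-GJ, Cys-Cys thiol, Cys-interface), assigns
    and detects extracellular Cys disulfide bonds in their oxidized (closed)
    or reduced (open) states, computes extracellular RMSD series after
    transmembrane alignment, profiles the water-accessible pore radius along
    the channel axis, assembles head-to-head hemichannel-pair models from a
    gap-junction template, and summarizes stabilization-center dynamics as a
    residue connectivity graph. Ships a synthetic-structure generator that
    plants ground-truth contacts, hydrogen bonds, disulfide geometries and
    pore profiles so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
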