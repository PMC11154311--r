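Package: rasconf
Title: Conformational State Analysis of GTP-Bound Ras from Molecular
    Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Frame-wise geometric classification of GTP-bound Ras
    trajectories into conformational state 1 and the three Tyr32-orientation
    substates of state 2 (OX, OY, OZ), from five characteristic inter-atomic
    distances around the nucleotide pocket. Includes ensemble statistics per
    (sub)state (occupancies, dwell and transition structure, per-residue
    RMSF, essential-dynamics PCA, dynamic cross-correlation matrices),
    sodium-ion accessibility counts near GTP, membrane reaction coordinates
    (beta1-sheet tilt and E132-L184 distance), and a seeded synthetic
    trajectory generator so the full pipeline is testable without raw MD
    data. Reads PDB structures and DCD or multi-model PDB trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
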