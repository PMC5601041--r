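Package: restcm
Title: EEG Reference Effects on the Dynamic Scalp-Potential Center of Mass
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the choice of EEG reference (reference
    electrode standardization technique (REST), average reference, linked
    mastoids, vertex) shapes the dynamic center of mass (CM) of positive scalp
    potentials. Implements a three-concentric-sphere volume conductor with
    analytic Legendre-series lead fields, REST re-referencing via a
    minimum-norm transfer matrix, positive-CM trajectories and traveling
    velocities, a dipole-grid simulation quantifying per-reference CM error,
    an ERP (visual oddball) analysis chain, a repeated-measures ANOVA /
    Greenhouse-Geisser / Tukey statistical kernel, and a seedable synthetic
    multi-subject oddball ERP cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
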