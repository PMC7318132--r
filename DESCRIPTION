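Package: nacprofiler
Title: Near-Attack-Conformation Accessibility Profiling for P450
    Site-of-Metabolism Selectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Frame-by-frame geometric classification of abstractable
    substrate hydrogens against the Compound I oxo/iron center of a
    cytochrome P450, following the near-attack-conformation (NAC)
    criterion used to score site-of-metabolism accessibility from
    molecular-dynamics ensembles. Provides multi-model PDB trajectory
    input, per-site accessibility profiles with event statistics,
    ensemble per-residue RMSF, Boltzmann weighting of activation
    barriers, a combined accessibility-times-reactivity selectivity
    ranking, and a seeded synthetic trajectory generator with known
    per-site ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
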