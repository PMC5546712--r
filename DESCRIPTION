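Package: dendsig
Title: Spatial Signaling Model and Molecular Signatures of LTP Induction in CA1 Dendrites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mesoscopic reaction-diffusion simulation of calcium- and
    cAMP-activated signaling in a hippocampal CA1 dendrite with spines
    (CaMKII, PKA, Epac, calcineurin, phosphodiesterases, beta-2 adrenergic
    receptor with Gs-Gi switching), together with the stimulation protocols
    (high/low frequency calcium trains, norepinephrine release via a
    Tsodyks-Markram model, bath agonists and antagonists) and a
    threshold-crossing classifier of spine and dendritic molecular
    signatures that predicts early and long-lasting forms of long-term
    potentiation. Provides a stochastic tau-leap/SSA voxel engine, a fast
    deterministic compartmental mode, calibration routines, and synthetic
    fixtures with analytic oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
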