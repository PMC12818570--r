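Package: ghksel
Title: Proton/Potassium Selectivity Analysis for pH-Gated Cation Channels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying H+/K+ selectivity of pH-gated cation
    channels such as lysosomal TMEM175 from whole-cell patch-clamp and
    solid-supported membrane electrophysiology (SSME) recordings.
    Implements Goldman-Hodgkin-Katz permeability-ratio equations based on
    reversal potentials and reversal-potential shifts, extraction of
    reversal potential, chord conductance and current density from
    voltage-ramp sweeps, exponential and Hill fits describing the erosion
    of the transmembrane pH gradient by the channel's own proton flux, a
    biophysical whole-cell simulator of that erosion (GHK fluxes, pH
    gating, buffering, weak-acid loading), SSME peak/charge and pK(A)
    titration analysis, and salt-bridge contact statistics for molecular
    dynamics distance series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    deSolve,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
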