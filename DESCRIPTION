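Package: ranvier
Title: Discrete Cable Model of Saltatory Conduction in Myelinated Axons
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates action-potential propagation along a chain of nodes of
    Ranvier in a myelinated axon using a discrete (FitzHugh-style) cable
    model: lumped nodal capacitances joined by axonal resistances, with
    threshold-gated, time-varying sodium and potassium conductance waveforms
    and a paranodal series resistance separating juxtaparanodal potassium
    channels from the node. Membrane potentials are integrated with the
    explicit Euler method. Includes scenario builders for paranodal injury
    (nodal stretch, myelin detachment, conduction block) and potassium
    channel blockade, conduction-velocity and latency metrics, a node-width
    sweep, a closed-form velocity approximation, and YAML configuration I/O
    with a thin command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
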