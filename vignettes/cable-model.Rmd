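---
title: "A discrete cable model of saltatory conduction and paranodal injury"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A discrete cable model of saltatory conduction and paranodal injury}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ranvier)
```

## The physical picture

In a myelinated axon the action potential does not travel as a continuous
wave: it jumps between the nodes of Ranvier, the ~0.3–1 µm gaps in the
myelin where sodium channels are concentrated.  Potassium channels sit
elsewhere — under the myelin in the juxtaparanodal zones — separated from
the node by the tightly attached paranodal myelin, whose thin
extracellular cleft presents a very large series resistance `R_p` to any
current flowing between juxtaparanode and node.

Mild crush or stretch injury perturbs exactly this architecture, in two
ways that are nearly invisible under a light microscope: myelin retracts
from the node, widening the bare membrane span `s` and therefore the
nodal capacitance `C = C_m·2πr_a·s`; and paranodal myelin detaches
radially, collapsing `R_p` by one or more orders of magnitude and letting
early outward potassium current reach the node.  This package quantifies
what those two lesions do to conduction velocity.

## Model structure and assumptions

The axon segment is a FitzHugh-style discrete cable: `n` lumped nodal
capacitances joined by equal axoplasmic resistances
`R_a = ρ_a L/(π r_a²)`.  The assumptions, stated up front:

* **Internodal myelin is a perfect insulator.**  Internodal leakage would
  shift currents and voltages by only a few percent and is ignored.
* **The extracellular return path is free.**  The endoneurial sleeve's
  resistance `R_e = ρ_e L/(2π r_e h)` is ~1% of `R_a` for realistic
  anatomy; `extracellular_resistance()` exists to verify that ratio for a
  given geometry, and the network then sets it to zero.
* **Conductance waveforms are stereotyped, not voltage-gated.**  Each ion
  species follows `G(t′) = a t′² e^(−bt′)` on the node's local clock
  `t′ = t − τ_j`, started when the node crosses threshold.  There is no
  Hodgkin–Huxley gating, no inactivation, no refractoriness: this is a
  single-pulse model.
* **Nodes activate at most once**, in threshold order; the rightmost node
  is clamped at the resting potential as an absorbing boundary.
* **Deterministic anatomy.**  All nodes share one geometry except for the
  explicit per-node injury overrides.

The waveform's quadratic-rise form is a reconstruction from its
documented properties: the amplitude constant's units
(ohm⁻¹cm⁻²s⁻²) require a `t′²` factor, and the fit
`b = 2/t*`, `a = e²G*/t*²` reproduces all four published constants from
the peak coordinates (Na: a = 2.07×10⁷ vs 2.1×10⁷ printed, b = 2×10⁴
exactly; K: a = 3.84×10⁵ vs 3.8×10⁵, b = 4×10³ exactly — the printed
values are rounded).  `fit_kinetics()` performs that fit;
`channel_kinetics()` also accepts raw `(a, b)`.

Sodium current uses the sodium-channel span `s*`, which injury does *not*
change — channels stay where they were before the myelin retracted — so a
stretched node has a larger capacitance but the same current source.
Potassium current sees the paranodal resistance in series with the
juxtaparanodal membrane conductance `g_K`:

$$ i_K = (V - E_K)\,\frac{g_K}{1 + g_K R_p}. $$

At `R_p = 0` this reduces to the same form as the sodium current; as
`R_p → ∞` it vanishes.  At normal parameters `g_K R_p ≈ 65` at the
conductance peak, so the healthy paranode suppresses potassium current
~60-fold — which is why collapsing `R_p` is so damaging.

## Parameters

All internal quantities are in cm / s / ohm / farad / volt, so every
formula above is used literally; configuration files carry µm / mV / µs
keys and convert only at the boundary.  Defaults describe a
textbook-normal axon:

| parameter | default | meaning |
|---|---|---|
| `d` | 1.0 µm | axon diameter |
| `s` | 0.65 µm | bare node width (mid-range of 0.3–1 µm) |
| `s*` | = `s` | sodium-channel span, fixed under injury |
| `λ` | 5.0 µm | juxtaparanodal span, both sides of the node |
| `L` | 1 mm | internodal distance (so `L/s` ~ 1500) |
| `ρ_a` | 200 Ω·cm | axoplasm resistivity |
| `C_m` | 1 µF/cm² | specific membrane capacitance |
| `R_p` | 3.2×10¹⁰ Ω | paranodal resistance, normal |
| `V_rest`, `V_th` | −85, −50 mV | resting and threshold potentials |
| `E_Na`, `E_K` | +67, −95 mV | equilibrium potentials |
| Na kinetics | t\* = 0.1 ms, G\* = 0.028 S/cm² | textbook peak |
| K kinetics | t\* = 0.5 ms, G\* = 0.013 S/cm² | textbook peak |

Two parameter notes.  The juxtaparanodal span is described in different
places as "ten times the nodal length" (6.5 µm) and "ten times the axon
radius" / 5.0 µm; every concrete experiment uses 5.0 µm, which is the
default here.  The extracellular resistivity `ρ_e` is never printed; it
defaults to the axoplasmic value, and matters only for the `R_e ≪ R_a`
check.

The derived scales worth knowing: `R_a ≈ 2.55×10⁹ Ω`,
`C ≈ 2.0×10⁻¹⁴ F`, so the discharge time constant
`R_aC = 4ρ_a L C_m (s/d) ≈ 52 µs` — and indeed the simulated normal chain
passes threshold from node to node every ~54 µs, i.e. 18.7 m/s over 1 mm
internodes.

## Numerical scheme

Explicit Euler, `V_j ← V_j + Δt·dV_j/dt`, at Δt = 0.1 µs over 2 ms by
default (20,000 steps × 21 nodes; well under a second on one core).
Choices that matter:

* **Threshold detection on the grid.**  `τ_j` is the first grid time with
  `V_j ≥ V_th`, no sub-step interpolation; at Δt = 0.1 µs the
  interpolation error is ~0.2% of an internodal delay.  Halving Δt moves
  every activation time by < 0.1%, consistent with first-order
  convergence.
* **Node 0's stimulus is its own kinetics.**  No current is injected;
  `τ_0 = 0` simply starts node 0's conductance clocks, and the sodium
  waveform depolarises it from rest.  Node 0 also keeps its full ionic
  terms (the no-left-neighbour equation is otherwise identical to the
  interior one).
* **Stability guard.**  |V| > 1 V aborts with advice to reduce Δt (the
  passive stability bound is Δt < 2R_aC ≈ 100 µs, but accuracy demands
  far less).
* **Degenerate inputs.**  Zero peak conductance yields an identically
  zero waveform (no division hazards in the fit); `g_K = 0` short-circuits
  the series formula; a node that never activates keeps `t′ = −∞` and
  contributes no ionic current.
* **Block classification needs a long enough window.**  A node that would
  fire after `t_max` is indistinguishable from a blocked one;
  `detect_block()` warns when the last activation falls in the final 10%
  of the window.

## Injury and treatment scenarios

`scenario_spec()` fixes the canonical experiments on a 21-node chain with
nodes 8–20 injured: stretch ×3 (`crush`), stretch + `R_p`×0.1
(`crush_detach`), stretch + `R_p`×0.01 (`block`), and block + 80%
potassium blockade everywhere (`treated`, the 4-aminopyridine analogue,
implemented as `block_factor = 0.2` multiplying the peak conductance).
Velocity is read at nodes 4–5 (normal region) and 15–16 (injured region),
after the wave has stabilised — internodal intervals settle to within ~2%
after three nodes.

Representative results at the defaults (all recomputed by the test suite
and `scripts/acceptance.R`, never hard-coded): normal 18.7 m/s; crush
7.6 m/s injured / 18.6 m/s normal region; detachment 6.2 m/s; block —
wave dies at node 9; treated — conduction restored through the injured
region at 6.9 m/s.  Node-10 latency grows from 0.58 ms to 0.82 ms (+42%)
under crush-plus-detachment, with only three injured nodes on the path.

One boundary artifact deserves mention: the last interior node sits next
to the resting-clamped terminal node, which loads it.  Under severe
injury (detachment and treated scenarios) that final node never reaches
threshold however long the window — restoration of conduction is
therefore judged by the wave traversing the measurement region (node 16
and beyond), not by every node firing, and `detect_block()` output for
those chains reflects the artifact.

## The node-width sweep and the closed-form estimate

`sweep_node_width()` applies a width uniformly (with `s* = s`, the
uninjured morphology) and records velocity.  The closed form
`v ≈ L/(αR_aC) = r_a/(2αρ_aC_m s)` predicts `v ∝ 1/s` exactly, with α
"near 0.5".  The full simulation confirms the monotone, convex decrease
but not strict hyperbolicity: over s ∈ [0.3, 2.0] µm simulated velocity
falls roughly as `s^−0.5`, so the product `v·s` drifts by ~2.5× while `s`
varies 6.7×, and the effective α fitted per width runs from ~0.6 to ~1.5.
The closed form is a trend statement — it ignores potassium current, the
finite sodium rise time, and the threshold's position between rest and
peak — and the tests treat it as such.

## What the scenarios do and do not emulate

The scenario generator reproduces idealised study conditions: identical
nodes, sharp injury boundaries, deterministic parameters, single pulses.
Real axons add anatomical dispersion, graded injury, temperature and
channel-density variation, internodal leakage, and compound action
potentials summed over fibre populations — none of which are modelled.
Passing tests therefore certify the electrical mechanism (capacitance
widening and paranodal shunting slow and block saltatory conduction, and
potassium blockade partially compensates), not quantitative predictions
for any particular preparation.

## Known limitations

* Single pulse only: no refractory period, no re-arming, no trains.
* Stereotyped kinetics: no voltage dependence or inactivation, so
  phenomena like accommodation are out of reach.
* Euler integration is part of the specified method; no adaptive or
  implicit solver is offered.
* The published latencies are printed in seconds ("0.57 sec"); a 19 m/s
  wave needs ~0.5 ms to reach node 10, so these are read as milliseconds
  throughout.  The discrepancy is noted rather than silently corrected.
* The terminal resting clamp distorts the last interior node (above).
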