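# ranvier

Discrete cable model of saltatory conduction in myelinated axons, for
computational neurophysiologists studying how subtle paranodal injury —
myelin retraction that widens the bare node of Ranvier, and paranodal
detachment that unmasks juxtaparanodal potassium current — slows or blocks
impulse conduction, and how potassium channel blockade (4-aminopyridine)
can partially restore it.

## The model

A myelinated axon segment is a chain of *n* nodes of Ranvier (default 21,
indexed 0…20) treated as lumped capacitances joined by equal axonal
resistances, with the internodal myelin taken as an ideal insulator:

- axonal resistance between nodes: `R_a = ρ_a L / (π r_a²)`
- nodal capacitance: `C_j = C_m · 2π r_a · s_j`, where `s_j` is the bare
  node width (the quantity stretch injury increases)
- the extracellular return path `R_e = ρ_e L / (2π r_e h)` is ~two orders
  of magnitude below `R_a` and is neglected in the network (compact model)

Each node carries threshold-gated, time-varying ionic currents.  After a
node crosses the threshold potential `V_th` at clock time `τ_j`, its
conductance waveforms run on local time `t′ = t − τ_j`:

```
G(t′) = a t′² e^(−b t′),   b = 2/t*,   a = e² G*/t*²
```

so the waveform peaks at `(t*, G*)` — Na⁺: 0.1 ms, 0.028 S/cm²;
K⁺: 0.5 ms, 0.013 S/cm².  Sodium current flows through the bare nodal
membrane (span `s*`, unchanged by stretch):

```
i_Na,j = 2π r_a s*_j G_Na(t′_j) (E_Na − V_j)
```

Potassium current originates in the juxtaparanodal membrane (span `λ`)
and must pass the paranodal resistance `R_p` in series — the resistance
that paranodal detachment destroys:

```
i_K,j = (V_j − E_K) · g_K / (1 + g_K R_p),   g_K = 2π r_a λ_j G_K(t′_j)
```

Membrane potentials obey `dV_j/dt = [i_Na,j − i_K,j + (V_{j−1}−V_j)/R_a −
(V_j−V_{j+1})/R_a] / C_j` (node 0 lacks the left term; the last node is
clamped at rest) and are integrated by the explicit Euler method at
Δt = 0.1 µs.  Conduction velocity is `v = L/(τ_{j+1} − τ_j)`, measured at
nodes 4–5 (normal region) and 15–16 (injured region); the closed-form
approximation `v ≈ L/(α R_a C) = r_a/(2 α ρ_a C_m s)` makes the inverse
dependence on node width explicit.

## Worked example

```r
library(ranvier)

# textbook-normal axon: d = 1 µm, s = 0.65 µm, λ = 5 µm, L = 1 mm,
# ρ_a = 200 Ω·cm, C_m = 1 µF/cm², R_p = 3.2e10 Ω
sim <- simulate_axon(node_chain())
summary(sim)
#> Conduction velocity, nodes 4-5: 18.66 m/s
#> Conduction velocity, nodes 15-16: 18.76 m/s
#> Conduction block: no (last activated node 19)
#> Amplitude at node 19: 96.3 mV

# crush injury: nodes 8-20 stretched x3 (Na span unchanged)
crush <- run_axon_config(axon_config("crush"))
conduction_velocity(crush, 15, 16)
#> [1] 7.61035
```

The normal chain conducts at 18.7 m/s; tripling the bare node width in
nodes 8–20 (which triples their capacitance while the sodium-channel span
stays fixed) slows the injured region to 7.6 m/s.  Scenario presets
`crush_detach` (additionally R_p × 0.1), `block` (R_p × 0.01; the wave
dies at node 9) and `treated` (block + 80% potassium blockade; conduction
returns at ~6.9 m/s) cover the remaining experiments, and
`sweep_node_width()` maps velocity against node width.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/axonsim.R run --scenario crush_detach --out results/
Rscript inst/cli/axonsim.R sweep --out results/
Rscript inst/cli/axonsim.R fixtures --out configs/
```

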