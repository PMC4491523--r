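# pulsereduce

Nonlinear one-dimensional (1-D) pulse-wave simulation on branched
arterial networks, and principled reduction of those networks into
lumped (windkessel) models that preserve net peripheral resistance and
total compliance.

## What it does

* **Simulate**: a conservative finite-volume solver (MUSCL + HLL,
  SSP-RK2) for nonlinear 1-D blood flow in tapered elastic vessels,
  with characteristic-based coupling at the inlet, at bifurcations
  (total-pressure continuity), and at three-element windkessel (RCR)
  outlets. The scheme is well-balanced: uniform-pressure rest states
  are discrete steady states to round-off, even on tapered vessels.
* **Reduce**: lump peripheral terminal vessels into their outflow
  windkessels (`lump_terminal()`), merge sibling lumps into a new RCR
  terminal for their parent with proximal resistance equal to the
  parent's outlet characteristic impedance (`merge_siblings()`), and
  chain these into schedules (`trim_generation()`,
  `trim_to_generation()`, `trim_peripheral_pair()`,
  `reduce_to_windkessel()`). Net resistance is preserved exactly;
  total compliance is preserved by construction of the lumping rule.
* **Compare**: six relative waveform-error metrics (average, systolic
  and diastolic, for pressure and flow) via `error_report()`, and a
  one-call study driver `run_reduction_study()` that simulates a
  cascade of reduced models and tabulates all metrics.
* **0-D models**: stand-alone two-/three-element windkessel dynamics
  (`wk2_response()`, `wk3_response()`) and Frank's whole-system
  windkessel (`frank_whole_system()`).
* **Fixtures & I/O**: deterministic generators of plausible arterial
  trees, including 55- and 67-artery-style systemic networks
  (`make_tree()`), a hypertensive transform (`apply_hypertension()`),
  and plain-text JSON/CSV round-trip I/O for networks, inflows and
  waveforms. Ready-made examples live in `inst/extdata/`.

## Quick start

```r
library(pulsereduce)

net <- make_tree("single-vessel", seed = 1)
iw  <- make_inflow(period = 0.8, stroke_volume = 70e-6,
                   systolic_fraction = 0.3)
sol <- simulate_network(net, iw,
                        solver_settings(dx = 0.02, cycles = 20L,
                                        init = 9.3e3))
w <- waveforms_at(sol$waves, "root")
plot(sol$waves$time, w$p, type = "l")

# reduce a 55-segment tree to its equivalent windkessel
wk <- reduce_to_windkessel(make_tree("tree-55-style", seed = 7))
c(R_net = wk$r, C_net = wk$c)
```

A full reduction study (complete model vs progressively trimmed models
vs Frank's windkessel):

```r
net <- make_tree("symmetric-tree", generations = 2, seed = 21)
study <- run_reduction_study(net, iw,
                             settings = solver_settings(dx = 0.02,
                                                        cycles = 10L,
                                                        init = 9.3e3),
                             out_dir = "study_out")
study$summary   # all six metrics, percent, per model and probe
```

## Command-line interface

`inst/cli/pulsereduce.R` (installed at
`system.file("cli", "pulsereduce.R", package = "pulsereduce")`) exposes
subcommands `simulate`, `reduce`, `wk`, `compare`, `fixtures` and `run`
(YAML-configured studies). For example:

```sh
Rscript pulsereduce.R fixtures --kind tree-21-style --seed 7 --out net.json
Rscript pulsereduce.R simulate --network net.json \
        --inflow inflow.csv --cycles 12 --dx 0.02 --init 9300 --out waves.csv
Rscript pulsereduce.R reduce --network net.json --schedule full \
        --out wk.json --report validity.csv
```

## Units and conventions

SI throughout: lengths m, areas m², flows m³/s, pressures Pa,
resistances Pa·s/m³, compliances m³/Pa. Vessels are parameterised by
diastolic radius and diastolic pulse-wave velocity; the tube law is
`P = P_d + (β/A_d)(√A − √A_d)`.

## Documentation and tests

The methods vignette (`vignettes/pulsereduce-methods.Rmd`) documents
the governing equations, the numerical schemes, the reduction algebra
and its regime of validity. The test suite checks the solver against
independent oracles (well-balanced rest states, Poiseuille drops,
transit times, reflection coefficients, mean-pressure identities) and
the reduction against a brute-force circuit solver and a
200-compartment linearised chain model.
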