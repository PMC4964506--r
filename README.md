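# aquaflux

Trajectory analysis of water permeability and residue dipole gating in
tetrameric channel proteins (aquaporin-like systems) under perpendicular
electric-field pulses.

Membrane water channels such as human aquaporin-4 conduct water through
four parallel pores whose conduction is gated by a handful of residues at
the pore mouths — the selectivity filter (HSD-201, ARG-216, with SER-211
alongside) at the extracellular end and a second stage (HSD-95, CYS-178)
at the cytoplasmic end. Nanosecond electric-field pulses applied
perpendicular to the pores perturb the dipolar orientation of these
residues and, through them, the channel's water transport. `aquaflux`
provides the full analysis chain needed to quantify that story from MD
trajectories, plus a ground-truth-known synthetic trajectory generator so
that every stage of the chain is testable without any MD engine.

## What it computes

**Osmotic permeability (per pore).** The collective diffusion model: the
collective coordinate accumulates the in-channel water displacements,

    dn = Σ_{i ∈ S(t)} dz_i / L ,      n(0) = 0,

so one full permeation shifts n by ±1. Its diffusion constant comes from
the mean-square displacement, D_n = ⟨n²(t)⟩ / 2t, and the single-channel
osmotic permeability is

    p_f = v_w · D_n      [cm³ s⁻¹],

with v_w the volume of a water molecule. Alongside: the Einstein z
self-diffusivity of permeating waters with its log–log (Fickian)
exponent, and discrete permeation-event counts.

**Dipole response (per residue).** Dipole vectors μ = Σ q_a (r_a − r_com),
normalized cos θ distributions against the membrane normal, and
flip-transition kinetics (dwell-filtered crossings of cos θ = 0) with
rates in ns⁻¹.

**Rearrangement.** Heavy-atom RMSD per residue versus the initial
configuration (no rotational superposition, global drift removed); a
residue is flagged when the median RMSD after 1 ns exceeds 1 Å, and flags
assemble into a residue × field-condition matrix whose cells list the
pores affected.

**Statistics.** Paired one-tailed Student's t-tests of p_f against the
zero-field case (paired by pore, n = 4), one-way ANOVA on per-pore
permeability ratios across conditions, and one-tailed transition-rate
comparisons at the 90% level.

## Worked example

Generate a synthetic four-pore system under a 0.05 V/Å pulse along +y and
analyse pore A:

```r
library(aquaflux)

spec <- synth_spec(waters_per_pore = 10, water_D = 0.2, duration = 20,
                   dt_frame = 0.01, seed = 1,
                   field = field_protocol(E0 = 0.05, duration = 20))
sim <- simulate_system(spec)
win <- unwrap_trajectory(sim$window)

perm <- pore_permeability(win, sim$topology, sim$regions$A,
                          max_lag = 0.2, self_max_lag = 0.5)
print(perm)
#> pore A: D_n = 4.978 /ns, p_f = 1.493e-13 cm^3/s, D_self = 0.2107 A^2/ps, exponent = 1.03, events +8/-9

rid <- sim$truth$dipoles[["A SER-211"]]$residue_id
cs  <- cos_theta_series(win, sim$topology, rid)
tr  <- detect_transitions(cs, dwell_threshold = 0.04)
print(tr)
#> aq_transitions: 19 events over 20 ns (rate 0.95 /ns; dwell >= 0.04 ns)

h <- orientation_histogram(cs)
histogram_mean(h)
#> [1] 0.175
```

Reading the numbers: this pore holds N = 10 independent waters of true
diffusivity D = 0.2 Å²/ps in a channel of L = 20 Å, so the analytic
collective diffusion constant is N·D/L² = 5 ns⁻¹ — the fitted
D_n = 4.98 ns⁻¹ recovers it, and p_f is exactly v_w·D_n (here with
v_w = 3.0×10⁻²³ cm³). The self-diffusivity of permeating waters returns
the single-particle D (0.21 Å²/ps) with a Fickian exponent near 1, as it
must for free Brownian motion. SER-211's dipole flips at 0.95 ns⁻¹ —
roughly double its zero-field rate of 0.5 ns⁻¹, because the 0.05 V/Å
field stabilises the transition state of the flip — while its mean cos θ
stays near zero (the ±y field biases occupancy only weakly through the
flip axis' y-projection).

The full multi-condition comparison (zero field plus ±0.012 … ±0.065 V/Å,
three replicas, t-tests/ANOVA, rearrangement matrix, report files) is one
call:

```r
report <- run_pipeline(pipeline_config(seed = 1), output_dir = "out")
```

A thin command-line front end with `synth` / `perm` / `dipole` / `rmsd` /
`stats` / `all` subcommands is installed at `inst/cli/aquaflux.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/aquaflux.R", package="aquaflux"))')" all --out out --seed 1
```

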