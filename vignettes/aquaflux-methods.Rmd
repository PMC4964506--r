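---
title: "aquaflux: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{aquaflux: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquaflux)
```

## Scope

aquaflux analyses trajectories of tetrameric water channels — aquaporin-like
systems with four pores whose axes lie along the membrane normal z — under
perpendicular (±y) electric-field pulses. It answers three questions per
pore and field condition:

1. How much water does the channel conduct? (osmotic permeability via the
   collective diffusion model)
2. How do the gating residues orient? (dipole cos θ distributions and
   flip-transition kinetics)
3. Which residues rearrange? (heavy-atom RMSD against the initial
   configuration)

and wraps the comparisons in the statistical layer used for such data:
paired one-tailed t-tests against the zero-field case across the four
pores, and one-way ANOVA across conditions.

The package deliberately contains no molecular-dynamics engine. Real input
arrives as PDB topologies (with a partial-charge table) plus DCD
trajectories; for development and validation a synthetic generator
produces systems whose every ground truth — diffusivities, flip rates,
occupancies, injected displacements — is known exactly.

## Osmotic permeability: the collective diffusion model

The single-channel osmotic permeability $p_f$ (cm$^3$ s$^{-1}$) relates
water flux to an osmotic gradient. At equilibrium — no gradient applied —
it is measurable from fluctuations through the collective coordinate
$n(t)$: starting from $n(0) = 0$, each frame step adds

$$\mathrm{d}n \;=\; \sum_{i \in S(t)} \mathrm{d}z_i \,/\, L(t),$$

where $S(t)$ is the set of waters inside the pore cylinder,
$\mathrm{d}z_i = z_i(t) - z_i(t-\delta t)$ (unwrapped coordinates), and
$L$ is the channel length. One complete permeation shifts $n$ by $\pm 1$.
$n(t)$ diffuses; its diffusion constant comes from the mean-square
displacement, $D_n = \langle n^2(t)\rangle / 2t$, and

$$p_f = v_w\, D_n,$$

with $v_w$ the average volume of one water molecule. `collective_coordinate()`,
`msd_multi_origin()`, `fit_Dn()` and `osmotic_permeability()` implement the
chain; `pore_permeability()` runs it end to end for one pore.

Numerical choices, all configurable:

* **Membership rule.** A water contributes $\mathrm{d}z_i$ to a step only
  when it is inside $S$ at *both* endpoints of the step. This is the
  standard discretisation; the full-traversal identity (one scripted
  crossing contributes $n \to n \pm 1$ up to boundary-step error) is the
  regression test for it.
* **Cylinder membership** is decided by the water **oxygen**, with a
  half-open z interval $[z_{lo}, z_{hi})$ (no double counting at the
  boundary) and an inclusive radius.
* **Channel length** is fixed ($L = z_{hi} - z_{lo}$) by default;
  `length_mode = "per_frame"` divides each step by the current anchor-atom
  separation instead.
* **MSD origins.** All overlapping time origins are used — the
  variance-minimising standard estimator.
* **Fit window.** $D_n$ is half the least-squares MSD slope over a lag
  window. The estimator's standard error grows like
  $\sqrt{\tau_{max}/T}$ (lag over span). For the synthetic systems below,
  $n(t)$ is *exactly* Brownian at every lag, so the shortest usable lags
  are unbiased and minimise variance; the oracle-recovery analyses
  therefore cap the lag at 0.2 ns and fit 10–50% of it (0.02–0.1 ns).
  For real MD, where sub-ns lags contain correlated or ballistic motion,
  the window should be widened past that regime — both `max_lag` and
  `fit_window` are plain arguments and are echoed into every result.
* A negative fitted slope (possible in noise-dominated, frozen channels)
  is clamped to $D_n = 0$ and flagged rather than propagated.
* **Units.** Coordinates Å, time ns, $D_n$ ns$^{-1}$;
  $p_f = v_w \cdot D_n \cdot 10^9$ is the only place a unit conversion
  happens. $v_w$ defaults to $3.0\times10^{-23}$ cm$^3$ (18 g/mol at
  0.997 g/cm$^3$); it is a parameter because reported analyses rarely
  state it.

### Self-diffusivity and the non-Fickian exponent

`self_diffusivity_z()` estimates the Einstein z self-diffusivity
$D = \lim_{t\to\infty} \langle [z(t_0+t) - z(t_0)]^2 \rangle / 2t$
restricted to waters that complete a passage, pooling multi-origin MSDs
over their contiguous in-channel stretches. The log–log MSD slope over the
same window is reported as the Fickian exponent (1 = Fickian, < 1
subdiffusive — the typical signature of confined channel water, 2 =
ballistic). If no water completes a passage the result is flagged empty
rather than raising an error. One caveat the test suite makes explicit:
restricting to in-channel segments conditions on *not leaving*, which
biases the MSD downward once the diffusion length at the fitted lags
approaches the channel length; keep fitted lags short relative to
$L^2/2D$.

### Permeation events

`permeation_events()` scores a +z event when a water oxygen travels from
below $z_{lo}$ to above $z_{hi}$ while remaining inside the cylinder
radius whenever its z is inside the channel; −z events mirror it.
Re-crossing requires a full reset (re-entry from a reservoir). Events are
a discrete cross-check of $n(T)$: the net count can differ from $n(T)$ by
at most the partial traversals in progress at either end of the window.

## Dipole response

`residue_dipole()` computes $\vec\mu = \sum_a q_a (\vec r_a - \vec r_{com})$
with the residue's mass-weighted centre of mass as reference point. For
net-neutral residues the reference is immaterial; for charged residues
(arginine) the dipole is origin-dependent, so the convention is recorded
in every output. A side-chain-only variant is available via a flag;
which convention matches any given published analysis is usually
unknowable, so neither is claimed to be canonical.

`cos_theta_series()` reports $\cos\theta = \mu_z/|\vec\mu|$ per frame
against the +z axis; frames with vanishing dipole become missing values,
excluded from histograms and rate denominators. `orientation_histogram()`
normalises to a probability density over $[-1, 1]$ whose bin integral is
exactly 1 (40 bins by default).

`detect_transitions()` defines a dipolar flip as a crossing of
`crossing_level` (default 0) followed by at least `dwell_threshold` of
continuous residence on the new side; shorter excursions are chatter and
collapse into the surrounding state. The default dwell of 0.1 ns suits
typical flip timescales; the kinetics validation uses the documented
minimum of two frame intervals because the dwell filter censors true
dwells shorter than the threshold — an intrinsic downward rate bias of
order $2k\,\tau_{dwell}$ that the analyst should keep below the target
accuracy.

## Rearrangement

`residue_rmsd_series()` computes per-residue heavy-atom RMSD against the
*initial configuration* — deliberately without rotational superposition,
since the question is whether the residue left its starting position, not
whether it changed internal shape. Global drift is removed by subtracting
the per-frame displacement of the protein (non-water) heavy-atom
centroid; whether published analyses do this is typically unstated, so it
is a flag (`remove_drift`). A residue is *rearranged* when the median
RMSD over frames later than `settle_time` (1 ns) strictly exceeds
`threshold` (1 Å); the median resists transient spikes, and mean/max are
available. `build_rearrangement_matrix()` assembles the
residue × condition overview whose cells list the pores flagged, with
absent conditions marked distinctly from empty cells.

## Statistical layer

The pairing unit is the **pore** ($n = 4$), matching error bars computed
across the four channels; replicas are averaged within a pore before
testing. `paired_one_tailed_t()` delegates to `stats::t.test(paired =
TRUE)` with explicit degenerate branches (zero-variance differences yield
p = 0, 1 or 0.5 by direction and sign). `one_way_anova()` uses
`stats::aov`. Transition-rate comparisons are one-tailed (greater) at
α = 0.10 — the 90% criterion conventionally quoted for such kinetics —
and permeability comparisons default to one-tailed (less, i.e. reduced
conduction) at α = 0.05. The ANOVA across conditions runs on per-pore
permeability *ratios*, each pore normalised by its own zero-field mean;
that normalisation is a choice (a global denominator is equally
defensible) and is recorded in the report provenance. No multiple-testing
correction is applied by default, matching common practice in this
literature; the p-values are reported raw so any correction can be
applied downstream.

## The synthetic generator: what it emulates, and what it does not

`synth_spec()` + `simulate_system()` produce a four-pore system with three
ingredients:

* **Waters** (`simulate_channel_waters()`): independent 1D Brownian
  motion along z, Gaussian steps of variance $2 D\, \delta t$, static
  lateral offsets inside the cylinder, rigid hydrogens. Under the default
  `confinement = "periodic"`, the N waters per pore live on a z-ring of
  circumference L — a minimal model of a channel at steady state whose
  occupancy is exactly N, for which the independent-particle identity
  $D_n = N D / L^2$ is exact and serves as the package's primary oracle
  (N = 10, D = 0.2 Å²/ps, L = 20 Å gives $D_n$ = 0.005 ps⁻¹).
  `confinement = "reservoir"` instead adds 20 Å reservoir slabs with
  reflecting outer walls and free passage through the channel, for
  realistic permeation-event trajectories. Waters do **not** interact: no
  single-file exclusion, no hydrogen-bond network. That is what makes the
  oracle exact, and it is also the clearest statement of what passing
  tests do *not* show about real channel water.
* **Residue dipoles** (`simulate_residue_dipoles()`): each gating residue
  is a two-atom dumbbell whose dipole follows a two-state telegraph
  process between orientations $\cos\theta = \pm c$. The field biases the
  switching rates $k_\pm = k_0\, g \, e^{\pm \mu E s / 2kT}$ ($s$ = the
  flip axis' projection on the field direction), giving the Boltzmann
  occupancy ratio $e^{\mu E s / kT}$. The common gain
  $g = \exp\!\big(\min(\mu E \sqrt{1 - s^2},\, B\,kT)/kT\big)$ models
  stabilisation of the transition state — the flip path passes through
  the orientation best aligned with the field — so switching
  *accelerates* with intensity (capped by the barrier height $B$ in kT)
  while the occupancy bias is untouched. Without this term a pure
  rate-bias telegraph would flip *less* often under field
  ($k_0/\cosh(\mu E s/2kT)$), the opposite of the accelerated
  orientational sampling the analysis is designed to detect. All
  Boltzmann factors use kT at 298 K; 1 D = 0.2081943 e·Å, centralised in
  `aq_constants()`.
* **Scripted rearrangements** (`inject_rearrangement()`): rigid
  heavy-atom displacements of chosen magnitude from a chosen onset, so
  the RMSD criterion has exact expected values. Thermal positional noise
  is off by default precisely so that a 1.0 Å injection produces an RMSD
  statistic of (almost exactly) 1.0 Å and exercises the strict-inequality
  boundary.

A free-rotor variant (`sample_free_rotor()`) draws orientations from the
Boltzmann density $\propto e^{x\cos\theta}$ by exact inverse-CDF sampling;
its mean alignment is the Langevin function $\coth x - 1/x$
(`langevin_function()`), the closed-form oracle for the histogram
machinery.

Default study conditions (changeable per argument, chosen once): field
intensities 0.012–0.065 V/Å along ±y as 10 ns static pulses (Gaussian
envelopes supported), three replicas per condition, 10 waters per pore
with D = 0.2 Å²/ps (a confined-water scale), channel L = 20 Å and radius
4 Å, pore centres at (±15, ±15) Å, and five gating residues per pore —
SER-211, HSD-201, ARG-216 at the extracellular mouth (z = +8 Å) and
HSD-95, CYS-178 at the cytoplasmic mouth (z = −8 Å) — with representative
side-chain dipole magnitudes (2.1, 3.7, 5.4, 3.7, 1.6 D), flip rate
0.5 ns⁻¹ and barrier cap 6 kT. The dumbbell separation is 0.5 Å so that a
bare dipole flip moves each atom well below the 1 Å rearrangement
threshold. An optional gating coupling scales the water diffusivity by
0.5 whenever the instantaneous intensity reaches 0.035 V/Å — a
qualitative stand-in for dipolar-gating-reduced permeability, used by the
end-to-end directional test; no quantitative residue-to-water coupling is
claimed.

Everything is reproducible: a spec's seed fully determines the output,
and the pipeline derives per-run seeds from one master seed.

## Problem sizes used in validation

The shipped tests and the acceptance script run entirely on synthetic
systems at these scales, chosen to give each estimator comfortable
statistical power: the permeability oracle uses 4 pores × 10 waters over
100 ns at 10 ps/frame (3 seeds); kinetics checks use 16 telegraph series
over 200 ns at 10 ps/frame; the Langevin check uses $10^5$ samples per
coupling; the end-to-end pipeline runs 11 conditions × 3 replicas × 10 ns.

## Known limitations

* The synthetic water model has no inter-water correlations; real
  single-file channels show collective effects the oracle identity
  ignores by construction.
* XTC input is not supported (DCD and PDB only); convert externally if
  needed.
* Orthorhombic boxes only; no velocity records; no PSF parsing — charges
  come from a plain-text table.
* The in-channel self-diffusivity estimator carries the segment
  conditioning bias discussed above; it is a descriptive statistic, not a
  substitute for a proper propagator analysis.
* `run_pipeline()` generates its conditions synthetically; applying the
  module functions to real trajectories is supported at the function
  level (`read_topology()`, `read_trajectory()`, then any analysis), but
  the orchestration layer does not yet schedule heterogeneous real-data
  inputs.
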