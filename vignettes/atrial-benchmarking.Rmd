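---
title: "Benchmarking human atrial myocyte models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking human atrial myocyte models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model lineup

`atrialbench` implements a benchmarking framework for ionic models of the
human atrial myocyte. Three models are built in, identified by the initial
of their first author as is conventional in this literature:

* **C** — Courtemanche–Ramirez–Nattel (1998): Luo–Rudy lineage, 21 state
  variables, two-compartment sarcoplasmic reticulum (SR) with a
  voltage-dependent phenomenological Ca²⁺ release, instantaneous-buffer
  formulation for troponin/calmodulin/calsequestrin. Native units:
  currents in pA/pF, time in ms.
* **N** — Nygren et al. (1998): Lindblad rabbit-atrial lineage, 29 states,
  a restricted extracellular cleft space with its own Na⁺/K⁺/Ca²⁺
  balances, a diadic space under the L-type channels, dynamic cytosolic
  buffers, and an electroneutral Na⁺ influx that stabilizes the long-term
  ion concentrations. Native units: currents in pA, time in s (converted
  to ms at the integrator interface).
* **M** — Maleckar et al. (2009): the N model with reformulated
  repolarizing currents (I_t, I_Kur from newer human data), the
  electroneutral Na⁺ influx removed, an optional acetylcholine-activated
  K⁺ current (inactive at the default ACh = 0), and a larger fast-Na⁺
  permeability (P_Na = 0.0018 vs 0.0016 nL/s in N; this reproduces the
  published relationship between the two models' I_Na extrema and upstroke
  velocities).

The Koivumäki and Grandi models are *plugin slots only*: the registry
reserves their names, and the integrator supports the per-state RK4
sub-integrator override that the Grandi model's stiff Ca²⁺/calsequestrin
states require, but their full equation sets are out of scope.

Chronic-AF (cAF) electrical remodeling is a fixed conductance scaling
applied uniformly to all models: I_to and I_CaL × 0.35, I_Kur × 0.51,
I_K1 × 2.10, plus a 30% reduction of the tissue conductivity for
gap-junctional remodeling. A variant tag guards against applying the
scaling twice.

## Numerics

All state updates are explicit. Hodgkin–Huxley gates use the Rush–Larsen
exponential update `y ← y∞ + (y − y∞)·exp(−dt/τ)`, which is exact for a
gate with frozen voltage over one step; all other states use forward
Euler. Within a step the gates are advanced **first** (at the
start-of-step voltage) and the ionic currents then use the end-of-step
gate values: this Gauss–Seidel-style ordering has the same formal order
of accuracy as evaluating everything at the old state but a markedly
smaller error constant during the Na⁺-driven upstroke — it reduces the
strand CV change under dt halving from ~0.8% to 0.15–0.31% across the
three models. The default step is **dt = 0.01 ms** (10 µs), with 5 µs
selectable; the temporal-convergence test (strand CV change < 0.75%
under dt halving) is part of the acceptance suite. Coarsening the grid
from 0.1 to 0.2 mm lowers CV by 1.0–1.4% for the N/M models but by
~3.0% for C, whose sharper upstroke (dV/dt_max ≈ 200 V/s here) leaves
only ~2–3 voxels across the wavefront at 0.2 mm; the corresponding
acceptance check is therefore red for C at the 2.5% bound.

Purely voltage-dependent quantities — gate steady states, the per-step
Rush–Larsen factors, and the voltage factors of the currents — are
tabulated on a 0.02 mV grid over [−150, 100] mV and linearly interpolated
inside the compiled integrators. Interpolation error is below 10⁻⁸
relative (verified against the analytic path in the unit tests); tables
are parameter-free, so control and cAF variants share them. This is the
standard optimization in tissue-scale electrophysiology solvers and gives
a 3–5× speedup.

Tissue uses the monodomain reaction–diffusion model on cubic voxels
(dx = 0.1 mm by default) with a 3-point (strand) or 5-point (patch)
Laplacian. No-flux boundaries use the zero-gradient ghost convention,
which conserves the spatial mean of V_m exactly (a mirrored-neighbour
ghost does not; the conservation property is tested). The surface-to-
volume ratio and specific membrane capacitance enter only through the
combination D = σ/(βC_m); because σ is *tuned* to a target conduction
velocity, their absolute values affect no benchmarked quantity. The
nominal constants (β = 1400 cm⁻¹, C_m = 1 µF/cm²) only fix the scale on
which σ is reported. A CFL-style bound dt ≤ dx²/(2·dim·D) is checked at
grid setup (warning, not error). Cleft-space states of the N/M models are
per-voxel with no lateral diffusion: the monodomain abstraction treats
extracellular space as grounded.

## Protocols and measurement conventions

Conventions the source tables leave open were fixed once, as follows:

* **Stimulus**: rectangular, 2 ms, delivered at 2× the diastolic
  threshold in single cells and 1.2× the tissue threshold in tissue.
  Thresholds are found by doubling + bisection to 1% relative precision;
  an AP means peak V_m > 0 mV (single cell) or a propagated upstroke at
  three-quarters of the strand (tissue). Single-cell thresholds are
  probed from the published resting state; tissue thresholds from the
  pre-paced seeded strand, and they are re-measured at every trial
  conductivity during tuning because the source–sink balance shifts with
  σ. Shorter pulses (0.5–1 ms at 2× their own thresholds) were evaluated
  and move the AP features *away* from the published values, so 2 ms was
  kept.
* **AP features**: RMP is V_m immediately before the stimulus; amplitude
  is peak − RMP; APD_x runs from the time of maximum upstroke velocity to
  the first crossing of (peak − x%·amplitude) on the repolarizing limb,
  with linear interpolation between samples. dV/dt_max excludes the
  stimulus-current contribution (otherwise the pulse amplitude inflates
  it). An APD level not reached before the next stimulus is reported as
  undefined with a reason, not an error.
* **Activation time** (tissue): time of maximum total dV/dt during the
  upstroke, refined by a parabolic fit through the neighbouring steps.
  This is robust across models with different resting potentials, unlike
  a fixed-voltage crossing.
* **CV**: distance between the centers of the first and second strand
  halves divided by their activation-time difference, on the fifth
  strand beat.
* **ERP**: from the beat-5 state of the strand protocol, the S2 follows
  the final S1 of the train; the ERP is the shortest coupling interval
  whose premature stimulus produces a *propagated* AP at the center of
  the distal half — upstroke dV/dt above 10% of the S1 reference, peak
  above −20 mV, and an arrival time after both the coupling interval and
  the S1 wave's own distal arrival (the last condition prevents the
  still-travelling S1 front from being misattributed to S2 at short
  coupling intervals). Bisection at 1 ms resolution matches the integer
  precision of the published ERPs.
* **Alternans**: beat-to-beat APD₅₀ differences above 2 ms count as
  alternating (above numerical jitter, well below the published
  bifurcations); a consistently sign-alternating difference sequence is
  period-2, a repeating long–short–short pattern period-3. The final
  10 s of each 30 s run is classified.
* **Conductivity tuning**: CV(σ) is measured on a single seeded strand
  beat and iterated with the near-√σ scaling law `σ ← σ·(target/cv)²`
  until within 0.5% of 750 mm/s at BCL 1 s, with a stability cap on σ.
  Tuning uses the control variant; cAF runs reuse the tuned value × 0.70.

## Rotor analysis

The 2D protocol seeds a square patch with the 50-beat pre-paced state,
delivers planar S1 beats from the left edge and a cross-field S2 over
the lower half. Phase is the analytic-signal (Hilbert) phase of each
voxel's mean-subtracted V_m; a time-delay-embedding variant is available
for cross-checks. Phase singularities sit on 2×2 plaquettes whose
discrete line integral of wrapped phase differences is ±2π; angle
wrapping uses the principal value (`atan2(sin, cos)`), matching the
complex-argument convention of the brute-force oracle used in the tests.
Tracks are linked by nearest-neighbour matching at 2 mm per ms of frame
period. The pseudo-ECG is the infinite-volume-conductor lead-field sum of
the discrete Laplacian of V_m weighted by 1/r, for two electrodes 5 mm
above the patch plane and 10 mm apart; amplitudes are arbitrary units
(the prefactor cancels in dominant-frequency analysis). Dominant
frequency is the largest spectral peak in 1–30 Hz of the Hann-windowed,
zero-padded (≥ 0.1 Hz resolution) signal.

**Scale.** The full 100 × 100 mm patch at dx = 0.1 mm (10⁶ voxels for
several seconds) is supported by the same code but is an offline
reproduction mode. The test suite exercises a scaled-down chronic-AF
rotor: a 32 mm patch at dx = 0.25 mm and dt = 0.02 ms, with the tissue
conductivity reduced a further (250/602)² so that the reentrant
wavelength fits the patch — the same reduced-gap-junction route by which
a rotor can be accommodated on a small domain under the critical-mass
argument. One S1 beat (from the pre-paced seed) replaces the four
full-scale S1 beats, S2 is applied 190 ms later, and ~1.1 s is recorded.
On this domain the induced rotor meanders strongly; its pseudo-ECG
therefore carries Doppler sidebands of the meander and its largest
spectral peak sits below the rotation rate. The dominant-frequency /
phase-rotation consistency check is accordingly anchored on the movie
itself — the DF of a core-adjacent voxel's V_m against the median
net-winding rate at probes 8 mm from the mean core, over the stabilized
final 700 ms — where the two agree within a few percent.

## Synthetic fixtures

The mock excitable cell is a two-variable Mitchell–Schaeffer-type model
(fast activator, slow recovery gate) mapped onto a configurable voltage
range, registered through the same plugin contract as the ionic models so
every protocol runs on it unchanged. Its knobs are calibrated at
construction by deterministic simulate-and-adjust: the recovery time
constant τ_close against the paced APD₉₀, and (optionally) τ_open against
the **strand** ERP measured by the very S1–S2 protocol used for the ionic
models, on a canonical 100-voxel test strand — tissue refractoriness is
loaded by source–sink effects and is the quantity the protocols report,
so the single-cell refractory interval would be the wrong calibration
target. Physiological realism of the mock is explicitly *not* a goal:
what passing fixture tests show is that the protocol and analysis
machinery recovers known ground truth, not that the ionic models are
correct — that is what the table/restitution reproductions are for.

Plane-wave movies carry their analytic activation map (so CV recovery is
exact), and ideal vortex phase fields carry their center, chirality and
rotation frequency.

## Problem sizes and determinism

The test suite runs the published protocols at their native sizes where
that is cheap (50 s single-cell characterization runs, the 20-minute
stability run, 200-voxel strands with conductivity tuning and ERP
bisection) and at the scaled-down patch described above for the 2D
experiment. Everything in the package is deterministic — explicit
integrators, fixed protocols, no random numbers — so repeated runs are
bit-identical; the only seeds in the test suite fix the generated cases
of property-style tests.

## Known limitations

* The printed N-model I_Ks extremum could not be reconciled with the
  published g_Ks (the model cannot produce a current of that magnitude at
  plateau potentials with g_Ks = 1 nS); all other current extrema of the
  C/N/M columns agree to a few percent.
* AP amplitude (and with it APD₅₀ for the short triangular N/M action
  potentials, whose early plateau falls slowly through the 50% level) is
  sensitive to the stimulus convention, which the source protocol does
  not fully specify; amplitudes here sit 2–5% below the printed values
  with matching APD₉₀ and RMP.
* Fibroblast coupling, β-adrenergic/cholinergic regulation, anisotropy,
  bidomain effects and realistic atrial geometry are out of scope.
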