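# atrialbench

Benchmarking framework for ionic models of the human atrial myocyte.

Mathematical models of atrial electrophysiology are the workhorse of in
silico studies of atrial fibrillation (AF), but the published human atrial
cell models differ substantially in action-potential (AP) morphology,
rate adaptation, long-term stability and tissue-level dynamics. This
package implements three of those models — Courtemanche–Ramirez–Nattel
1998 (**C**), Nygren et al. 1998 (**N**) and Maleckar et al. 2009
(**M**) — together with the protocols used to characterize and compare
them, for anyone who needs a reproducible, tested reference
implementation of these models and their chronic-AF (cAF) variants:

* single-cell pacing with AP/Ca²⁺-transient feature extraction
  (amplitude, RMP, APD₅₀/APD₉₀, dV/dt_max, CaT levels), long-term
  stability runs, and alternans classification over a BCL grid;
* chronic-AF electrical remodeling as fixed conductance scalings
  (I_to, I_CaL × 0.35; I_Kur × 0.51; I_K1 × 2.10; tissue conductivity
  × 0.70);
* explicit monodomain tissue simulation (Rush–Larsen + forward Euler,
  dt = 10 µs, cubic voxels of 0.1 mm) on 1D strands and 2D patches,
  with conductivity auto-tuned to a conduction velocity of ≈750 mm/s at
  BCL 1 s;
* steady-state strand restitution of APD₉₀, conduction velocity (CV),
  effective refractory period (ERP) and wavelength (WL = ERP × CV);
* S1–S2 cross-field rotor initiation on 2D patches with
  phase-singularity tracking (analytic-signal phase + winding numbers),
  pseudo-ECG synthesis and dominant-frequency analysis;
* synthetic fixtures with known ground truth (a calibrated mock
  excitable cell, plane waves, ideal vortex phase fields) so every
  analysis stage is testable independently of the ionic models.

The membrane model is dy/dt = f(y, V) with V_m obeying
C_m dV/dt = −I_ion + I_stim (single cell) or the monodomain equation
βC_m ∂V/∂t = ∇·(σ∇V) − βI_ion + I_stim (tissue). Gating variables are
advanced with the exact exponential (Rush–Larsen) update; everything
else with forward Euler. The compiled integrators use voltage lookup
tables (0.02 mV grid, linear interpolation, ≤1e−8 relative error).

## Worked example

Reproduce the single-cell characterization of the Courtemanche model:
50 s of pacing at BCL 1 s with a 2 ms stimulus at twice the diastolic
threshold, then features of the terminal AP:

```r
library(atrialbench)
m  <- atrial_model("courtemanche")
tr <- pace(m, bcl = 1, duration = 50)
extract_ap_features(tr)
#> <ap_features> beat 50: amp 107.48 mV, RMP -81.00 mV,
#>   APD APD50=169.3 APD90=294.2, dV/dt_max 198.3 V/s
```

The published values for this protocol are amplitude 110.11 mV, RMP
−81.04 mV, APD₅₀ 165.16 ms, APD₉₀ 294.83 ms: the terminal AP is
reproduced to within ~2% (amplitude is stimulus-convention sensitive;
see the vignette). The cAF variant shortens and triangulates the AP:

```r
extract_ap_features(pace(atrial_model("courtemanche", "caf"),
                         bcl = 1, duration = 50))
#> <ap_features> beat 50: amp 112.75 mV, RMP -84.33 mV,
#>   APD APD50=84.4 APD90=145.2, dV/dt_max 204.1 V/s
```

Tissue restitution at one BCL (tuning takes a couple of minutes):

```r
sigma <- tune_conductivity(m)          # ~750 mm/s at BCL 1 s
p     <- run_strand_protocol(m, bcl = 0.4, sigma = as.numeric(sigma))
erp   <- measure_erp(p)
c(cv = p$cv, erp = as.numeric(erp), wl = wavelength(as.numeric(erp), p$cv))
#>      cv     erp      wl
#>   754.1   300.0   226.2
```

(published: CV 751.9 mm/s, ERP 302 ms, WL 227.1 mm). Rotor experiments
and the published comparison tables are available through
`s1s2_cross_field()` / `compute_phase()` / `track_singularities()` /
`pseudo_ecg()` / `dominant_frequency()` and `run_benchmark()` /
`compare_to_reference()`; the printed reference tables ship as CSV under
`inst/extdata/`.

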