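---
title: "ablasim: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ablasim: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ablasim)
```

# Scope

`ablasim` simulates microwave ablation (MWA) of liver tissue and
tissue-mimicking phantoms with a water-cooled coaxial monopole applicator at
2.45 GHz, and quantifies the predicted necrosis zone. The pipeline is

1. applicator/domain geometry on an axisymmetric (r, z) half-plane,
2. frequency-domain electromagnetic (EM) solve for the antenna field,
3. volumetric heat source (SAR) from dielectric losses,
4. transient Pennes bioheat solve with perfusion, metabolic heat and
   convective needle cooling,
5. necrosis maps from the Arrhenius damage integral and a 60 °C
   critical-temperature threshold,
6. revolution of the 2D maps into 3D voxel volumes and surface meshes,
7. Dice / Hausdorff / mean surface-distance metrics against a segmented
   reference zone after rigid registration.

Everything is SI internally (m, s, K, W); temperatures cross to °C only at
the damage-model and reporting boundaries.

# Geometry and materials

The applicator is a 15-gauge (1.45 mm OD, 150 mm long) coaxial monopole.
The internal build of the commercial device is proprietary, so the defaults
derive the nominal radii from a 50 Ω PTFE-filled coax constraint within the
1.45 mm OD: inner conductor 0.145 mm, dielectric to 0.50 mm, outer conductor
to 0.60 mm, catheter sheath to 0.725 mm. All radii are `needle_spec()`
arguments and can be overridden. The outer conductor terminates at the feed
gap (default centre 25 mm above the tip, width 1 mm — a typical monopole gap,
configurable); below it the dielectric-coated inner conductor runs to the
ceramic tip (default length 5 mm, relative permittivity 9 — the tip material
is not characterised publicly, so it is exposed as a parameter). This is the
classic interstitial monopole construction: the coated distal section
radiates, the gap is the feed.

Coordinates: z = 0 at the needle tip, z increasing toward the hub, r ≥ 0 from
the symmetry axis; "above the tip" is +z.

The material table (`build_material_table()`) carries, per material, the
EM constants (relative permittivity, conductivity at 2.45 GHz) and the
thermal constants (density, specific heat, conductivity, perfusion rate,
metabolic heat). Liver: ε = 43.03, σ = 1.69 S/m, ρ = 1069 kg/m³,
Cp = 3600 J/(kg·K), k = 0.55 W/(m·K), Qm = 1000 W/m³. Tumor: ε = 54.8,
σ = 2 S/m, ρ = 1040, Cp = 3760, k = 0.57, Qm = 1300. Blood: ρb = 1000,
Cb = 3639, ωb = 0.00361 1/s, Tb = 310.15 K. The polyacrylamide phantom
medium is not fully characterised in the open literature (its dielectric
properties are pH-dependent), so it defaults to the liver values with
perfusion and metabolism switched off — exactly the two terms that do not
exist in a gel — at an initial temperature of 290.15 K (both overridable).

The grid (`rasterize()`) is graded: grid lines are forced onto every
material interface, the spacing is 0.1 mm at the needle wall, tip and gap and
grows geometrically (factor 1.3) to a 1 mm cap. A homogeneous-cylinder
identity (revolved cell volumes sum to πR²H within 1e-9 relative) guards the
volume bookkeeping.

# EM model

With azimuthal symmetry the monopole excites the TM₀ mode, fully described
by the azimuthal magnetic field H(r, z). The package solves

d/dr[ (1/ε̃) (1/r) d(rH)/dr ] + d/dz[ (1/ε̃) dH/dz ] + k₀² H = 0,

with ε̃ = εr − iσ/(ωε₀), by cell-centred finite volumes on the graded grid.
Design choices:

* **Copper as perfect electric conductor.** Implemented by setting
  1/ε̃ = 0 in conductor cells; with harmonic face averaging this enforces
  zero tangential E on conductor faces and H = 0 inside, and decouples the
  shielded coax interior exactly (a fully shielded section leaks < 1e-6 of
  the port amplitude — a regression test).
* **Excitation.** A unit-amplitude transverse-electromagnetic 1/r profile is
  impressed across the coax dielectric at the top boundary. The absolute
  power scale is set only by `normalize_to_input_power()`: after the solve,
  the SAR is rescaled so its revolved volume integral equals the delivered
  power (35 W phantom / 42 W clinical). This conservation contract (held to
  1e-9 relative) replaces explicit port-impedance calibration: all cable and
  matching losses are folded into the single delivered-power number.
* **Open boundaries.** Stretched-coordinate absorbing layers (16 cells,
  cubic profile) on the outer radial and bottom boundaries. The top boundary
  carries the port and is left reflective outside the needle: an absorbing
  layer there would attenuate the guided coax wave, and tissue at 2.45 GHz
  is lossy enough (≈ 48 Np/m for liver) that reflections from a wall ≥ 50 mm
  from the gap are negligible.
* **Verification.** A 1D layered-slab harness built from the same
  complex-permittivity and stretched-boundary machinery reproduces the
  closed-form plane-wave attenuation constant
  α = ω√(µε/2·(√(1+(σ/ωε)²)−1)) for liver within 2% (measured ≈ 0.4%).
  The solver refuses grids coarser than λ/10 in the densest medium.

SAR is Qext = σ|E|²/2 per cell, with E derived from H at cell centres.

# Bioheat model

Pennes' equation

ρT CT ∂T/∂t = kT ∇²T + ρb Cb ωb (Tb − T) + Qm + Qext

is integrated on the tissue cells with implicit backward Euler (default
Δt = 0.5 s), assembled once and factored with a sparse Cholesky; each step is
a pair of triangular solves, so a 10-minute transient on ~10⁴ cells takes
seconds. Backward Euler is unconditionally stable on the 0.1 mm graded grid
and monotone (an M-matrix), so the discrete maximum principle holds — both
are property tests. The discrete energy balance closes to machine precision
each step with insulated boundaries (tested at 0.1%).

* **Needle cooling.** The circulating water is replaced by a convective
  (Robin) condition h(T_cool − T) on every tissue face adjoining the needle;
  the needle interior is excluded from the thermal domain. The film
  coefficient of the real device is unpublished; the default
  h = 500 W/(m²·K) is representative of water-cooled applicators and is
  deliberately exposed. Coolant: 7 °C (phantom) / 20 °C (clinical).
* **Outer boundary.** Dirichlet at the initial temperature; the wall is
  ≥ 50 mm from the gap while the heated zone stays within ~25 mm over
  10 min. An `insulated` option exists for verification runs.
* **Omissions (by design).** Vaporization enthalpy above 100 °C,
  temperature-dependent tissue properties and discrete-vessel (heat-sink)
  advection are not modelled; properties are constants.
* **Verification.** With conduction suppressed (a test hook) and perfusion
  on, the solution relaxes as Tb + (T0−Tb)·exp(−t/τ) with
  τ = ρT·CT/(ρb·Cb·ωb) ≈ 293 s for the tabulated constants; the integrator
  matches within 0.5%. Probe series are bilinear interpolations of the
  snapshots; halving Δt moves 600 s probe temperatures by < 0.5%.

# Damage models

The Arrhenius integral Ω = ∫ A·exp(−Ea/(R·(T(t)+273.15))) dt uses liver
kinetics A = 7.39e39 1/s, Ea = 2.577e5 J/mol (the frequency factor is
per-second; Ω is dimensionless). It is accumulated by trapezoidal
integration on the snapshot cadence (default 1 s — a config knob, because
accuracy near steep ramps depends on it; against a 10× oversampled reference
the default cadence is within 0.5% at Ω ≈ 1). At constant temperature the
integrator matches the closed form A·t·exp(−Ea/(R(T+273.15))) within 0.1%;
the time to Ω = 1 at 60 °C is ≈ 3.42 s. Ω = 1 corresponds to
1 − e⁻¹ ≈ 63% of the damage process completed; the necrosis mask is the
strict threshold Ω > 1. The completed-damage fraction field is also
available, so display-style thresholds (e.g. 98%) can be applied without
changing the quantitative rule.

The critical-temperature model marks a cell necrotic when its temperature
statistic reaches 60 °C. The default statistic is the running maximum
(necrosis is irreversible); a `final_time` mode provides the end-time
isoline instead. Thresholding conventions are fixed for reproducibility:
strict `>` at the Ω threshold, `≥` at the temperature threshold — boundary
cells are measure-zero at float resolution, but the convention matters for
bit-identical reruns.

# Zones and metrics

Necrosis masks are contoured with marching squares (sub-cell linear
interpolation); open isolines ending on the inner radial margin are closed
through the symmetry axis. `revolve()` voxelizes the 360° solid of
revolution (default 0.5 mm isotropic voxels; inside/outside by even-odd
polygon tests on a spacing/8 radial raster) and sweeps the contour into a
closed triangle mesh (72 angular steps). Revolved cylinders and spheres land
within 2% of their analytic volumes at 0.5 mm voxels, converging at first
order in spacing.

Metrics (`compute_metrics()`) resample the simulated volume through a rigid
transform onto the reference lattice (nearest-neighbour, so masks stay
binary; the lattice is extended to the union bounding box so nothing is
clipped) and report:

* Dice 2|A∩B|/(|A|+|B|);
* Hausdorff distance, taken as the *symmetric* max-max surface distance —
  the directed variant is also common, so the choice is stated here;
* "Euclidean distance", read as the mean symmetric nearest-surface
  distance, the usual companion metric; a median or centroid distance would
  be defensible readings too, so this one is documented rather than assumed.

Surface distances use an exact voxel Euclidean distance transform
(Felzenszwalb, in C++), verified against brute-force all-pairs computation
on masks up to 15³ voxels.

Registration policy: if a transform is supplied (e.g. from a manual surface
registration) it is validated (orthonormal, det +1) and used as-is — the
pipeline never silently re-registers. Without one, `register_zones()` runs
iterative closest point on subsampled surface voxels from a centroid-aligned
start with Kabsch updates; a 5 mm synthetic displacement is recovered within
0.2 mm.

# Synthetic fixtures

`generate_reference_zone()` stands in for a radiologist's segmentation: a
voxelized ellipsoid with optional smooth boundary jitter and an optional
cylindrical defect subtracted, emulating a blood vessel piercing the
ablation zone (the heat-sink signature). `generate_sensor_series()` emulates
fiber-optic probe recordings with the saturating rise
T∞ − (T∞−T0)e^(−t/τ) plus seeded Gaussian noise. Both are deterministic for
a fixed seed, using a private RNG stream that does not disturb the caller's
RNG state.

What the fixtures do *not* emulate: real segmentations have anisotropic
voxels, partial-volume boundaries and observer variability; real sensor
traces have drift and discrete sampling artefacts. Passing tests against
these fixtures therefore demonstrates that the geometry processing and
metric plumbing are correct, not that the simulator predicts any particular
clinical outcome.

# Study conditions and what the baseline shows

The default `case_config()` values are the study conditions: phantom at
35 W delivered for 600 s starting from 290.15 K with 7 °C coolant; clinical
at 42 W (a 120 W generator with the 60–70% cable-loss midpoint) with
perfusion, metabolic heat, a 5.5 × 4.35 mm half-axis tumor centred near the
feed gap, and 20 °C coolant.

On the phantom baseline the package reproduces the expected qualitative
structure: heating concentrates a few mm radially from the shaft around the
feed gap (~20–25 mm above the tip), there is no direct heating below the
tip, and the Arrhenius zone is strictly larger than the 60 °C isoline zone
(area ratio ≈ 1.28 at default settings).

Peak temperature deserves a caveat. With the *full* 35 W forced into the
tissue by the power-conservation contract, the 600 s peak is ≈ 188 °C,
mesh-converged (< 1 K change when the finest cell halves to 0.05 mm) and
located ≥ 2 mm from the needle. Port-fed models of the same applicator
deposit less than the power arriving at the needle, because an imperfectly
matched antenna reflects part of it back up the cable; temperature rise is
linear in deposited power, so, e.g., ~60% absorption would put the same
model near 120 °C. `ablasim` keeps the conservation contract because it is
explicit and testable; users comparing against port-fed results should
treat `input_power` as *absorbed* power and derate accordingly. Vaporization
(not modelled) would also clamp real peaks near 100–110 °C.

# Numerical choices and degenerate inputs

* Sparse complex EM system solved as the equivalent 2N real system (LU);
  bioheat solved by one Cholesky factorisation and per-step triangular
  solves.
* Rasterization tie-breaks: a cell takes the material of the region
  containing its centre; regions are matched in a fixed priority order
  (needle parts, tumor, base medium), so overlaps are resolved
  deterministically.
* Zero-duration runs produce a single snapshot, Ω = 0, empty masks, empty
  volumes and no metrics — a graceful degenerate bundle.
* Empty contours revolve to empty volumes; metrics on two empty volumes are
  an error (undefined), a single empty side gives Dice 0 with infinite
  distances.
* Constant fields short-circuit the marching-squares call (all-inside gives
  the domain boundary loop; all-outside gives an empty contour).
* Reruns of `run_case()` with the same config are bit-identical; the run
  manifest records every parameter plus grid statistics.

# Problem sizes

Default grids are ~66 × 168 cells (phantom tank, 0.1 mm minimum cell, 1 mm
cap), chosen so a full 600 s case — EM solve, 1200 implicit steps, damage,
revolution and metrics — completes in a few seconds on one CPU while staying
within the verified convergence regime (halving the EM cell size moves
normalized SAR at probes ≥ 2 mm from the needle by < 5%; halving Δt moves
probe temperatures by < 0.5%). The test suite uses a reduced 20–25 mm tank
for solver-level tests and ≤ 15³ voxel masks where brute-force oracles are
involved.

# Known limitations

* 2D axisymmetry cannot represent heterogeneous anatomy, off-axis vessels
  or a deformed zone; revolved volumes are bodies of revolution by
  construction.
* No vaporization, tissue shrinkage, charring or temperature-dependent
  properties; above ~100 °C the predicted temperatures are upper bounds.
* The heat-sink effect of nearby vessels is absent from the thermal model
  (the vessel-shaped fixture only emulates its *signature* in reference
  segmentations).
* The needle internals are a nominal 50 Ω reconstruction, not the
  proprietary device; the feed-gap width and tip permittivity materially
  shape the near-field and are exposed for sensitivity studies.
* The delivered power is interpreted as fully absorbed (see above).
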