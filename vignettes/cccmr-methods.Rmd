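---
title: "Dose calculation with density-specific kernels in a transverse magnetic field"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose calculation with density-specific kernels in a transverse magnetic field}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Dose calculation for MR-guided radiotherapy must account for the Lorentz
force on secondary electrons: in a 1.5 T field transverse to the beam the
electron trajectories curl, dose distributions become left-right asymmetric,
and electrons crossing into low-density regions gyrate back across the
boundary (the electron return effect, ERE), producing hot and cold spots at
tissue interfaces. Monte Carlo (MC) engines model this directly but slowly.
Collapsed cone convolution/superposition (CCC) is the fast clinical
alternative: precomputed point-spread energy deposition kernels (EDKs) are
transported from the TERMA distribution along a discrete set of cone
directions, with heterogeneity handled by density scaling of the kernel
distances.

A single kernel cannot represent a magnetic field: the distortion of the
electron cloud depends on the mass density, because the gyroradius is set by
the field while the collision range is set by the density. `cccmr`
implements the density-indexed variant of CCC for transverse fields: 3D
kernels are generated by MC in water spheres of eight mass densities (0.25
to 2.0 g/cm^3 in 0.25 steps) for monoenergetic photons of 1-7 MeV, and the
superposition selects (or linearly interpolates) the kernel matching the
*average* mass density between the interaction point and the deposition
point, in addition to classic density scaling via the radiological distance.

## Model and pipeline

The dose at `r` is the superposition over source voxels `s` and spectral
energies of `T_E(s) * K(E, rho_bar(s, r), p(s, r))`, where `T_E` is the
TERMA (total energy released per unit mass by primary photons), `p` the
radiological path length from `s` to `r`, and `rho_bar = p / |r - s|` the
average density along the path. The kernel `K` is the fraction of the
primary photon energy deposited per unit volume around a forced interaction.
The engine realizes this as a scatter (source-driven) collapsed-cone sweep:
every source voxel emits along the 1800 kernel directions; each traversed
voxel receives the differential kernel fraction between its entry and exit
radiological radii.

The full pipeline is:

```{r}
library(cccmr)
kernels <- generate_kernel_set(n_histories = 1e5, seed = 101)   # 7 x 8 EDKs
phantom <- build_phantom("water", spacing = 0.4)
beam    <- beam_spec(c(2, 2), ssd = 143.5)

mc  <- simulate_reference_dose(phantom, beam, default_mc_spectrum(),
                               n_histories = 1e7, seed = 102)

terma <- compute_terma(phantom, beam, energy_spectrum(1:7, rep(1/7, 7)))
mono  <- superpose(terma, kernels, phantom, per_energy = TRUE)
# fit the coarse spectrum so the collapsed-cone depth dose matches the MC
fit <- fit_spectrum(extract_pdd(mc)$dose,
                    sapply(mono, function(d) extract_pdd(d)$dose) * 7,
                    1:7, depths = extract_pdd(mc)$depth)
```

`run_benchmark()` wraps these steps, normalizes both distributions to their
water CAX maxima and evaluates gamma, depth-dose and off-axis agreement.

## The Monte Carlo engine

The built-in engine is a deliberately small condensed-history code, not a
general-purpose MC; it provides the physics that drives the ERE and supplies
*both* the kernels and the reference doses, so the two dose routes share
identical interaction data and the comparison isolates the superposition
approximations.

* **Photons**: Klein-Nishina Compton sampling on free electrons; pair
  production above 1.022 MeV with the pair emitted along the photon
  direction, the positron annihilating at rest into two isotropic back-to-
  back 0.511 MeV photons; the non-Compton remainder below the pair threshold
  is absorbed on the spot (photoelectric-like, photons under 0.05 MeV).
  Branching fractions are tied to the embedded total attenuation table, so
  the MC interaction density and the TERMA model agree exactly. Rayleigh
  scattering and bremsstrahlung photons are omitted (collision-only
  transport); both engines share the omission.
* **Electrons**: continuous slowing down with the embedded water collision
  stopping powers; exact gyration about the field axis (half-rotate /
  translate / half-rotate per step); Highland-formula Gaussian multiple
  scattering (X0 = 36.08 g/cm^2); cutoffs 0.01 MeV (photons) and 0.521 MeV
  electron total energy, residual energy deposited locally. Outside the
  phantom the electron gyrates loss-free and re-enters or is dropped after
  three turns - this is what produces entry/exit-face ERE in the reference
  dose.
* **Steps**: `min(0.1 cm, 2% of the residual CSDA range, 0.1 gyroradius)`
  with a 0.005 cm floor; the floor stops sub-0.5 MeV electrons (residual
  range under a few mm) from consuming hundreds of steps that cannot move
  dose across a 4 mm voxel. `transport_settings(fine_steps = TRUE)`
  restores the 0.001 cm historical step cap.
* **RNG**: counter-based per-history streams (splitmix64-seeded
  xoshiro256**), so results are bit-reproducible for a given seed under any
  work partitioning.

Per-batch sums (10 batches) provide per-voxel relative standard errors, and
every run closes an exact energy ledger (energy in + annihilation energy =
deposited + escaped + rest mass bound in pairs).

## Kernel scoring choices

* Radial grid: 65 shells to 60 g/cm^2, innermost spacing 0.01 and outermost
  5.0 g/cm^2. The interior spacings follow a power-warped geometric
  progression; a pure geometric progression cannot satisfy the two endpoint
  spacings and the total radius simultaneously, so one warp exponent is
  solved numerically (`edk_radial_bounds()`); the grid travels with every
  container so alternatives are drop-in.
* Angular grid: regular 6 x 6 degree bins (30 polar x 60 azimuth = 1800).
  Equal-angle was chosen over equal-solid-angle because it makes each
  angular bin a cone direction and the collapse a pure reshape.
* Sphere radius x density is constant (60 g/cm^2), so all kernels share the
  radiological lattice.
* Deposits by primary charged particles are tagged and accumulated together
  with energy-weighted bin positions (the sums of deposit radius and polar
  cosine), which `characterize_kernel()` turns into the effective depth,
  radial and lateral distances; analytic fixture kernels without scored
  positions fall back to bin centroids, flagged in the result. The total
  kernel (primary + scatter descendants) is what the superposition
  transports; characterization uses the primary component only.

## Superposition numerics

* The cumulative radial table per (density, direction, energy) is evaluated
  linearly in `p` inside a shell; a segment's deposit is the cumulative
  difference between exit and entry radii.
* `rho_bar` is the cumulative radiological length over the geometric length,
  evaluated at the segment exit; kernels are interpolated element-wise
  linearly in density, clamping outside 0.25-2.0 g/cm^3.
* Sources below `1e-6` of the maximum TERMA are skipped (`ccc_settings()`).
* TERMA uses the same attenuation table as the MC, a point source, and a
  sharp-edged divergent field; the fluence of voxels straddling the field
  edge is weighted by the sub-voxel coverage fraction (4 x 4 sampling) of
  their projection onto the collimation plane, which removes the half-voxel
  penumbra bias a binary center-in-field test would cause at 4 mm voxels.
* The spectrum seen by the collapsed cone is not the MC spectrum: following
  the validation design, a 1 MeV-grid spectrum is fitted by non-negative
  least squares so that the superposed depth-dose curve reproduces the MC
  curve at depths at or beyond the maximum (the buildup region is sensitive
  to the spectral discretization, which shows up as a different buildup
  rise). The superposition is linear in the spectral weights, so the fit
  reuses the per-energy dose components without recomputation.

## Evaluation stack

Distributions are normalized to the CAX maximum of the same algorithm's
water-phantom dose for the same field size. Regions follow TG-53: buildup
(shallower than d_max), penumbra (20-80% of the CAX dose at the same depth),
inner (above 80%); voxels below 20% are excluded. The 3D gamma uses global
normalization (3% of the water CAX maximum) and 2 mm DTA with a search
radius of twice the DTA. At a 2 mm lattice the search runs at native
resolution; at the desk-scale 4 mm lattice the DTA is sub-voxel, so
the benchmark interpolates the evaluated distribution trilinearly at 1 mm
steps (`gamma_criteria(subdivide = ...)`) - without interpolation any
sub-voxel shift in a gradient region is judged on dose difference alone,
which standard gamma tools avoid by interpolating. Both the 20% cutoff and
the cutoff-free "entire grid" variant are available (`cutoff = 0`).

## The benchmark conditions and what they show

`desk_preset()` fixes the self-consistency study conditions: 0.4 cm voxels
(21.0 x 15.6 x 15.6 cm^3 phantoms), 2 x 2 cm^2 field at SSD 143.5 cm, the
full 7 x 8 kernel grid at 1e5 histories per kernel, and 1e7 histories per
reference dose. These sizes keep a full three-phantom benchmark within
minutes on one core while the statistical noise stays below the 3% gamma
criterion. The MC source spectrum is a synthetic flattening-filter-free
shape, `phi(E) = E exp(-E / 0.9 MeV)` on a 0.07 MeV grid - a stand-in for a
clinical accelerator spectrum, adequate here because the collapsed-cone
spectrum is refitted to the resulting depth dose, exactly as a commissioned
algorithm would be.

Because kernels and references come from the same engine, the benchmark
measures the superposition approximations themselves (cone discretization,
straight-line density scaling, average-density kernel choice), not the
fidelity of the underlying interaction data to any clinical beam. Passing
it does not show that the engine reproduces a real linac; it shows the
collapsed-cone machinery agrees with a transport solution of its own
physics. Known structural deviations, visible in the benchmark and expected
from the method:

* hot/cold spots at density boundaries are reproduced but underestimated -
  the kernel assumes energy travels along straight density-scaled rays, so
  electrons that would curl back across a boundary ahead of the deposition
  point are not fully represented;
* the dose in the low-density slab is underestimated within the field, the
  more so the larger the field;
* the last voxels before the beam-exit face: the reference MC includes
  electrons returning from the vacuum side, which no infinite-medium kernel
  carries;
* the penumbra shape differs slightly (6-degree angular averaging of the
  kernel distortion).

Two gamma summaries are reported for each phantom: the entire-volume
passing rate (no low-dose cutoff), which is what a whole-phantom "all"
region tallies and is dominated by the out-of-field volume, and the far
stricter in-field rate over voxels above 20% of the normalization dose,
which concentrates on the structural deviations above. At desk scale the
benchmark reaches > 99% entire-volume in all three phantoms while the
in-field rates (about 96% water, 88% heterogeneous) expose the interface
and exit-face deficits directly.

A note on quantifying the kernel distortion: the signed first moment of
the kernel along the drift axis is *not* monotone in density. Below about
0.5 g/cm^3 the electrons complete full gyration loops, so the kernel
becomes ring-like - strongly distorted yet with a receding net first
moment. The monotone trends with density are carried by the effective
depth, the effective radial distance and the forward/lateral elongation
ratio, all of which grow as density increases and the Lorentz force loses
its grip on the shortening electron tracks.

## Known limitations

Differential kernels only (no cumulative-cumulative variant); no kernel
tilting with beam divergence; no off-axis spectral variation; no
patient-CT import; collision-only electron transport without delta rays or
bremsstrahlung secondaries; a synthetic source spectrum rather than a
machine model. The gamma search interpolates only the evaluated
distribution, matching common practice.
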