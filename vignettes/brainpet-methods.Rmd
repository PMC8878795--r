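---
title: "Methods: a desk-scale Monte Carlo and MLEM bench for a dual-layer brain PET ring"
author: "brainpetsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, reconstruction and figures of merit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
detector model, the photon-transport engine, the coincidence processor, the
reconstruction, and the NEMA-adapted figures of merit, together with the
numerical choices behind them and what a desk-scale simulation can and cannot
show about a real scanner.

## The instrument being modelled

The geometry is a brain-dedicated PET ring of the TRIMAGE type: 18 flat
sectors on a regular polygon around the z axis, 3 square modules per sector
along z, 4 tiles (2x2) per module. Every tile carries two stacked LYSO:Ce
crystal layers sharing a 3.4 mm pitch: a 7x7 "top" layer of 3.3x3.3x8 mm
crystals facing the field of view and, behind it, an 8x8 "bottom" layer of
3.3x3.3x12 mm crystals coupled to the SiPMs. The layers are staggered by half
a pitch, and the layer identity of each hit provides a two-level depth of
interaction (DOI) measurement. The ring totals 216 tiles and 24,408 crystals,
with a 164 mm axial and 260 mm transaxial field of view.

The apothem of the sector polygon is not part of the published description;
the package closes the polygon tightly,
`innerRadius = (sectorWidth + gap)/2 / tan(pi/18)` with `sectorWidth = 54.4`
mm and zero default gap, giving 154.26 mm. It is a configurable override, as
are inter-sector gaps. A tile's top layer covers only the central
23.8x23.8 mm of its 27.2 mm footprint; the 1.7 mm borders are modelled as
inactive, while the 0.1 mm inter-crystal reflector gaps inside a layer are
not (crystals are assumed to fill their pitch cell; this overestimates the
sensitive volume by about 6% per layer cross-section).

## Photon transport

`simulateAcquisition()` runs decay-to-singles Monte Carlo:

* **Decays.** Positron emissions are sampled analytically from the shape
  primitives of the phantom, in proportion to activity, with primitive
  precedence enforced by thinning; the accepted count is Poisson at the
  effective positron rate (branching 0.967 for F-18, 0.906 for Na-22).
  Sampling from the analytic shapes rather than a voxelized map keeps a
  0.1 mm point source a true point at any grid resolution.
* **Emission.** The annihilation point is displaced by the positron range
  (per-axis Gaussian; FWHM 1.02 mm for F-18, 1.1 mm for Na-22, both
  toggleable). The first photon is isotropic; the second deviates from
  back-to-back by a folded-Gaussian acollinearity angle of 0.25 degrees FWHM
  at a uniform azimuth.
* **Phantom.** Photons are tracked through the voxelized attenuation map by
  Woodcock (delta) tracking, which is exact for piecewise-constant media.
  All soft-material interactions are treated as Compton scattering off free
  electrons (Klein-Nishina, sampled by rejection under a uniform envelope;
  the photoelectric fraction of water or polyethylene above 100 keV is below
  0.1%). The map stores mu at 511 keV; at other energies mu is scaled by the
  Klein-Nishina total cross-section ratio. Every Compton vertex increments
  the ground-truth scatter counter. Photons are terminated below 20 keV.
* **Detector.** The crystal ring is intersected analytically (18 slab
  boxes); the interaction point is sampled by Woodcock tracking with the
  LYSO attenuation split into a photoelectric part (0.33 of 0.083 mm^-1 at
  511 keV, scaling as E^-3) and a Compton part (Klein-Nishina scaling). In
  the default `"tracking"` model a photoelectric interaction deposits the
  remaining energy, while a Compton interaction deposits the recoil energy
  and the scattered photon is tracked on through the ring; deposits are
  summed per crystal, blurred by the energy resolution (17.8% FWHM at
  511 keV, scaling as 1/sqrt(E)), and every crystal above the 100 keV
  threshold becomes one single. The alternative `"simple"` model stops at
  the first interaction and deposits the full photon energy; it is the
  cleaner object for analytic checks (its photopeak fraction in a 350-650
  keV window is the Gaussian integral 0.9998) but it cannot reproduce the
  strong window dependence of the measured sensitivity, which is why
  tracking is the default.

Timestamps carry the true flight time (mm / c); sub-nanosecond differences
matter for the 5 ns coincidence window. A detector timing jitter is not
modelled, which is conservative for a 5 ns window (coincident photons arrive
within ~1.5 ns even across the full bore).

## DAQ model

Dead time (17.2 us, paralyzable) is applied per tile: the 64-channel ASIC
that reads one tile is the natural busy unit. `sortCoincidences()` applies
the energy window to singles first, clusters the surviving stream with the
5 ns window, discards windows holding more than two singles, and rejects
pairs below the minimal sector separation (default 1). The delayed-window
stream (offset 500 ns) estimates randoms; ground truth classifies each
prompt as true, scattered (same decay, any phantom Compton vertex) or random
(different decays). NECR is computed as T^2/(T+S+R) with single-counted
randoms; both the ground-truth and the delayed-window randoms are reported.

The list-mode format is a 64-byte header (magic, version, packet count,
geometry hash) followed by fixed 24-byte little-endian packets: two uint32
crystal ids, two uint16 energies (keV), a uint64 picosecond timestamp and a
uint16 flag word (prompt/delayed, truth class, truth-valid). At the measured
~132 kHz prompt rate this is 3.17 MB/s of payload.

## Reconstruction

The system matrix is factorized as `N A G R`: per-LOR normalization factors
`N` (crystal-efficiency fan-sums times a sector-difference class factor,
unit mean), per-LOR attenuation factors `A = exp(-integral mu dl)` computed
by exact ray tracing through the mu map, a ray-driven geometric projector
`G` (Siddon/Amanatides-Woo traversal; intersection lengths telescope to the
chord length at machine precision), and a space-invariant image-space
Gaussian PSF `R` with 2.3 mm FWHM applied on both sides of `G` (separable
convolution, reflective boundaries, kernel truncated at 4 sigma). LOR
endpoints are crystal centers; DOI enters through the layer identity.

MLEM runs the multiplicative EM update; the sensitivity image (backprojection
of `N A` over all admissible LORs) is estimated by uniform sampling of
crystal pairs (default 2e6 samples) for the full ring, or computed exactly
from the data LORs on complete-sampling toy problems — the latter mode is
what the log-likelihood monotonicity and count-conservation tests use, since
EM monotonicity is only guaranteed with a consistent sensitivity. The
penalized variant applies a quadratic 6-neighborhood penalty through a
De Pierro separable surrogate, so each voxel update solves a scalar
quadratic; the root is evaluated in the cancellation-free form
`2c / (B + sqrt(B^2 + 4Ac))`, which reduces exactly to the EM update as
`beta -> 0`. The published reconstruction regularizes with the Wang-Qi
technique; the exact variant is not identifiable from the description, so the
quadratic-penalty optimization-transfer scheme documented here stands in,
with `beta` as configuration rather than a reproduced constant, and
`beta = 0` (plain MLEM) as the default everywhere results are reported.
Randoms are handled by delayed-window subtraction per LOR, floored at zero;
no scatter correction is applied (none is described for the instrument), so
reconstructed backgrounds include the scatter pedestal.

## Figures of merit

* **Sensitivity**: prompt true coincidences per positron emission for the
  0.1 mm Na-22 source in its 10 mm acrylic cube at the CFOV, per energy
  window (none / 250-750 / 350-650 keV), with the NU4 branching convention.
* **Spatial resolution**: point sources in a warm background (warm because
  the nonnegativity constraint of MLEM would otherwise underestimate the
  width); background-subtracted 1D profiles through the peak with a
  3-point parabolic peak estimate and linear half-maximum interpolation.
* **Uniformity**: 100 x sd/mean over a 101 mm x 10 mm cylinder VOI in the
  uniform half of the image-quality phantom.
* **Recovery coefficients**: NU4 convention — average the slices covering
  the central 10 mm of the rods, take the axial profile at the max pixel,
  normalize by the uniform mean times the nominal 4:1 ratio; the quoted sd
  propagates profile and background variability.
* **Spill-over ratios**: mean of a cold-rod VOI eroded by 2 voxels from the
  nominal radius over the uniform mean.
* **NECR / SF**: activity sweep of the NU4 rat-like (50 x 150 mm PE, line
  source at 17.5 mm) and head-like (200 x 150 mm PE, line at 45 mm)
  phantoms; frame durations shrink with activity so each point simulates a
  fixed decay budget; the peak is located by a 3-point quadratic fit in
  log-activity; SF is reported from the randoms-negligible regime.

## Decisions where the design was open

* The image-quality rod circle radius (36 mm) makes the six rods equally
  spaced and non-overlapping inside the 135 mm phantom; the rods span the
  upper 50 mm of the 103 mm height, and the uniformity VOI sits at
  z = -30 mm.
* The Derenzo rods use the conventional center-to-center spacing of twice
  the rod diameter within each 60-degree wedge, on a 120 mm phantom.
* The warm-background resolution phantom is not dimensioned in the published
  protocol. The package default is a 212 mm cylinder covering the full
  radial series; the bundled desk-scale experiment uses a 120 mm x 40 mm
  cylinder with 40 kBq point sources at 0, 25 and 50 mm, sized so each point
  collects ~1e4 coincidences — enough for a stable FWHM at the package's
  count budget. A per-voxel contrast prescription was considered and
  rejected: at desk scale it leaves a point source with a few hundred counts
  and an FWHM estimate dominated by noise.
* The scatter-phantom line sources are 1.6 mm radius water channels spanning
  the phantom length (NU4 values; not printed).
* "4.5 cm from the axial center" for the head phantom's line source is read
  as a 45 mm radial offset from the cylinder axis, the NU2/NU4 scatter
  phantom convention.
* Dead-time scope, the 100 keV singles threshold, the 500 ns delayed-window
  offset and the multiple-coincidence kill policy are documented defaults,
  all configurable.

## Problem sizes

The bundled experiments run at a configurable fraction of the published
count scale. The package's reference runs use: 2e5 decays for sensitivity,
3e5 decays per scatter-fraction point, 2.5e5 decays per NECR activity (12
log-spaced activities, 0.5-40 MBq), a 0.02-scale resolution acquisition
(~1.4e7 decays, ~5e5 prompts, 1 mm grid, 100 iterations) and a 0.008-scale
image-quality acquisition (~7e7 decays, ~1.1e6 prompts, 2 mm grid). Rates,
ratios and FWHMs are unbiased under count scaling; the uniformity %STD is
not — it measures noise at the achieved count density and is therefore far
larger here than at full scale, which is why only its trend across
iterations is meaningful at desk scale.

## What the simulation does and does not show

The engine reproduces the structural physics of the instrument: solid-angle
acceptance, dual-layer DOI sampling, windowed energy response of a
photoelectric/Compton mixture, paralyzable tile dead time, randoms growth,
and attenuation. Fidelity gaps, in rough order of importance:

* **Scatter acceptance.** With free-electron Klein-Nishina transport and a
  350-650 keV window, the ground-truth scatter fraction of large phantoms is
  substantially higher than the published instrument values (and the scatter
  pedestal correspondingly lifts the cold-rod spill-over, and loads the NECR
  denominator). The component physics is verified against closed forms
  (Beer-Lambert transmission, Klein-Nishina sampling against numeric
  integration), so this is a modelling-scope difference rather than a
  numerical defect.
* **Detector micro-structure.** No optical transport, no reflector
  materials, no SiPM saturation or per-channel thresholds; inter-crystal
  scatter is tracked but light sharing is not.
* **Point-spread realism.** Data and model both collapse detection to
  crystal identity; with a consistent forward model and ample counts, MLEM
  at 100 iterations recovers a point source sharper than the published
  figures, which were presumably count-limited and regularized.
* No Lu-176 intrinsic background, no Rayleigh scattering, no Doppler
  broadening, no pile-up beyond the dead-time model.
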