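---
title: "Simulating Cherenkov light emission in external-beam radiotherapy of the larynx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating Cherenkov light emission in external-beam radiotherapy of the larynx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

During external-beam photon radiotherapy (EBRT), the secondary electrons
set in motion by the 6 MV treatment beam travel faster than the phase
velocity of light in tissue and emit Cherenkov light. Light that escapes
at the patient's surface can be measured during treatment, and — because
the internal light sources are the treated tissue itself — it opens a
route to tomographic, contrast-free probing of the tumor during the
treatment course. Designing reconstruction algorithms for such
measurements requires knowing, *inside* the patient, where the light is
born, how much of it reaches the surface, in which spectral band, and on
which part of the surface the tumor-born light emerges.

`cherenkovrt` implements this entire simulation-and-analysis chain at desk
scale for a laryngeal (neck) geometry: synthetic voxelized anatomy,
IMRT/VMAT delivery described as control-point sequences, coupled
X-ray–electron radiation transport with dose scoring, Cherenkov generation
from the Frank–Tamm relation, optical Monte Carlo transport to the
surface, monitor-unit (MU) calibration, and the downstream analyses
(surface light maps, spectra, the tumor spot, origin-of-surface-light
distributions, and reduced-measurement-area comparisons).

## Model and assumptions

### Geometry and materials

A `voxel_grid` holds tissue labels (air, skin, adipose, muscle, bone,
tumor, water) and mass densities on a regular lattice, default spacing
$1.0 \times 1.0 \times 1.3$ mm. Coordinates are millimetres in a
right-handed frame: $+x$ toward the patient's left, $+y$ anterior, $+z$
superior. The synthetic neck is a muscle cylinder (radius 50 mm) wrapped
in 5 mm adipose and 2 mm skin, with an anterior air lumen (airway, radius
8 mm), a posterior bone cylinder (vertebral stand-in, radius 12 mm) and an
ellipsoidal tumor ($8 \times 8 \times 10$ mm) lateral to the lumen —
dimensions chosen as typical adult-neck values. Densities are nominal
bulk values plus seeded Gaussian jitter (sd 0.02 g/cm³), emulating the
voxel-to-voxel variation a CT-derived density map would show. A
piecewise-constant density-to-tissue calibration table stands in for a
scanner calibration curve.

### Radiation transport

The therapeutic photons interact predominantly by Compton scattering; the
package transports X-rays with two channels only:

* **Compton scattering**, with the polar angle sampled from the
  Klein–Nishina differential cross-section by rejection and the secondary
  electron taking $E - E'$ with the momentum-balancing direction;
* **photoelectric absorption**, which deposits the photon energy locally.

Free paths are sampled against the heterogeneous attenuation by 3D DDA
ray marching. Attenuation tables are built from the closed-form
Klein–Nishina total cross-section times the electron density
($\rho N_A Z/A$) plus an effective-Z power law
($\propto Z_{\mathrm{eff}}^{3.6}/E^3$, anchored to the water photoelectric
cross-section at 10 keV) — the resulting water mass attenuation agrees
with the standard reference values to a few percent over 0.01–6 MeV.
Rayleigh scattering and pair production are omitted; at 6 MV they are
minority channels, and their omission slightly hardens the beam without
touching the mechanism under study.

Secondary electrons slow down continuously (CSDA) along straight lines in
0.1 mm steps, depositing (stopping power × step × density scaling) at
each step midpoint; the water collision stopping-power curve, scaled by
mass density, is used for every tissue (soft-tissue mass stopping powers
differ from water by only a few percent). Electron multiple scattering
and bremsstrahlung are omitted — a documented bias: real dose
distributions are laterally wider and slightly shorter-ranged than the
straight-line CSDA ones. The simulated central-axis depth dose in water
still shows the characteristic build-up with a maximum near 1.5 cm.

Absorbed dose is energy per voxel mass (volume × local density); the
`units` flag distinguishes per-particle from physical grids.

### Cherenkov emission

While an electron's kinetic energy exceeds the local threshold
$E_{\mathrm{thr}} = m_ec^2\left(1/\sqrt{1 - n^{-2}} - 1\right)$
(0.219 MeV at $n = 1.4$ — the "~0.2 MeV" figure for soft tissue), each
step emits a Poisson number of photons with mean given by the band
integral of the Frank–Tamm spectral density,

$$\frac{d^2N}{dx\,d\lambda} = \frac{2\pi z^2}{137.036}
\left(1 - \frac{1}{\beta^2 n^2}\right)\frac{1}{\lambda^2},
\qquad
\frac{dN}{dx}\Big|_{[\lambda_1,\lambda_2]} = \frac{2\pi z^2}{137.036}
\left(1 - \frac{1}{\beta^2 n^2}\right)
\left(\frac{1}{\lambda_1} - \frac{1}{\lambda_2}\right),$$

with $z$ the charge number of the emitting particle. We read $z$ as the
*particle* charge ($z = 1$ for electrons), the standard Frank–Tamm usage;
it is configurable. Wavelengths are drawn from the $1/\lambda^2$ density
by inverse CDF over 500–1200 nm and directions on the Cherenkov cone
$\cos\theta_c = 1/(\beta n)$ with mid-step $\beta$. The 500–1200 nm band
matches the range over which tissue optical properties are defined; light
below 500 nm is so strongly absorbed in tissue that it does not
contribute to surface measurements.

Emission is analog (integer photons, each carrying its birth position) by
default because the origin-of-surface-light analysis needs per-photon
provenance; an expected-value mode (`analog = FALSE`) scores the mean
emission per voxel without a photon bank for variance-reduced emission
maps. For memory control the bank can be uniformly thinned
(`keep_prob`), capped (`bank_cap`), or restricted to photons born in one
tissue (`birth_tissue`); thinning is unbiased and leaves the emission
grid untouched.

### Optical transport

Each optical photon performs exponential-path sampling against the
spectrally interpolated local $\mu_t = \mu_a + \mu_s$, accumulated voxel
by voxel (DDA); at an interaction it is absorbed with probability
$\mu_a/\mu_t$, otherwise deflected by the closed-form Henyey–Greenstein
inverse CDF with the local anisotropy $g$. At tissue–air interfaces
(including the airway lumen and the domain boundary) the unpolarized
Fresnel reflectance decides reflection versus Snell refraction, with
total internal reflection beyond the critical angle; interior
tissue–tissue interfaces are index-matched (tissue indices are close and
the boundary physics of the reference simulations is unspecified — a
`fresnel = FALSE` switch gives the simple-escape alternative).
Wavelength is fixed at birth. A hard event cap (default $10^6$,
counting scattering and boundary events) terminates pathological
histories as absorbed, keeping the photon-count balance exact:
births = absorbed + exited + capped.

### Tissue optical properties

Fully tabulated per tissue on a 10 nm grid over 500–1200 nm and
config-overridable. The shipped defaults are smooth parametric
approximations of the usual literature families: a hemoglobin-like
visible band (strong below 600 nm, weak deoxy-like 760 nm feature), a
water fraction (rising absorption beyond 900 nm), a lipid 930 nm feature
for adipose and a melanin-like term for skin; reduced scattering follows
$a(\lambda/500)^{-b}$ converted through $g$. They reproduce the
qualitative spectral shape that drives every conclusion here — visible
absorption two orders of magnitude above the near-infrared window — but
are not fits to any specific measurement, and no quantitative claim in
the package rests on their absolute values. Tumor and adipose share one
anisotropy curve. Refractive indices are wavelength-independent (muscle
and tumor 1.40, skin 1.42, adipose 1.44, bone 1.55, water 1.33).

### Treatment plans and the source model

Plans are control-point sequences. The shipped defaults carry the
delivery characteristics of the two studied treatments: IMRT with a
left-lateral beam at gantry 90° (8 control points, 157.5 MU) and a
right-anterior-oblique beam at 278° (10 control points, 155.1 MU); VMAT
with two 114-control-point arcs, 100°→260° counter-clockwise (360.7 MU)
and 260°→100° clockwise (306.6 MU). Gantry angle is referenced to
gravity: 0° points the beam along $-y$, angles increase toward the
patient's left. MU totals are split uniformly across control points
unless per-point weights are supplied, since plan-level weights are not
published. Arc spans are fully configurable: the source descriptions of
this delivery are internally inconsistent (200° arcs versus the
100–260° = 160° tabulated ranges), so the tabulated ranges are the
default and no claim of clinical equivalence is made.

Vendor phase-space files and true multileaf-collimator geometry are
proprietary and out of scope. The source is a point at 100 cm
source-axis distance emitting through a binary aperture mask (2.5 mm
cells in the isocenter plane — the MLC stand-in, preserving the
intensity-modulation mechanism without leaf transmission), with energies
from a parametric 6 MV histogram spectrum
($\propto E e^{-E/1\,\mathrm{MeV}}$ on 0.25–6 MeV; mean ≈ 1.9 MeV, a
documented property within the 1.5–2.5 MeV range expected of 6 MV
beams).

### MU calibration

The linac convention is that 1 MU delivers 1 cGy at depth $d = 1.5$ cm on
the beam axis in water at 100 cm source-surface distance with a
10×10 cm field. `calibrate_mu()` reads the per-particle dose $D_d$ at
the axis voxel nearest that depth in a simulated 30×30×50 cm water
phantom (beam along $-z$) and sets $N = 1\,\mathrm{cGy}/D_d$ particles
per MU; `scale_to_physical()` multiplies any per-particle quantity by
$N \times \mathrm{MU}$. The calibration is exact by construction at the
calibration point — the package verifies the pipeline wiring, not a
physical constant. With an even voxel count the axis falls between
voxels; the tie goes to the lower index.

## Derived analyses

* **Surface maps** bin exits per exposed voxel face (photons/mm²),
  optionally median-filtered over each element's ≈3×3 neighbourhood
  (elements within Chebyshev distance 1 in voxel indices — the kernel is
  a package choice, configurable) and thresholded at a fraction of the
  maximum: 5% for the full 500–1200 nm band, 10% for the narrow
  710–720 nm band.
* **Spectra** are contiguous wavelength histograms, peak-normalized
  (sum-normalization available).
* **Tumor spot**: the largest connected component of the (unthresholded,
  by default median-filtered) tumor-born surface map at ≥50% of its
  maximum; the fraction is configurable since the underlying notion is
  qualitative. Ties go to the component containing the smallest element
  id. Because the synthetic tumor abuts the airway — as laryngeal tumors
  do — part of the tumor-born light exits into the lumen, and the spot
  may include lumen surface as well as external skin.
* **Origin distributions** histogram the birth positions of photons whose
  exit element lies in a region (photons/mm³).
* **Reduced areas**: anterior-half surface bands of a given width along
  the left-right axis (defaults 100 and 80 mm) centered on the spot's
  area-weighted centroid.
* **Similarity** between two origin distributions is the histogram
  intersection of the unit-sum-normalized grids,
  $\sum_v \min(a_v, b_v)$ — bounded in [0, 1], 1 iff identical, 0 for
  disjoint support. The underlying comparison is qualitative; a bounded,
  interpretable overlap makes the reduced-area statement testable.
* **Display cut-offs** (`apply_fraction_cutoff`): 1% of maximum for
  emission maps, 10% for dose maps.

## What the synthetic data does and does not emulate

The generator reproduces the *mechanisms*: layered heterogeneous anatomy
with realistic densities, an air lumen and bone, a tumor at a realistic
depth (~25–30 mm below the skin), spectrally resolved optics with a
visible/NIR contrast, modulated multi-angle delivery, and seeded
stochastic density texture. It does not reproduce any real patient's
anatomy, true MLC leaf sequences, measured optical constants, or the
vendor source spectrum. Passing tests therefore demonstrate that the
chain is correct (oracles, conservation, closed forms) and that the
qualitative findings — light co-localized with dose, NIR-dominated
surface light, a stable tumor spot, near-complete 10 cm reduced-area
measurements — emerge from the mechanisms alone; they do not validate
absolute light yields for any real patient.

## Numerical choices

* Electron step 0.1 mm (≪ voxel size; the step-sum oracle test pins the
  stepping), energy cutoffs 10 keV for electrons and X-rays; residual
  energy is deposited locally.
* Attenuation/stopping tables on an 80-point log grid over 0.01–6 MeV,
  linearly interpolated; optical tables linearly interpolated in
  wavelength.
* Interaction points are placed exactly where accumulated optical depth
  equals the sampled depth; positions are recomputed from the flight
  origin to avoid drift.
* All randomness (R and C++ alike) draws from R's RNG, so a single
  `set.seed()` makes runs bit-identical.
* Degenerate inputs: zero-density voxels transport as vacuum and may not
  receive dose; `mu_t = 0` gives an infinite free path; air cannot emit
  (its threshold is infinite) or host optical photons (birth in air is an
  error).

## Problem sizes used by the shipped tests

Chosen so each check has comfortable statistical margin: $10^5$ source
photons for the water calibration (2 mm voxels) and the slab
transmissions; $10^6$ photons for the wavelength KS test, the
Henyey–Greenstein moment and the diffusion Green's-function comparison
(observed agreement ~3%, asserted at 15%); $10^5$ primaries with the
Cherenkov bank thinned to ~$10^6$ traced photons for the end-to-end
surface analyses; two independent $2\times10^5$-primary tumor-only runs
for spot stability (observed Jaccard ≈ 0.8, asserted > 0.5).

## Known limitations

Straight-line electrons (no lateral scatter) narrow the dose penumbra;
the two-channel photon physics omits Rayleigh and pair production; the
water-based stopping/attenuation scaling ignores composition differences
beyond $Z/A$ and $Z_{\mathrm{eff}}$; optical constants are parametric
approximations; the surface is the axis-aligned exposed-face mesh (exact
per-face bookkeeping, no smoothing — a marching-cubes style export is
available only for visualization via PLY); no polarization, fluorescence
or time-resolved transport. Comparisons against clinical
treatment-planning systems and tomographic reconstruction are out of
scope.
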