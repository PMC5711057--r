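---
title: "Monte Carlo MLC transport and VMAT QA: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo MLC transport and VMAT QA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlcport)
```

`mlcport` is a desk-scale Monte Carlo toolchain for the problem at the heart
of patient-specific VMAT quality assurance: an independent calculation of the
dose a treatment plan delivers, with the multileaf collimator (MLC) modeled
well enough that transmission, interleaf leakage, tongue-and-groove dips and
rounded-tip penumbra all show up in the result. This vignette documents the
models, their assumptions, the tunable parameters, and the numerical choices,
in that order.

## The simplified leaf transport

Photons are carried through the MLC with a deliberately reduced interaction
set: **primary attenuation plus a single Compton scatter**, and nothing else.
Electrons set in motion in the leaves are not followed, photoelectric
absorption and pair production in tungsten remove photons but create no
secondaries, and a Compton photon that scatters once is attenuated but never
scattered again. This is the classic fast-MLC-model compromise: through
6–7 cm of tungsten the transmitted signal is dominated by the exponentially
attenuated primary and the first-scatter buildup, while higher orders change
the transmitted *dose* by far less than the ~0.1% (of open field) resolution
a transmission measurement probes.

Two variance-reduction choices make the 1%-scale transmission measurable
with ~10^6^ histories on one core:

* **Forced transmission.** The primary is never absorbed by sampling;
  its statistical weight is multiplied by $e^{-\mu t}$ along its tungsten
  radiological path $t$ (in g/cm^2^, so $\mu$ is the mass attenuation
  coefficient). The dominant signal is then carried with almost zero
  variance.
* **Forced first scatter.** Each attenuated primary spawns exactly one
  Compton photon with weight
  $w\,(1 - e^{-\mu t})\, f_c\, e^{-\mu' r}$, where $f_c$ is the Compton
  share of the total cross section, the interaction depth is drawn from the
  truncated exponential along the chord, the angle and scattered energy
  follow Klein–Nishina sampling (Kahn's composition/rejection method), and
  $r$ is the scattered photon's own residual tungsten path at its energy.
  Whether first-scatter photons should be re-attenuated on the way out is
  not something the reduced model pins down by itself; we attenuate them,
  which keeps the total outgoing weight bounded by the incoming weight.
  Scattered photons heading away from the patient are dropped — they cannot
  reach any scoring plane below the MLC.

Interaction data are embedded tables at standard reference energies
(0.01–10 MeV, log-spaced): total mass attenuation for tungsten and water,
and the water mass energy-absorption coefficient for kerma scoring. The
incoherent component is computed from the closed-form total Klein–Nishina
cross section scaled by $Z/A$, which keeps the Compton fraction used for
branching exactly consistent with the angular sampler. Lookups interpolate
log-log and are exact at the nodes.

## The leaf geometry model

The MLC is described by per-leaf projected widths, two thickness-versus-
cross-leaf-position tables (one per half of the leaf height), and a small
set of scalar parameters: physical thickness, tip radius of curvature, tip
facet angle, maximum tip thickness, density, closed-pair tip offset, and the
distance of the upper MLC surface from the source.

* The **HD120** preset has 60 leaves per bank — 32 quarter-centimeter
  central leaves and 28 half-centimeter outer leaves, projecting to 22.0 cm
  at isocenter — a 6.9 cm leaf height, a 16 cm tip radius and no tip facet.
  Its packaged density is 18.9 g/cm^3^, the transmission-calibrated value.
* The **Millennium120** preset has 6.7 cm leaves, an 8 cm tip radius and the
  11.3° tip facet, applied as a planar cut tangent to the tip arc.

The numeric content of the vendor geometry tables is proprietary, so the
packaged tables are *synthesized*: full-height leaf bodies; the upper-half
metal shifted half a tongue width toward $+y$ and the lower half toward
$-y$, forming the interlocking tongue-and-groove; a vertical clearance that
makes the summed thickness dip below the full height inside the step
region; and an air gap between adjacent leaves within each half. A ray near
a leaf joint therefore crosses, depending on its exact position, full metal,
the clearance-reduced overlap, or a half-thickness channel — the structure
that produces interleaf leakage peaks in real MLCs.

Three idealizations matter when interpreting results:

* **Focused side faces.** The tables are indexed at the mid-plane of the
  leaf assembly and queried at `y * z_mid / z`, which makes leaf side faces
  converge toward the source. Real Varian leaf sides are parallel, so the
  geometric interleaf channel widens off the mid-plane in reality but not
  in the model. We compensate with an *effective* air gap (default
  0.0115 cm, a little wider than a physical leaf-side clearance), fixed
  once by the standard commissioning condition: the packaged HD120 at its
  calibrated density must reproduce the measured mean MLC transmission
  (~1.1% for a flattened 6 MV beam). This mirrors how such models are
  commissioned in practice — the measured transmission pins the one
  geometric degree of freedom the vendor tables would otherwise fix.
* **Tip model.** The leaf end is a circular arc spanning the leaf height,
  positioned so the ray from the source grazing the arc projects to the
  nominal leaf position at isocenter (tangent calibration); opposing closed
  tips are separated by the configurable `leaf_offset`.
* **Mid-plane attachment.** Each half's tungsten is attached at the
  interface between the two halves; for the near-vertical rays of a
  treatment beam the chord length, not the attachment side, is what counts.

Radiological paths are evaluated by midpoint integration across the leaf
height (default 128 steps, ~0.05 cm). A full-body chord is exact by
construction (the integration limits coincide with the leaf surfaces);
discretization error appears only for rays crossing tip arcs or leaf-side
steps, and the suite holds the tracer to within 1% of a dense-step
(0.004 cm) oracle on randomized rays and apertures.

One geometric subtlety is worth recording: the source phase plane sits at
55 cm from the target while the upper MLC surface default is 50.9 cm, so
with 6.9 cm leaves the phase plane falls *inside* the leaf assembly's
z-extent. Both values are kept — they are the documented conventions — and
transport resolves the overlap by rewinding each source photon along its
straight line from the focal spot before tracing, which is exact for
focal-spot photons.

## The source and VMAT synchronization

The vendor phase space is proprietary, so the source is parametric: a point
focal spot, a binned energy spectrum, and a radial fluence profile on the
55 cm phase plane. The `6X` preset uses a bremsstrahlung-like shape
$(E - 0.25)\,e^{-E/0.80}$ binned on 0.25–6 MeV (mean 1.82 MeV) with a flat,
mildly horned profile; `6X-FFF` uses $(E - 0.15)\,e^{-E/0.50}$ (mean
1.15 MeV) with a forward-peaked Gaussian profile (σ = 10 cm projected to
isocenter). These are stated approximations — the real spectra are not
public — packaged as editable CSV tables.

Dynamic delivery follows the meterset-synchronization contract: each history
draws a cumulative meterset fraction $u \sim U(0,1)$ and the machine state
(gantry angle, every leaf, every jaw) is interpolated linearly in $u$
between the bracketing control points, exactly at nodes, with gantry angles
unwrapped across the 360° seam. Uniform $u$ sampling delivers fluence per
control-point interval proportional to its meterset width, which is the
whole point: dose-rate modulation is represented by how densely control
points populate the meterset axis, not by a separate dose-rate variable.

## Scoring: collision kerma in water

There is no coupled electron transport in the phantom either. Dose is
approximated by **collision kerma under charged-particle equilibrium**:
each photon deposits
$w\,E\,(\mu_{en}/\rho)_\text{water}(E)\;e^{-(\mu/\rho)_\text{water}(E)\,d}$
at water-equivalent depth $d$, either on a plane through the isocenter
(film-plane geometry; the plane follows the gantry) or in a room-fixed
water box with a track-length estimator (depth measured from the box entry
point, so rotating deliveries accumulate correctly). The buildup region is
explicitly unsupported — comparisons should be made at depths beyond
electron equilibrium (the standard 5 cm and 10 cm planes are). In-phantom
scatter is likewise absent; transmission and pattern comparisons are ratio
or shape measurements in which this largely cancels, but absolute
percentage-depth-dose curves are out of scope.

Per-voxel relative uncertainties come from batch statistics (default 10
batches by history index); doubling histories shrinks them as $1/\sqrt{N}$,
which the suite verifies.

Simulated grids are normalized per source history; the jaw field area is
recorded so that `output_factor()` can put fields of different size on a
common per-unit-incident-fluence scale. Because the model has no collimator
head scatter and no phantom scatter, simulated output factors stay near
unity by construction; the field-size trends a water-tank measurement shows
are mostly physics outside this model, and the function's documentation
says so.

## Absolute dose

Monte Carlo dose per particle becomes absolute dose by the linear
calibration
$D_{abs} = D \times \frac{D^{cal}_{meas}}{D^{cal}_{MC}} \times U$,
with the calibration field the 10×10 cm^2^ reference at SAD 100 cm and
10 cm depth and $U$ the plan's monitor units. The monitor-backscatter
correction that a full virtual-linac calibration would carry is fixed at
zero — the construction of the monitor chamber needed to model it is not
available for this machine generation, and ignoring it reduces the
conversion to one factor. The constructor enforces the zero.

## Adaptive Savitzky–Golay denoising

The filter fits, per voxel, an order-2 polynomial (full 10-term 3D
quadratic basis) by weighted least squares over a cubic window, weights
$1/\sigma_i^2$ from the stated per-voxel uncertainties. Candidate window
half-widths are tried largest-first (default 4, 3, 2, 1 voxels); the first
whose fit passes a chi-squared test — reduced $\chi^2 \le 1 +
2\sqrt{2/\nu}$, i.e. within two standard deviations of the
$\chi^2_\nu$ expectation — supplies the voxel's fitted central value and a
new uncertainty from the fit covariance. If no window passes, the voxel is
returned untouched. That is the whole adaptivity mechanism: in smooth
regions the 9^3^ window passes and noise drops by roughly the square root
of the effective number of points; at a sharp dose step every window fails
and the edge survives exactly. The threshold multiplier is configurable
(`chi_mult`); the published descriptions of this filter name the test but
not the constant, and 2 is our choice, recorded here.

On the synthetic acceptance phantom (a broad flat-topped field with
Gaussian-like edges on a 50^3^ grid, 2% Gaussian noise with matching stated
uncertainties) the filter takes the high-dose-region RMS deviation from
truth from 2.0% to ~0.6%, comfortably under the 1% working target, without
biasing the flat-top mean.

## Gamma analysis

`gamma_3d()` implements the global-normalization gamma index: for each
reference voxel above the ROI threshold (default 20% of the reference
maximum),
$\gamma = \min_r \sqrt{(\Delta D / \Delta D_c)^2 + (|r| / \Delta d_c)^2}$
with 3%-of-maximum / 3 mm defaults. The evaluated grid is trilinearly
interpolated on a 0.3 mm cubic subgrid within a neighborhood capped at
3×DTA, visited in order of increasing distance so the search can stop as
soon as the distance term alone exceeds the running minimum — an exact
search over the discrete candidate set, verified voxel-for-voxel against a
no-shortcut brute-force oracle. Whether to interpolate or use voxel centers
is a genuine implementation freedom in gamma analysis; the subsample step is
a parameter so the choice is visible. The comparison is deliberately
asymmetric (normalization and ROI come from the reference grid), and a test
documents that exchanging the grids changes the answer.

## Transmission analysis and density calibration

`mean_transmission()` averages the voxelwise blocked/open ratio over a
12 cm span across the leaves (band along leaf motion configurable) — the
film-measurement recipe. `calibrate_density()` reproduces the commissioning
loop: simulate the blocked/open pair, compare with a target transmission,
and adjust the leaf density by bracketing root-finding (transmission is
monotone decreasing in density). All evaluations share one seed so the
objective is deterministic; the suite shows a round trip (simulate at a
shifted density, calibrate back) recovers the density within 1%.

## Validation patterns

The `patterns` generators reproduce the standard commissioning fields as
plans: the 15×17 cm^2^ open/blocked transmission pair (4000 MU blocked),
the static odd-leaf bar aperture, and three dynamic fields — a multibar
pattern with 7, 5 and 2 mm bars delivered simultaneously, a cross-leaf
gradient, and a negative pyramid (center-minimal, gradients along both
axes). The dynamic fields are realized as unidirectional sliding-window
sequences synthesized from their target fluence profiles: the leading edge
trajectory absorbs the negative fluence gradients, the trailing edge
follows at the exposure lag, and control points are placed at the meterset
values where the profile jumps so that linear interpolation between control
points is faithful. These are *equivalents* of the original delivery files
(which are not available), not replicas: bar positions and amplitudes are
parameters, and each plan's intended fluence is asserted analytically in
the tests via `plan_fluence()`.

## What the synthetic data do and do not show

Everything the acceptance checks exercise — transmission level, leakage
structure, filter behavior, gamma mechanics — runs on synthesized geometry
tables, parametric spectra and constructed noise. Passing them shows the
transport, the estimators and the QA algorithms are internally correct and
consistent with the commissioning-level numbers used to pin the model. It
does **not** show agreement with a particular linac's measured PDDs,
profiles, output-factor trends or patient plans: those depend on the real
phase space, the real leaf drawings and measurement hardware, all outside
this package. The honest reading is: the machinery is right, and the two
inputs that would make it machine-specific (spectrum, geometry tables) are
cleanly replaceable files.

## Problem sizes and numerical defaults

The shipped defaults are chosen for single-core desk-scale work:
transmission runs use 10^6^ histories per field with 2 mm planar voxels
(statistical error far below the 0.1% transmission scale, thanks to the
deterministic primaries); the denoising demonstration uses a 50^3^ grid;
tracer integration uses 128 steps across the leaf height; gamma uses the
0.3 mm subgrid. Each is a function argument, not a constant. Degenerate
inputs are rejected loudly: empty spectra, zero-area fields, inverted jaws,
closed-pair violations, rays parallel to the MLC plane, grids with missing
uncertainties, non-monotone meterset sequences and malformed table files
all raise errors naming the offending input.

## Known limitations

No electron transport anywhere (buildup and interface effects absent); no
head scatter, so output factors are near-unity by construction; no
phantom scatter, so only ratio/shape comparisons are meaningful; first
scatter only, so the leakage spectrum under very thick blocking is slightly
hard; parallel leaf sides are represented by focused sides plus an
effective gap, so the *off-axis growth* of interleaf leakage is
underestimated even though the mean is calibrated; the Millennium tip facet
is a single tangent cut; DICOM-RT plan import is not provided (the native
JSON plan dialect is documented and round-trip tested).
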