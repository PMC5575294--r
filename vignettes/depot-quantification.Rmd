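---
title: "Quantifying drug depot permeation from time-lapse radiographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying drug depot permeation from time-lapse radiographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depotr)
```

## The measurement problem

A solution infused into subcutaneous or muscle tissue forms a depot
around the needle tip. With an iodinated solution, a 2D radiograph
records, at every pixel, the beam attenuated by the solution along the
propagation direction — so a time-lapse stack carries the depot's shape,
its advancing boundary (the wetting front, WF) and the path-integrated
local solution content (the relative content of solution, RCS).

`depotr` implements the whole chain from raw detector counts to physical
quantities, plus a synthetic generator that produces radiograph stacks
with known ground truth so that each stage of the chain can be validated
by recovery rather than by eye.

## Physical models and their assumptions

### Darcy point source

The transport model treats the tissue as a homogeneous, isotropic porous
medium and the needle tip as a point source of volumetric flow $q$. Mass
conservation gives the radial seepage velocity $v(r) = q/(4\pi r^2)$;
with Darcy's law $v = -k\,\partial p/\partial r$ and integration from the
depot radius $r_t$ outward,

$$p_t = \frac{q}{4\pi k\, r_t} \quad\Longrightarrow\quad
  k = \frac{q}{4\pi p\, r_t}.$$

`permeability_darcy()` evaluates the right-hand form in SI, taking the
applied pressure from the empirical correlation
$p\,[\mathrm{kPa}] = 0.74\, q\,[\mu L/s] + 23$ when none is measured.
`permeability_compact()` is the algebraically equivalent compact form
$k = \tfrac{1}{2.96\pi r_t}\cdot\tfrac{q}{q + 31.08}$ (the constants are
$4\pi\cdot 0.74$ and $23/0.74$); a property test asserts the two agree to
relative $10^{-6}$ over a wide $(q, r)$ grid.

Assumptions worth keeping in mind: stationary incompressible flow,
no poroelastic deformation, a sharp depot boundary, and a pressure at the
needle tip equal to the pressure at the depot surface.

### Depot growth and the normalized front

During infusion, volume balance for a spherical depot with effective
volume fraction $\varepsilon$ gives
$\varepsilon \tfrac{4}{3}\pi\, \mathrm{WF}(t)^3 = q\,t$, i.e. the
cube-root law $\mathrm{WF}(t) = (3qt/4\pi\varepsilon)^{1/3}$ and its
dimensionless form $R(t) = \mathrm{WF}/\mathrm{WF}_m = (qt/Q)^{1/3}$,
which is independent of $\varepsilon$. `fit_normalized_wf()` fits the
single free scale $\mathrm{WF}_m$ by least squares **on WF** (not on
$R$), then reports $R^2 = 1 - SS_{res}/SS_{tot}$ on the normalized
trace. Fitting on WF keeps the estimator linear and puts the weight on
the late, well-measured samples; a constant or decreasing trace is
flagged degenerate with a warning rather than rejected.

### Injection criteria

Two empirical relations complete the picture. The tissue resistance
pressure $\mathrm{TRP}\,[\mathrm{kPa}] = 10.4\,q\,[mL/min] + 1.14$ is the
back-pressure the device must overcome. The fracture toughness of a
pressurized micro-crack of width $h$ in tissue of Young's modulus $E$,
$J = P^2 h / (1.27 E)$, compared with a tissue threshold $J_a$, separates
two regimes: below $J_a$ the solution permeates through existing
interfaces; at or above it, the injection opens a micro-crack network and
preferentially spreads horizontally. `assess_fracture()` uses the
boundary-inclusive rule $J \ge J_a$; the reference operating points only
compare orders of magnitude, so the choice of boundary convention is
immaterial in practice.

**Unit conventions.** The correlations are dimensional fits and their
flow units are not interchangeable: the pressure correlation takes $q$ in
µL/s (back-calculation against its published operating point at
25 µL/min — 0.74·0.4167 + 23 = 23.31 kPa — fixes the unit), while the TRP
relation takes $q$ in mL/min (10.4·0.025 + 1.14 = 1.40 kPa). Every public
function therefore takes an explicit `flow_unit` argument and converts
internally; a unit round-trip test guards the conversions.

**A recorded discrepancy.** Evaluating the pressure correlation at
6 mL/min (100 µL/s) gives 97.0 kPa, while the reference fast-injection
operating point is stated as 94 kPa. The package always evaluates the
correlation; 94 kPa is treated as an empirical anchor where one is
needed (see the Young's modulus default below).

## Imaging chain

Flat-field correction removes the detector's fixed pattern:
$\mathrm{FFC} = (\mathrm{object} - \mathrm{offset}) /
(\mathrm{gain} - \mathrm{offset})$, with the gain image averaged over
repeated sample-free exposures (10 by default in the generator, averaging
reduces flat noise by $\sqrt{n}$). Pixels where gain does not exceed
offset are masked (`NA`), and masks propagate through every downstream
operation. The Beer–Lambert inversion
$x = -\ln(\mathrm{transmission})/\mu$ then yields solution path length
per pixel; the RCS map is the same inversion relative to a pre-onset
baseline frame, $\mathrm{RCS} = \ln(\mathrm{baseline}/\mathrm{frame})/\mu$,
with negative (noise) values clipped to zero.

Sample drift is compensated by integer-pixel translation maximizing the
mean-subtracted cross-correlation against a reference frame (computed by
FFT); sub-pixel registration is deliberately not attempted — wetting
fronts are read at pixel resolution anyway, and a half-pixel drift test
shows recovery within one pixel. An optional mask excludes the needle
region (stationary in the lab frame) from the similarity score.

The projection model is parallel-beam. The real acquisition geometry is
cone-beam (source–detector 100 cm, sample–detector 60 cm), so absolute
magnification is ignored; all lengths are in detector-plane units. This
is a documented limitation, not a correction the package attempts.

## Front tracking and derived quantities

`detect_wf()` finds the outermost distance at which a 3-sample
median-smoothed profile exceeds
$\mathrm{floor} + f\,(\mathrm{peak} - \mathrm{floor})$ with $f = 0.1$ by
default. The outermost crossing is the tie-break so interior dips (local
texture) do not truncate the front; a profile that never exceeds the
threshold returns a distinguished no-front `NA` rather than zero.
`track_wf()` applies this along thin median bands through the needle tip
— both horizontal sides (taking the outermost) and downward — and, when
no explicit noise floor is supplied, estimates one per frame as five
times the standard deviation of the RCS map's corner patches, gated on
the near-needle RCS so pure-noise pre-onset frames yield no front.

Samples are labelled IR (injection region) while $t \le Q/q$ and DR
(diffusion region) afterwards; the boundary is placed at the end of
infusion, which is the natural switch between pressure-driven and
concentration-gradient-driven spreading. The depot aspect ratio
$\mathrm{WF}_v/\mathrm{WF}_h$ is summarised per region by its mean and
the standard deviation **across frames** (the spread of a ratio
time-series, not a replicate error). The coefficient of variation
$C_v = \sigma/\mu$ of ROI intensities uses the population $\sigma$; the
three standard ROIs (0.9 mm squares — 100 px at 9 µm) sit on the needle
tip and on the first post-onset front positions.

Onset is declared at the first time the needle-adjacent RCS exceeds the
pre-onset baseline mean plus $3\sigma$, sustained for 3 frames;
quasi-saturation at the earliest time after which the relative front
range within every subsequent 60 s window stays below 1 %. RCS profiles
use a 0.9 mm × 0.9 mm sliding window stepped outward from the needle;
for temporal comparisons all profiles of a sequence are normalized by the
single global maximum so that one scale spans the whole experiment
(per-profile normalization would hide filling).

## The synthetic generator

`generate_stack()` emulates, per frame: (i) an ellipsoidal depot whose
semi-axes satisfy the volume balance
$\varepsilon \tfrac{4}{3}\pi a_h^2 a_v = \max(0,\; qt - V_{lag})$ at a
fixed axis ratio (the beam-axis semi-axis equals the horizontal one);
(ii) Beer–Lambert attenuation along analytic ellipsoid chords;
(iii) detector fixed gain/offset patterns, Poisson shot noise on the
photon signal, Gaussian read noise and 16-bit quantization; (iv) slow
sample drift (depot and optional tissue texture move together, the
detector pattern does not); and (v) the flat-field calibration exposures
themselves, with the same noise model.

The onset lag is modelled as a dead volume $V_{lag}$ that must accumulate
before solution enters the tissue — an interpretation consistent with the
observed delays at both pump rates (100 µL at 100 µL/min gives 60 s; at
25 µL/min the same dead volume predicts 240 s against an observed
220 s, so $V_{lag}$ stays per-scenario configurable rather than fixed).
After infusion ends the front is frozen by default (quasi-saturation);
an optional power-law relaxation supports aspect-ratio-drift
experiments. The depot is uniformly filled (sharp front) by default; an
optional linear concentration taper over a configurable rim width
(`front_rim_mm`) produces graded fronts for threshold-sensitivity tests.

What the generator does **not** emulate — and what passing recovery
tests therefore cannot certify on real data: poroelastic coupling and
time-varying permeability, preferential flow along intercellular
channels (real RCS profiles show peaks and anisotropic texture), scatter
and beam hardening, cone-beam magnification, and needle/device imaging
artifacts.

## Parameters that matter

| Parameter | Units | Default | Rationale |
|---|---|---|---|
| `epsilon` | — | 1.0 | Effective volume fraction in the depot; never measured independently, so the neutral upper bound is the default and it cancels from all normalized quantities. |
| `anisotropy` | — | 1.0 | Vertical/horizontal semi-axis ratio; 1 reproduces the near-spherical slow-injection depots. |
| `youngs_modulus` | kPa | 1.01 | Not directly measured; the value jointly consistent (least squares) with the two reference $(P, J)$ operating points at $h = 800\,\mu m$. |
| `crack_width` | µm | 800 | Assumed mean micro-crack width behind the $J$ relation. |
| `fracture_threshold` | J/m² | 4100 | Tissue fracture threshold $J_a$. |
| `lag_volume` | µL | 100 | Dead volume; reproduces the observed 60 s onset at 100 µL/min. |
| `mu_abs` | 1/mm | 1.0 | Linear absorption coefficient of the iodinated solution; plausible for a 25 % contrast-agent dilution at ~80 kVp. It scales absolute RCS path lengths only — fronts, ratios and fits are invariant to it. |
| `frac` (WF threshold) | — | 0.1 | Fraction of peak-above-floor; low enough to sit on the front's toe, high enough to clear residual noise after median smoothing. |
| `qs_rel_tol` / `qs_window` | — / s | 0.01 / 60 | "Stopped advancing" means <1 % relative change per minute. |
| detector defaults | counts | gain 30000, offset 1000, read σ 50, Poisson on | A bright, shot-noise-dominated 16-bit detector; transmission noise ≈0.6 % per pixel. |

## Numerical choices and degenerate inputs

Counts are rounded to integers by default (a physical ADC); the exact
$10^{-12}$ inversion identities are exercised with `quantize = FALSE`
because 16-bit quantization alone contributes ~$2\times10^{-5}$ relative
error. Division by a zero flat-field denominator, non-positive
transmissions and zero ROI means all become `NA` masks, never infinities.
Front detection distinguishes "no front" (`NA`) from "front at zero".
Traces shorter than 3 samples, regions with no usable samples, windows
larger than the frame, and truth manifests with missing fields raise
errors; near-degenerate cases (needle at the border, clipped ROIs,
skipped zero-denominator aspect samples, featureless registration
frames) warn and continue. All randomness flows from a single mandatory
scenario seed; identical config + seed reproduces stacks, and the
analysis itself is deterministic (a rerun writes byte-identical tables).

## Problem sizes in the test-suite

The recovery tests run on 160×160 px frames at a 50 µm pixel pitch with
tens-of-µL injections, so depots span 15–40 px and a full
simulate–correct–track round trip takes well under a second; the
generator's *defaults* remain at the reference acquisition scale (9 µm
pixels, 36.0 mm × 24.0 mm field, 500 µL). These sizes were chosen so the
whole suite exercises every stage many times over — pixel-resolution
tolerances (2 px) translate to 100 µm, stricter in absolute terms than
the same tolerance at 9 µm would be relative to the larger depots.

## Known limitations

* Parallel projection only; no cone-beam magnification, scatter or
  beam-hardening corrections.
* Front tracking reads two axial profiles; it does not segment the full
  2D front shape, so strongly lobed depots are summarised by two radii.
* The Darcy estimator inherits the point-source assumptions; at fast,
  fracture-regime injections it reports an *effective* permeability of
  the cracked tissue, not an intrinsic material property.
* Registration is integer-pixel and translation-only; rotations or
  deformations of the sample are not modelled.
* `mu_abs` must be supplied (or calibrated) for absolute RCS path
  lengths; defaults make relative quantities exact but absolute ones
  nominal.
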