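# depotr

Quantifying drug depot permeation in subcutaneous and muscle tissue from
time-lapse X-ray radiographs.

When a drug solution is infused into tissue, it forms a growing depot
around the needle tip. Time-lapse radiography of an iodinated solution
makes that depot visible: each pixel records the attenuated beam, so the
image carries the path-integrated amount of solution along the beam.
`depotr` turns such radiograph stacks into physical measurements — where
the wetting front is, how fast it moves in each direction, how the local
solution content evolves, and what tissue permeability is consistent with
the observed depot — for researchers working on injection-device design,
drug-delivery modelling and tissue transport characterisation.

## The models at the core

**Darcy point source.** Treating tissue as a homogeneous porous medium and
the needle tip as a point source of volumetric flow *q*, the seepage
velocity at radius *r* is *v(r) = q / (4πr²)*; combining with Darcy's law
*v = −k ∇p* and integrating outward from the depot radius *r_t* gives the
pressure at the depot surface *p_t = q / (4πk r_t)*, hence the
permeability estimator

> *k = q / (4π p r_t)*  [m⁴/(N·s)]

with the applied pressure taken from the empirical correlation
*p*[kPa] = 0.74·*q*[µL/s] + 23.

**Depot growth.** Under constant infusion with effective volume fraction
ε, volume balance for a spherical depot gives the cube-root law
*WF(t) = (3qt / 4πε)^{1/3}*, or normalized by the end-of-infusion radius
*WF_m*: *R(t) = (qt/Q)^{1/3}*. `fit_normalized_wf()` fits the single free
scale *WF_m* to a measured front trace and reports R².

**Injection criteria.** Tissue resistance pressure
*TRP*[kPa] = 10.4·*q*[mL/min] + 1.14 sets the back-pressure a device must
overcome; the fracture toughness of a pressurized micro-crack of width *h*
in tissue of modulus *E*, *J = P²h / (1.27E)*, compared against a
threshold *J_a*, separates gentle permeation from fracture-driven
spreading at high flow rates.

**Imaging chain.** Raw frames are flat-field corrected,
*FFC = (object − offset) / (gain − offset)*, and inverted through the
Beer–Lambert law *I = I₀ e^{−μx}* to per-pixel solution path length
(the relative content of solution, RCS). Wetting fronts are read off
median-smoothed line profiles at a 10 % relative threshold; drift is
compensated by cross-correlation registration.

A synthetic generator (`generate_stack()`) renders parallel-projection
radiographs of an ellipsoidal depot growing under exactly these laws —
with onset dead volume, anisotropy, detector fixed patterns, shot/read
noise and sample drift — and records full ground truth, so every pipeline
stage is validated by recovery tests.

## Worked example

```r
library(depotr)

# pressures and fracture criterion for a slow (25 uL/min) infusion
p <- injection_pressure(25, "uL/min")        # 23.31 kPa
tissue_resistance_pressure(0.025, "mL/min")  # 1.40 kPa
J <- fracture_toughness(P = p, h = 800, E = 1.01)
assess_fracture(J, J_a = 4100)
#> Fracture assessment: J = 339 J/m^2 vs J_a = 4.1e+03 J/m^2 -> no_fracture

# idealized end-of-infusion depot (500 uL) and the permeability it implies
r_t <- wf_spherical(25, 1200, epsilon = 1)   # 4.924e-3 m
permeability_darcy(25, r_t, p)               # 2.889e-13 m^4/(N s)
```

The slow injection sits an order of magnitude below the fracture
threshold (gentle permeation), and the permeability estimate lands in the
10⁻¹³ m⁴/(N·s) range typical of subcutaneous tissue at pump rates.

A full synthetic round trip — simulate, correct, track, estimate:

```r
pr  <- injection_protocol(100, 40, needle_tip = c(80, 80), frame_interval = 2)
ti  <- tissue_parameters(lag_volume = 10, anisotropy = 0.85, mu_abs = 1)
cfg <- scenario_config(pr, ti, detector_model(), dims = c(160, 160),
                       pixel_size = 50, frame_times = seq(0, 30, 2), seed = 1)
sim   <- generate_stack(cfg)
flat  <- flat_field_set(sim$flats$gain_frames, sim$flats$offset_frames)
trans <- image_stack(lapply(sim$stack$frames, flat_field_correct, flat = flat),
                     sim$stack$timestamps, pixel_size = 50)
trace <- track_wf(trans, pr, ti)
aspect_ratio(trace, "IR")
#> IR aspect ratio: 0.847 +- 0.015   (generator truth 0.85)
estimate_permeability(trace, pr)
#> Darcy point-source permeability estimate (tissue)
#>   flow rate : 100 uL/min, pressure 24.2 kPa
#>   k_horizontal : 2.737e-12 m^4/(N s)  (r_t = 2 mm)
#>   k_vertical   : 3.219e-12 m^4/(N s)  (r_t = 1.7 mm)
```

The tracked aspect ratio recovers the generator's anisotropy to ~0.003,
and the directional permeabilities reflect the elongated depot: the
shorter vertical radius implies a larger apparent vertical resistance.

Whole runs can also be driven from the shell via the bundled wrapper:

```sh
Rscript inst/cli/depotr.R simulate --config inst/extdata/scenarios/slow-25.yaml --out sim
Rscript inst/cli/depotr.R analyze  --input sim --out report
Rscript inst/cli/depotr.R recover  --input sim --out check
```

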