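---
title: "Quantitative radiacoustic dosimetry: models, operators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative radiacoustic dosimetry: models, operators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(radiacoustics)
```

## The problem

Radiotherapy deposits dose inside the patient, but no clinical instrument
measures that dose directly during delivery.  Radiacoustic imaging offers a
route: a pulsed radiation beam heats tissue by microkelvins within
microseconds, thermoelastic expansion launches a pressure wave, and an
ultrasound array records it.  Under thermal confinement the initial acoustic
pressure is proportional to absorbed dose,

$$p_0(\mathbf r) = \Gamma\,\eta_{th}\,D(\mathbf r)\,\rho,$$

with $\Gamma$ the Grüneisen parameter, $\eta_{th}$ the heat fraction, $\rho$
the density.  Dose in Gy (J/kg) times density gives an energy density in
J/m³ = Pa, so for water ($\Gamma = 0.11$, $\rho = 1000$) a Bragg-peak dose
of 1.72 cGy yields $p_0 \approx 1.9$ Pa — a very quiet signal, which is why
practical systems average pulses and why measurement noise is a first-class
feature of the data.

This package implements the full quantitative chain on synthetic beams:
dose generation → initial pressure → wave propagation → instrument response
(the digital twin) → limited-view time-reversal reconstruction → a
physics-informed enhancement network → single-point pressure-to-dose
calibration → dosimetric evaluation (gamma index, SSIM, PSNR).

## Synthetic beams

`protonPencilBeam()` builds a separable dose field: an analytic depth-dose
curve with a Bragg peak at the range $R = \alpha E^p$ (defaults
$\alpha = 0.0022$ cm·MeV$^{-p}$, $p = 1.77$, the standard water values),
times a lateral Gaussian (default $\sigma$ = 4 mm).  The curve is an
entrance plateau (25% of peak, rising gently) that is switched off two
distal-falloff widths before the peak — this keeps the argmax of the curve
on the power-law range, which the tests rely on — plus an asymmetric peak:
slow proximal rise ($\sigma_{prox} = 0.07R$, floored at 2 mm) and sharp
distal falloff ($\sigma_{dist}$ = 3 mm by default).  This is a parametric
surrogate for a Monte Carlo or treatment-planning dose engine: only the
location, width and contrast of the peak matter for exercising the
reconstruction chain, not nuclear-interaction detail.

`electronFlashBeam()` models a collimated FLASH electron field: lateral
top-hat with Gaussian penumbra (error-function edges), a depth build-up
from the surface dose fraction to a maximum at $0.6\,R_{50}$ and a sigmoid
falloff through 50% at $R_{50}$ (width $0.05\,R_{50}$).  The FLASH pulse
structure — 1 Gy in 1 µs per pulse — gives the $10^6$ Gy/s instantaneous
dose rate via `instantaneousDoseRate()`.

`watertankCatalog()` enumerates the tank protocol: 7 beam energies × 5
array positions (centre plus 1 cm left/right/up/down) = 35 recordings, 2
excluded (emulating interference-contaminated acquisitions), and a 20/5/8
train/validation/test split.  The energies are not fixed by the protocol;
the default sweep 50–74 MeV puts Bragg peaks 22–46 mm deep, matching the
desk-scale tank geometry below.  Catalogs are fully reproducible from their
seed.

## Wave propagation: two schemes, on purpose

The package carries two pseudospectral solvers and uses each where it is
strongest.

**Production path (`propagate()`, time reversal).**  A first-order coupled
pressure–velocity k-space scheme with a split-field perfectly matched layer
(PML): spectral derivatives on staggered grids with the k-space correction
$\operatorname{sinc}(c_{ref}|k|\Delta t/2)$, exponential integration of the
per-axis absorption (quartic profile, peak 2 nepers/voxel, 12 voxels by
default).  Measured against the closed-form spherical-source solution the
recorded signals agree to 0.04–1.3% relative $L_2$ for source radii of 2–6
voxels, and the boundary leaves < 1% of the peak after the last geometric
arrival.  Simple damped-sponge absorbers were rejected: at wavelengths
comparable to the layer thickness they reflect tens of percent.

**Differentiable path (the twin operator).**  Training the enhancement
network requires the exact gradient of a sinogram-domain loss, i.e. the
exact adjoint of the forward operator.  A split-field PML is not
self-adjoint, so the operator embedded in training uses a second-order-in-
time k-space-corrected scheme whose every elementary operator — spectral
Laplacian, diagonal damping — has a trivial transpose.  Its adjoint is a
mechanical reverse sweep, verified in the tests by dot-product identities
($\langle Fx, y\rangle = \langle x, F^\top y\rangle$ to machine precision)
and by finite differences.  Within the causal recording window the two
schemes agree; they differ only in how boundaries absorb.

Numerical contracts: time steps obey CFL (default 0.3; `propagate()` errors
with the maximum stable `dt` if violated), sensors are sampled by
multilinear interpolation, units are SI internally.  The solver propagates
heterogeneous sound-speed maps; density heterogeneity enters only the
dose-to-pressure conversion, not propagation (a documented simplification).
A closed-form oracle is exported: for any radial profile $f$ the exterior
pressure is $p(r,t) = (r - ct)\,f(|r - ct|)/(2r)$ — the hard sphere gives
the classical bipolar N-wave.  Because a discontinuous sphere is not
representable on a band-limited grid, solver validation uses a
sigmoid-edged ball (edge = 1 voxel) against its exact closed form; the
physics tested (timing, $1/r$ decay, waveform) is identical and the
comparison is free of rasterisation artifacts.

## The digital twin

Real detection chains differ from ideal point samplers in three ways, each
modelled as a linear stage and composed into the unified forward operator
`forwardOperator()` ($F$):

1. **Radiation pulse** (`applyPulse()`): the source is not instantaneous;
   recorded signals are convolved with the pulse temporal profile
   (delta/box/Gaussian/double-Gaussian, unit area so signal integrals are
   preserved).
2. **Finite aperture** (`finiteElementSignal()`): each 3 × 3 mm element is
   subdivided into nine 1 × 1 mm sub-elements; the element signal is the
   sum of the field at the sub-element centres.  On a 2D grid the aperture
   has one in-plane axis and three sub-elements.
3. **Impulse response** (`applyImpulseResponse()`): the element behaves as
   a damped harmonic oscillator,
   $IR(t) = e^{-\pi f_0 t/q}\sin(2\pi f_0 t)$, energy-normalised.  The
   centre frequency and bandwidth of the reference instrument are not
   public; the defaults $f_0 = 1$ MHz, $q = 2$ are explicit placeholders
   and a user-supplied sampled response is accepted.

All stages are linear and time-invariant, so their order commutes (tested)
and $F$ is linear in $p_0$ (tested).  `adjointOperator()` applies the exact
transpose.

## Time reversal

`reverseSinogram()` flips the time axis; `trReconstruct()` re-emits the
reversed signals from the sub-element locations through the medium (additive
sources by default; a Dirichlet mode exists for comparison) and returns the
field at the final reversed-time step.  The exact initial/boundary
conditions of ideal time reversal are unattainable with partial surface
data, which is why the practical source-injection form is the default.  With
a full ring the reconstruction correlates with the source at $r \ge 0.95$;
with the planar limited-view array it localises a Bragg peak to within 2
voxels but distorts amplitude and morphology and produces negative values —
exactly the artifacts the enhancement network exists to repair.  No
positivity clamp is applied inside TR so those artifacts reach the network.

## The enhancement network and its physics loss

A compact additive-skip convolutional encoder–decoder (U-Net family; 2D or
3D, `depth` resolution levels, `base_channels` features, 3^d kernels,
average-pool down, nearest-neighbour up) maps the normalised time-reversal
reconstruction to a prediction of the initial pressure.  Training minimises

$$L = \lambda_1\,\tfrac1n\sum|N(p_{rec}) - p_0|^2 +
      \lambda_2\,\tfrac1n\sum|F(N(p_{rec})) - S_m|^2 ,$$

the second term pushing the prediction through the embedded twin operator
and comparing with the measured sinogram.  No deep-learning framework is
used: forward and backward passes are hand-written on BLAS matrix products,
and the physics gradient is the exact discrete adjoint $F^\top$, so
gradients are exact (finite-difference checked in the tests).

Design choices that mattered in practice:

* **Leaky activations and an identity path.**  Hidden units are leaky ReLU,
  and a direct input→output connection initialised at 1 makes the network
  start near the identity map.  Without these the mostly-zero background of
  dose maps drives a saturating output head into a dead zone and training
  collapses to predicting zero.
* **Linear head, rectified inference.**  The `"nonneg"` contract (dose is
  non-negative) is enforced by rectifying at inference rather than by a
  saturating activation during training, for the same gradient-health
  reason.  `"linear"` skips the clamp (ablation).
* **Per-sample max normalisation.**  Each sample is scaled by
  $\max|p_{rec}|$; because every stage of the chain is linear, the same
  scalar serves input, target and sinogram, and `enhance()` re-applies it,
  so predictions stay on the input's physical scale and the whole chain is
  scale-equivariant (this is also why the calibration factor is invariant
  to global sinogram rescaling).
* **$\lambda_2$ auto-balance.**  The loss weights are tunable; by default
  $\lambda_1 = 1$ and $\lambda_2$ is set once, before the first update, to
  equalise the two terms at initialisation.
* **Optimiser.** Adam, learning rate $10^{-3}$, minibatch 4, everything
  seeded (init and batching), so runs are bit-reproducible.

## The benchmark study and what it does (and does not) show

`watertankSetup()` + `simulateWatertankStudy()` emulate the tank protocol
at desk scale: an 80 × 64 voxel water slab at 1 mm (the axial plane through
the beam), beams entering at one side, a 12-element linear array (3 mm
pitch, 3 sub-elements) observing from the opposite side, Gaussian 2 µs
pulse, 1 MHz damped-oscillator response, ~58 µs recording window at CFL 0.3
(about 290 samples).  Two conditions define the training regime, chosen to
match how such data exist in reality:

* **Measurement noise** at 14 dB SNR per sinogram.  Radiacoustic signals
  are faint (pascals); even after 10-pulse averaging real recordings are
  noisy, and badly contaminated ones are dropped (the catalog's exclusion
  mechanism).
* **Scarce ground truth.**  Dose ground truth is only characterised for the
  calibrated central beam position; off-centre acquisitions provide
  sinograms but no $p_0$ label.  The physics-informed network trains on all
  20 training samples (labels where they exist, sinogram self-supervision
  everywhere); the supervised baseline can only use the 4 labeled ones.
  This is the regime the method is designed for — with every sample
  perfectly labeled and noiseless, a plain supervised network has nothing
  to gain from a physics term and the comparison degenerates.

On five held-out samples the expected ordering emerges on both mean SSIM
and gamma pass rate: physics-informed > supervised baseline > time
reversal.  What this does *not* show: performance on real measured
sinograms (EMI, transducer miscalibration, tissue heterogeneity are absent
here), absolute metric values comparable to experimental reports, or 3D
performance at clinical grid sizes — the 2D slab is the test vehicle; all
operators support 3D.

## Calibration and evaluation

`calibrationFactor()` implements single-point calibration $K = D_c/p_c$:
the machine log gives the delivered dose at a reference location (1.72 cGy
per pulse at the tank Bragg peak; 1.88 cGy in the torso protocol), the
reconstruction gives $p_c$ there (argmax voxel by default, optional 3^d
neighbourhood mean), and $K\,p_{pred}$ is the absolute dose map.  The
end-to-end synthetic recovery test closes the loop: generate a beam of
known peak dose, push it through generation → detection → reconstruction →
enhancement → calibration, and recover the peak within 15% (measured ~5%).

The gamma index uses global normalisation to the maximum reference dose,
3 mm / 3% criteria and a 10% low-dose threshold by default.  The search is
an exact pruned exhaustive search on the native grid — offsets are visited
in order of increasing distance and stop when the distance term alone
exceeds every remaining voxel's current minimum — so it equals the
brute-force oracle exactly while staying fast.  SSIM is the global
(single-window) formula with $k_1 = 0.01$, $k_2 = 0.03$ and dynamic range
defaulting to the reference maximum; a sliding-window variant is available.
PSNR reads the printed size prefactor as $\sqrt{MN}$, i.e. the standard
$20\log_{10}(\max|G|/\mathrm{RMSE})$; a `"literal"` mode keeps the full
$MN$ factor for comparison.

## Reproducing the study

```{r, eval = FALSE}
library(radiacoustics)
setup   <- watertankSetup()
catalog <- watertankCatalog(7, 5, 2, split = c(20, 5, 8), seed = 1)
records <- simulateWatertankStudy(catalog, setup)
net     <- networkConfig(gridShape(setup$grid))
pinn    <- trainEnhancer(studyTrainingSet(records), net,
                         trainConfig(epochs = 30, seed = 11), setup$twin)
test1   <- studySplit(records, "test")[[1]]
p_pred  <- enhance(test1$p_rec, pinn$model)
ssimIndex(test1$p0, p_pred)
```

Problem sizes throughout (2D 80 × 64 study grid, 48³–64³ oracle grids,
30-epoch training) were chosen so the full suite and the acceptance script
run comfortably on a single CPU; every operator accepts larger grids and 3D
inputs unchanged.

## Known limitations

* Propagation ignores density gradients and shear; attenuation is an
  optional approximate homogeneous power-law model, off by default.
* Beams are axis-aligned; oblique incidence is out of scope.
* The transducer response is parametric (placeholder $f_0$, $q$); a
  measured impulse response can be supplied as samples.
* The enhancement network is deliberately compact; it demonstrates the
  training machinery and the physics-term mechanism, not state-of-the-art
  capacity.
* Containers are R-native serialized archives with named datasets and
  attributes; no HDF5 dependency is used.
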