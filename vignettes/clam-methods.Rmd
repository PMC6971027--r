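---
title: "Models and methods behind clamsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clamsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clamsim)
```

This vignette records the physical models, the parameter conventions, and
the deliberate design choices in `clamsim`. It is the companion to the test
suite: every claim here about behaviour is something a test computes.

## 1. The mirror-pair illumination model

A nearly parallel mirror pair (length $L$, separation $S$, relative
misalignment $\alpha$) decomposes an input light cone of full angle
$\Delta\theta$ into $N = \Delta\theta/\alpha$ zig-zag beamlets. Beamlet $k$
undergoes $2k$ reflections and is retroreflected, so it carries a path
delay $2kS$, a power fraction $R^{2k}$, and behaves as a low-NA virtual
source. The package reduces this to three per-source quantities — exit
angle, delay, power — plus a selection flag.

Choices worth recording:

* **Sheet count uses a floor.** $N = \lfloor\Delta\theta/\alpha\rfloor$,
  since only complete angular bins become beamlets. A $10^{-9}$ slack
  absorbs floating division landing a hair under an integer.
* **Exit angle of beamlet $k$ is $(k+\tfrac12)\alpha$** — the centre of the
  $k$-th angular bin. The per-beamlet angle only orders the sources; no
  downstream quantity depends on it.
* **Acceptance NA.** The closed form $\sqrt{L\alpha/2S}$ is validated
  against an honest 2D zig-zag ray trace (a test oracle, bisected to find
  the largest retroreflected entry angle). The trace shows the *full*
  acceptance cone is $\sqrt{2L\alpha/S}$; the design formula is its
  half-angle, and the two agree within 1–2% across
  $\alpha \in [0.2, 2]$ mrad, $S \in [20, 60]$ mm, $L \in [100, 300]$ mm
  (the tests assert 5%).
* **The relay is collapsed into one number.** Real systems image the
  virtual sources through several telescopes into sheets; the published
  systems report uniform sheet spacing and thickness, so the package maps
  re-indexed selected sources directly to depths $k' z_0$ with a single
  user-set spacing $z_0$. Nothing in the reconstruction depends on the
  relay's internals.
* **Mode selection.** By default the highest-order modes are kept
  (`keep_highest`), mirroring the practice of selecting the 30–40
  highest-order beamlets whose relative intensities are most uniform;
  `equalize_power = TRUE` then sets all sheet powers to 1.

### Coherence

Two conventions for coherence length are exposed because both are common:
rectangular spectrum, $L_c = \lambda^2/\Delta\lambda$; Gaussian spectrum of
FWHM $\Delta\lambda$, $L_c = \sqrt{2\ln 2/\pi}\,\lambda^2/\Delta\lambda$
(prefactor $\approx 0.664$). A 712 nm/5 nm source gives 0.10 mm under the
first; a 532 nm/44.5 pm line gives 4.23 mm under the second — the Gaussian
prefactor is required to reproduce the quoted millimetre-scale value for
narrow lines, which is why the `coherence_spec` lineshape is explicit.
Grouping is a connected-components pass over the sorted delays with
adjacency "gap $\le L_c$": with $2S \gg L_c$ every sheet is its own group
(the speckle-free regime); the all-singleton condition is exactly
$2S > L_c$.

## 2. The OFDM encoding plan

`make_plan(f_cam, f_vol, N, f_H)` sets $\Delta f = f_{vol}$, fills carriers
downward from $f_H$, and fixes the demodulation window $T = 1/f_{vol}$.
Carriers that are integer multiples of $1/T$ are *bin-aligned*: over one
window the discrete Gram matrix is the identity to machine precision.
Validation is separate from construction and never raises; it reports
violations of

* `nyquist`: $f_H < f_{cam}/2$;
* `harmonic`: $f_L > f_H/2$ (keeps the square wave's odd harmonics out of
  band — the cross-term between a square carrier and its third harmonic is
  exactly $-2/3$ under the package's $2/T$ inner-product normalisation,
  i.e. one third of the square's diagonal);
* `depth_sampling`: $\beta\Delta f \lesssim w_{LS}$. Reference systems run
  this rule right at its edge (1.77 μm pitch against 1.5 μm sheets), so by
  default a pitch up to $1.2\,w_{LS}$ is a warning and only beyond that a
  violation; `strict = TRUE` restores the hard inequality.

The inner product is normalised by $2/T$ so a unit cosine has unit norm;
channel phases default to zero (no published phase convention exists, and
magnitude demodulation discards them anyway). The square waveform exists to
model the sgn-pattern reticle faithfully; cosine is the default and the
reconstruction assumption.

## 3. The forward model

Axes are `(z, y, x)`: `z` the detection/sheet-stacking axis, `x` the
illumination propagation axis, all sample-space lengths in μm.

* **Excitation**: per sheet, a Gaussian axial profile of FWHM $w_{LS}$
  scaled by relative power; Beer–Lambert attenuation
  $e^{-(\mu_s'+\mu_a)x}$ when the phantom declares scattering (full
  radiative transfer is out of scope). Coherent mode multiplies each
  sheet's field by a fully developed speckle pattern — a low-pass-filtered
  circular complex Gaussian field, intensity normalised to mean 1 — shared
  within a coherence group. Filtering preserves circularity, so
  single-group contrast is 1 by construction and $M$ independent groups
  average to $1/\sqrt M$; the tests measure both.
* **Detection**: depth-dependent lateral blur
  $\mathrm{FWHM}(z) = \mathrm{FWHM}_0\sqrt{1+((z-z_f)/z_R)^2}$ with
  $z_R = \texttt{dof\_scale}\cdot\lambda/(\pi\,\mathrm{NA}^2)$ and the
  diffraction-limited default $\mathrm{FWHM}_0 = 0.51\lambda/\mathrm{NA}$
  (1.20 μm at NA 0.25, 590 nm). `dof_scale` is the phenomenological handle
  for the spherical-aberration extended depth of field produced by a
  high-index block: no aberration prescription is published, only the
  refractive index and thickness of the block, so the package models the
  *effect* (a flatter defocus curve at unchanged in-focus width). Under a
  quadratic fit near focus the measured DOF scales proportionally with
  `dof_scale`; reproducing a 31 → 41 μm (≈32%) extension therefore
  corresponds to `dof_scale ≈ 1.32`.
* **Camera**: Eq.-style multiplexing $\sum_k \tfrac12[1+m_k(t)]\,E_k(y,x)$.
  The factor $\tfrac12$ makes the physical transmission live in $[0,1]$
  (the reticle transmits between 0 and 1 with mean $\tfrac12$); any
  constant is absorbed into `photon_scale`. Exposure is integrated with a
  midpoint rule over 4 sub-steps (global shutter; rolling shutter is out of
  scope — the sub-step count only matters above ~kHz carriers and is
  configurable). Noise order is the standard sCMOS forward convention:
  Poisson on expected photons, additive Gaussian read noise, clip,
  quantise. `photon_scale = 0, read_noise_sigma = 0` is the documented
  noiseless mode that returns continuous intensities — the oracles depend
  on it.
* **Flow and photobleaching**: sub-voxel linear-interpolation advection
  along `x` (mass-conserving away from boundaries), and pointwise decay
  $F \leftarrow F e^{-k_b I^\gamma \Delta t}$. The exponent $\gamma$
  carries the entire multiplexed-vs-scanned story: at equal signal per
  volume, a scanned system concentrates the dose into $N$-fold intensity
  for $1/N$ the time, multiplying the bleaching rate by $N^{\gamma-1}$;
  $\gamma = 1$ makes the two schedules exactly equivalent.

## 4. Reconstruction

* **Matched filter, not bin picking.** The carriers are known from the
  plan, so each channel is demodulated by
  $(2/W)\,|\sum_t w(t)\,I(t)\,e^{-i2\pi f_k t}|$; for bin-aligned plans
  this *is* the DFT bin. The rectangular window is the default because it
  preserves the $\approx 1.21/T$ channel width that characterises the
  calibration spectra; Hann is available for jitter robustness.
* **Peak measurement** (for calibration) selects, per channel, the pixel
  with the strongest matched-filter response before evaluating a finely
  sampled spectrum around the nominal carrier — each depth plane dominates
  its own patch of a calibration image, and measuring there avoids the
  peak-pulling that a pixel-averaged signal suffers when many
  equal-amplitude carriers share one series. Centres are refined by
  parabolic interpolation; bandwidths are half-max crossings.
* **Calibration** is ordinary least squares of depth on frequency. The
  calibration driver renders the standard target — a thin fluorescent
  plane at 45° to both arms — over 3 demodulation windows (≈0.39 s at
  $\Delta f = 7.7$ Hz, which also reproduces the ~3 Hz channel width).
* **Assembly** stacks channel images by calibrated depth and applies a
  centred boxcar along the channel axis, shrink-to-valid at the edges.
  Width 3 is the default: the published pipeline states a boxcar but not a
  width, and 3 is the smallest width that suppresses the channel
  discreteness.
* **Richardson–Lucy** uses FFT (circular) convolution, 20 iterations by
  default (mid-range of the published 10–40), early stop when the relative
  update drops below $10^{-4}$. Non-negativity is intrinsic; flux is
  conserved within 1% for interior objects.
* **Magnitude demodulation** discards carrier phase deliberately; depth is
  encoded in frequency, not phase.

## 5. Phantoms and metrics

The generators emulate the test objects used to characterise such systems:
beads on a 45° plane (PSF and calibration targets), random 3D bead fields,
flow-channel beads, and a TiO₂-in-gel scattering phantom. They are
deterministic per seed. What they do **not** emulate: real fluorophore
spectra, depth-dependent speckle decorrelation, aberrations beyond the
quadratic defocus law, rolling-shutter artefacts, or tissue heterogeneity —
so green tests certify the computational chain, not biological image
quality.

* **Mie solver**: Bohren–Huffman series (downward logarithmic-derivative
  recurrence, upward Riccati–Bessel), returning $Q_{sca}$ and $g$;
  suspension bookkeeping converts mass concentration to number density.
  Defaults are anatase TiO₂ at 532 nm: particle index 2.55, density
  4.23 g/cm³, medium index 1.33, 160 nm diameter, 1.2 mg/mL — which yields
  $\mu_s' \approx 22$ cm⁻¹ and a transport mean free path of ≈450 μm
  (asserted in the acceptance tests; the Rayleigh limit anchors the series
  at small size parameter).
* **SNR convention**: $10\log_{10}[(\bar S - \bar B)/\sigma_B]$, stated
  explicitly because dB conventions vary; published absolute dB figures are
  therefore not comparison targets, only monotonic behaviour is.
* **DOF**: quadratic fit to FWHM($z$), DOF = width of the region within
  $\sqrt2$ of the fitted minimum, in closed form from the coefficients;
  non-positive curvature flags an unbounded DOF.

## 6. Numerical and I/O choices

* Gaussian blurs are separable banded-matrix convolutions with zero
  padding (linear, flux-preserving in the interior); kernels truncate at
  $4\sigma$.
* FWHM measurements interpolate half-max crossings linearly and return
  `NA` when a profile is cut by the grid; `measure_psf` skips beads at
  boundaries or closer than an isolation radius instead of reporting
  corrupted widths.
* Frame sequences are written as 16-bit multi-page TIFF, volumes as 32-bit
  multi-page TIFF, both with a JSON sidecar carrying scale, plan, depth
  axis, processing log and seeds — one self-describing, dependency-light
  container readable by any imaging tool.
* Configuration is YAML with unit-suffixed keys, unknown keys rejected.
  The channel-count key is `n_channels` (a bare `N` is a YAML 1.1 boolean
  literal and silently becomes `FALSE` in most parsers).

## 7. Problem sizes

The test suite and acceptance script run deliberately small scenes chosen
to exercise every code path at interactive speed: 24–40 channels, grids of
order $30^3$ voxels, one to three demodulation windows (245–1240 frames),
$\le 20$ Richardson–Lucy iterations. All stochastic assertions fix their
seeds and state their sampling tolerances inline.

## 8. Known limitations

Wave-optical propagation inside the mirror cavity, Gaussian-beam waist
evolution, polarisation, rolling-shutter readout, motor jitter side lobes
(beyond optional phase noise), radiative-transfer scattering, and any
denoising stage are all out of scope. The lateral positions of virtual
sources at the entrance plane are not modelled beyond the
angle/delay/power triple.
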