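# clamsim

Simulation and reconstruction toolkit for **coded light-sheet array
microscopy (CLAM)** — a fully parallelized volumetric fluorescence imaging
scheme in which a dense array of mutually incoherent light sheets
illuminates the sample simultaneously, each sheet is intensity-modulated
with its own orthogonal frequency carrier, and a single 2D camera records
the sum of all depth planes. A per-pixel short-time Fourier transform then
separates the planes again, so an entire 3D volume is captured in one
demodulation window with no mechanical scanning.

The package is aimed at optical-imaging researchers who want to explore the
design space of such a system (mirror geometry, carrier plans, camera
limits, noise regimes) and at image-analysis developers who need a faithful
forward model to exercise reconstruction code against.

## The model

**Illumination.** An angle-misaligned mirror pair ("infinity mirror") of
length *L*, separation *S* and misalignment *α* splits an input light cone
of angle *Δθ* into *N = Δθ/α* retroreflected beamlets. Beamlet *k* makes
2*k* reflections, so it returns with an extra path delay *D = 2kS* and a
power fraction *R*^(2k); the set behaves as an array of virtual sources
that relay optics project into a light-sheet array. The acceptance of the
pair is *NA ≈ √(Lα/2S)*. Because the delay increment 2*S* far exceeds the
source coherence length *L*c, the sheets superpose **incoherently** — a
smooth, speckle-free illumination volume even in scattering media.

**Encoding.** Sheet *k* is modulated with *m_k(t) = cos(ω_k t)* (a spinning
reticle with transmission `T(r,φ) = ½ + ½ sgn[cos(2πr·φ)]` realises a
square-wave version with a linear frequency chirp across the array). The
camera records

  I_cam(x, y, t) = Σ_k [1 + m_k(t)] · ∫ I_em,k(x, y, z − z₀k) dz,

and carriers spaced by Δf are orthogonal over a window T = 1/Δf, so the
volume rate is f_vol = Δf. The design rules are: *f_H < f_cam/2* (Nyquist),
*f_L > f_H/2* (keeps carrier harmonics out of band), and the channel depth
pitch *Δd = βΔf* at most about one sheet thickness.

**Reconstruction.** A matched filter at each known carrier (equivalently, a
bin-aligned STFT) demodulates every pixel; channel images are placed on the
depth axis through a linear frequency→depth calibration (slope *β* in
μm/Hz), smoothed axially with a boxcar, and deconvolved with
Richardson–Lucy.

## Worked example

```r
library(clamsim)

# mirror pair and source
geom <- mirror_pair(L_mm = 200, S_mm = 50, alpha_rad = 1e-3,
                    R = 0.998, dtheta_rad = 0.04)
num_sheets(geom$dtheta_rad, geom$alpha_rad)          # 40
as.numeric(effective_na(200, 50, 1e-3))              # 0.0447
coherence_length(coherence_spec(532, 44.5e-3, "gaussian")) / 1e3  # 4.22 mm

# fast-mode carrier plan: 24 channels at 13 vol/s on a 3183 fps camera
plan <- make_plan(f_cam = 3183, f_vol = 13, N = 24, f_H = 1399)
c(plan$f_L, plan$f_H)                                # 1100 1399
validate_plan(plan, w_ls_um = 1.5, beta_um_per_hz = 1.2 / 13)$violations
# character(0)

# synthetic acquisition: 1 um beads on a 45-degree plane
lsa <- light_sheet_array(virtual_sources(geom, keep_highest = 24),
                         z0_um = 1.2, w_ls_um = 1.5)
ph  <- make_bead_phantom(bead_field_spec(6, 1, "tilted_plane_45deg", seed = 2),
                         phantom_grid(c(26, 24, 32), c(1.2, 1, 1)))
det <- detection_model(na = 0.25, lambda_em_nm = 590, dof_scale = 12,
                       focal_plane_z_um = 13.8)
fs  <- render_frames(ph, lsa, plan, det, camera_model(3183),
                     duration_s = plan$window_T)     # 245 frames, one window

vol <- reconstruct(fs, plan)[[1]]
dim(vol$volume)                                      # 24 x 24 x 32
max(vol$depth_axis_um)                               # 27.6 um depth span

res <- measure_psf(vol, attr(ph, "centres_um"), voxel_um = c(1.2, 1, 1))
median(res$fwhm_x_um[res$ok])                        # 1.75 um
```

The numbers mean: the 200/50 mm pair at 1 mrad supports 40 sheets inside a
0.045 acceptance NA; the 24 carriers exactly fill the 1.1–1.4 kHz band and
pass all three design rules; one demodulation window (245 frames at
3183 fps ≈ 1/13 s) reconstructs a 24-plane volume spanning 27.6 μm; and the
measured lateral bead width (1.75 μm) is the 1.2 μm detection PSF broadened
by the 1 μm bead diameter and the default width-3 axial boxcar.

A command-line wrapper with `design-check`, `simulate`, `reconstruct`,
`calibrate`, `psf` and `bleach` subcommands is installed at
`system.file("cli", "clam.R", package = "clamsim")`; a reference YAML
configuration ships in `inst/extdata/default_config.yaml`.

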