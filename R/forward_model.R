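#' Fluorophore phantom
#'
#' A 3D fluorophore density on a regular grid. Arrays are ordered
#' `(z, y, x)`: `z` is the detection (sheet-stacking) axis and `x` the
#' illumination propagation axis.
#'
#' @param density non-negative 3D array `(z, y, x)` of fluorophore density
#'   (arbitrary units).
#' @param voxel_um voxel size, length-3 `(z, y, x)` in micrometres.
#' @param scattering optional list with `mu_s_prime_cm` (reduced scattering
#'   coefficient, 1/cm), `mu_a_cm` (absorption, 1/cm; default 0) and
#'   `g` (anisotropy, informational).
#' @param flow_velocity_um_s optional flow speed along `x` (um/s).
#' @return An object of class `phantom`.
#' @export
phantom <- function(density, voxel_um, scattering = NULL,
                    flow_velocity_um_s = NULL) {
  if (length(dim(density)) != 3) {
    clam_abort("shape", "density must be a 3D (z, y, x) array")
  }
  if (any(density < 0)) clam_abort("domain", "density must be non-negative")
  check_positive(voxel_um, "voxel_um", "invalid_spec")
  if (length(voxel_um) == 1) voxel_um <- rep(voxel_um, 3)
  stopifnot(length(voxel_um) == 3)
  if (!is.null(scattering)) {
    if (is.null(scattering$mu_a_cm)) scattering$mu_a_cm <- 0
    check_positive(scattering$mu_s_prime_cm, "mu_s_prime_cm", "invalid_spec")
  }
  structure(list(density = density, voxel_um = voxel_um,
                 scattering = scattering,
                 flow_velocity_um_s = flow_velocity_um_s),
            class = "phantom")
}

# grid coordinates (um) along each axis, first voxel centred at 0
phantom_axes <- function(ph) {
  d <- dim(ph$density)
  list(z = (seq_len(d[1]) - 1) * ph$voxel_um[1],
       y = (seq_len(d[2]) - 1) * ph$voxel_um[2],
       x = (seq_len(d[3]) - 1) * ph$voxel_um[3])
}

#' Detection-path model
#'
#' Wide-field detection orthogonal to the sheets. The lateral PSF FWHM grows
#' quadratically away from the focal plane,
#' `FWHM(z) = FWHM0 * sqrt(1 + ((z - z_f) / z_R)^2)`, with the Rayleigh-like
#' range `z_R = dof_scale * lambda / (pi * NA^2)`. `dof_scale >= 1` is a
#' phenomenological handle for the spherical-aberration extended depth of
#' field produced by a high-index block in the detection path: it flattens
#' the FWHM curve without changing the in-focus resolution.
#'
#' @param na detection numerical aperture, in (0, 1).
#' @param lambda_em_nm emission wavelength (nm).
#' @param lateral_fwhm0_um in-focus lateral FWHM (um); default is the
#'   diffraction-limited `0.51 * lambda / NA`.
#' @param axial_fwhm0_um detection axial FWHM (um), informational for PSF
#'   kernels; default `2 * lambda / NA^2`.
#' @param dof_scale depth-of-field stretch factor, `>= 1`.
#' @param focal_plane_z_um focal plane depth (um).
#' @return An object of class `detection_model`.
#' @export
detection_model <- function(na, lambda_em_nm = 590, lateral_fwhm0_um = NULL,
                            axial_fwhm0_um = NULL, dof_scale = 1,
                            focal_plane_z_um = 0) {
  if (na <= 0 || na >= 1) clam_abort("invalid_spec", "na must be in (0, 1)")
  check_positive(lambda_em_nm, "lambda_em_nm", "invalid_spec")
  if (dof_scale < 1) clam_abort("invalid_spec", "dof_scale must be >= 1")
  lam_um <- lambda_em_nm * 1e-3
  diff_limit <- 0.51 * lam_um / na
  if (is.null(lateral_fwhm0_um)) lateral_fwhm0_um <- diff_limit
  if (lateral_fwhm0_um < diff_limit - 1e-9) {
    clam_abort("invalid_spec",
               "lateral FWHM %.3f um below the diffraction limit %.3f um for NA %.2f",
               lateral_fwhm0_um, diff_limit, na)
  }
  if (is.null(axial_fwhm0_um)) axial_fwhm0_um <- 2 * lam_um / na^2
  structure(list(na = na, lambda_em_nm = lambda_em_nm,
                 lateral_fwhm0_um = lateral_fwhm0_um,
                 axial_fwhm0_um = axial_fwhm0_um,
                 dof_scale = dof_scale,
                 focal_plane_z_um = focal_plane_z_um,
                 z_r_um = dof_scale * lam_um / (pi * na^2)),
            class = "detection_model")
}

#' Lateral PSF FWHM at depth z
#'
#' @param detection a [detection_model()].
#' @param z_um depth (um).
#' @return Lateral FWHM (um) at each depth.
#' @export
lateral_fwhm_at <- function(detection, z_um) {
  dz <- z_um - detection$focal_plane_z_um
  detection$lateral_fwhm0_um * sqrt(1 + (dz / detection$z_r_um)^2)
}

#' Camera model
#'
#' Global-shutter photon-counting model: expected photons are the rendered
#' intensity times `photon_scale * exposure`, drawn Poisson, then Gaussian
#' read noise is added, and the result is clipped and quantised to
#' `bit_depth` bits. Setting both `photon_scale = 0` and
#' `read_noise_sigma = 0` selects the noiseless mode: frames are returned as
#' unscaled continuous intensities (used by the demodulation oracles).
#'
#' @param f_cam frame rate (frames/s).
#' @param exposure_s exposure per frame (s), at most `1 / f_cam`.
#' @param pixel_um pixel pitch (um), informational.
#' @param photon_scale photons per density unit per second.
#' @param read_noise_sigma read noise rms (electrons/counts).
#' @param bit_depth ADC bit depth.
#' @param rng_seed integer seed making the noise reproducible.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(f_cam, exposure_s = 1 / f_cam, pixel_um = 6.5,
                         photon_scale = 0, read_noise_sigma = 0,
                         bit_depth = 16, rng_seed = 1L) {
  check_positive(f_cam, "f_cam", "invalid_spec")
  if (exposure_s > 1 / f_cam + 1e-12) {
    clam_abort("invalid_spec", "exposure %g s exceeds the frame period %g s",
               exposure_s, 1 / f_cam)
  }
  if (photon_scale < 0 || read_noise_sigma < 0) {
    clam_abort("invalid_spec", "noise parameters must be >= 0")
  }
  structure(list(f_cam = f_cam, exposure_s = exposure_s, pixel_um = pixel_um,
                 photon_scale = photon_scale,
                 read_noise_sigma = read_noise_sigma,
                 bit_depth = as.integer(bit_depth),
                 rng_seed = as.integer(rng_seed)),
            class = "camera_model")
}

#' Per-sheet 3D excitation profiles
#'
#' Sheet `k` contributes a Gaussian axial profile centred at its depth with
#' FWHM equal to the sheet thickness, scaled by its relative power and, when
#' the phantom declares scattering, attenuated along the propagation axis
#' `x` by Beer-Lambert `exp(-(mu_s' + mu_a) * x)`. In `"coherent"` mode each
#' sheet's field is multiplied by a fully developed speckle pattern (complex
#' circular-Gaussian phasor field, low-pass filtered laterally, unit mean
#' intensity) shared within the sheet's coherence group; sheets in distinct
#' groups carry independent patterns, so their summed intensity averages the
#' speckle down by `1/sqrt(M)` for `M` groups.
#'
#' @param lsa a [light_sheet_array()].
#' @param ph a [phantom()] (defines the grid and scattering).
#' @param mode `"incoherent"` (default) or `"coherent"`.
#' @param seed integer seed for the speckle draws.
#' @param speckle_corr_vox speckle grain correlation half-width in voxels.
#' @return A list of non-negative 3D arrays, one per sheet.
#' @export
excitation_profiles <- function(lsa, ph, mode = c("incoherent", "coherent"),
                                seed = 1L, speckle_corr_vox = 1) {
  stopifnot(inherits(lsa, "light_sheet_array"), inherits(ph, "phantom"))
  mode <- match.arg(mode)
  ax <- phantom_axes(ph)
  d <- dim(ph$density)
  atten <- rep(1, d[3])
  if (!is.null(ph$scattering)) {
    mu_t_um <- (ph$scattering$mu_s_prime_cm + ph$scattering$mu_a_cm) * 1e-4
    atten <- exp(-mu_t_um * ax$x)
  } else if (mode == "coherent") {
    clam_warn("no_scattering",
              "coherent mode without a scattering spec: returning smooth profiles")
    mode <- "incoherent"
  }

  speckle <- NULL
  if (mode == "coherent") {
    groups <- unique(lsa$coherence_group)
    speckle <- withr::with_seed(seed, {
      out <- lapply(groups, function(g) speckle_intensity(d, speckle_corr_vox))
      names(out) <- as.character(groups)
      out
    })
  }

  lapply(seq_len(nrow(lsa)), function(k) {
    zprof <- lsa$relative_power[k] *
      gaussian_profile(ax$z, lsa$depth_z_um[k], lsa$thickness_w_ls_um[k])
    exc <- outer(zprof, rep(1, d[2])) %o% rep(1, d[3])
    exc <- sweep(exc, 3, atten, `*`)
    if (!is.null(speckle)) {
      exc <- exc * speckle[[as.character(lsa$coherence_group[k])]]
    }
    exc
  })
}

# Fully developed speckle intensity: |filtered CN(0,1)|^2, mean 1.
# Low-pass filtering a circular complex Gaussian field keeps it circular
# Gaussian, so the intensity stays exponential (contrast 1) at any grain.
speckle_intensity <- function(d, corr_vox) {
  re <- array(rnorm(prod(d)), d)
  im <- array(rnorm(prod(d)), d)
  if (corr_vox > 0) {
    for (i in seq_len(d[1])) {
      re[i, , ] <- blur_gaussian_2d(matrix(re[i, , ], d[2], d[3]), corr_vox, corr_vox)
      im[i, , ] <- blur_gaussian_2d(matrix(im[i, , ], d[2], d[3]), corr_vox, corr_vox)
    }
  }
  inten <- re^2 + im^2
  inten / mean(inten)
}

#' Camera-plane image of one excited sheet
#'
#' Multiplies the phantom density by one sheet's 3D excitation, blurs each
#' depth slice with the depth-dependent lateral detection PSF, and
#' integrates along `z` to form the 2D `(y, x)` emission image that the
#' camera would see from that sheet alone.
#'
#' @param ph a [phantom()].
#' @param excitation_k 3D excitation array for the sheet.
#' @param detection a [detection_model()].
#' @return A non-negative 2D `(y, x)` matrix.
#' @export
emission_image <- function(ph, excitation_k, detection) {
  stopifnot(inherits(ph, "phantom"), inherits(detection, "detection_model"))
  if (!all(dim(excitation_k) == dim(ph$density))) {
    clam_abort("shape", "excitation grid %s does not match phantom grid %s",
               paste(dim(excitation_k), collapse = "x"),
               paste(dim(ph$density), collapse = "x"))
  }
  ax <- phantom_axes(ph)
  d <- dim(ph$density)
  img <- matrix(0, d[2], d[3])
  for (iz in seq_len(d[1])) {
    sl <- ph$density[iz, , , drop = TRUE] * excitation_k[iz, , , drop = TRUE]
    if (d[2] == 1 || d[3] == 1) sl <- matrix(sl, d[2], d[3])
    if (any(sl > 0)) {
      s_um <- lateral_fwhm_at(detection, ax$z[iz]) / FWHM_SIGMA
      img <- img + blur_gaussian_2d(sl, s_um / ph$voxel_um[2],
                                    s_um / ph$voxel_um[3])
    }
  }
  img
}

#' Render the multiplexed camera frame sequence
#'
#' Implements the multiplexed camera signal: every frame is the sum over
#' sheets of the sheet's emission image weighted by its transmitted carrier
#' `(1 + m_k(t)) / 2`, integrated over the exposure with midpoint
#' sub-stepping, then passed through the camera noise chain (Poisson shot
#' noise, Gaussian read noise, clip and quantise). With the camera in
#' noiseless mode the continuous intensities are returned untouched.
#'
#' @param ph a [phantom()].
#' @param lsa a [light_sheet_array()] (one sheet per plan channel).
#' @param plan an [make_plan()]; `plan$N` must equal `nrow(lsa)`.
#' @param detection a [detection_model()].
#' @param camera a [camera_model()].
#' @param duration_s total duration (s); at least one window `plan$window_T`.
#' @param n_sub exposure sub-steps (midpoint rule).
#' @param mode excitation mode, see [excitation_profiles()].
#' @return An object of class `frame_sequence`: list with `frames`
#'   (`(t, y, x)` array), `frame_rate`, `duration_s`, `metadata`.
#' @export
render_frames <- function(ph, lsa, plan, detection, camera, duration_s,
                          n_sub = 4, mode = "incoherent") {
  stopifnot(inherits(plan, "encoding_plan"), inherits(camera, "camera_model"))
  if (nrow(lsa) != plan$N) {
    clam_abort("shape", "plan has %d channels but the array has %d sheets",
               plan$N, nrow(lsa))
  }
  if (duration_s < plan$window_T - 1e-12) {
    clam_abort("invalid_spec",
               "duration %g s shorter than one demodulation window %g s",
               duration_s, plan$window_T)
  }
  exc <- excitation_profiles(lsa, ph, mode = mode, seed = camera$rng_seed)
  d <- dim(ph$density)
  E <- vapply(exc, function(e) as.vector(emission_image(ph, e, detection)),
              numeric(d[2] * d[3]))          # (pixels x sheets)

  n_frames <- round(duration_s * camera$f_cam)
  t0 <- (0:(n_frames - 1)) / camera$f_cam
  sub <- (seq_len(n_sub) - 0.5) / n_sub * camera$exposure_s
  W <- matrix(0, n_frames, plan$N)
  for (j in seq_len(n_sub)) {
    tj <- t0 + sub[j]
    for (k in seq_len(plan$N)) {
      W[, k] <- W[, k] + 0.5 * (1 + modulation_waveform(plan, k, tj)) / n_sub
    }
  }
  raw <- W %*% t(E)                          # (frames x pixels)

  noiseless <- camera$photon_scale == 0 && camera$read_noise_sigma == 0
  if (!noiseless) {
    lam <- raw * camera$photon_scale * camera$exposure_s
    counts <- withr::with_seed(camera$rng_seed, {
      n <- rpois(length(lam), lambda = as.vector(lam))
      n + rnorm(length(lam), sd = camera$read_noise_sigma)
    })
    top <- 2^camera$bit_depth - 1
    raw <- matrix(pmin(pmax(round(counts), 0), top), nrow(raw), ncol(raw))
  }

  frames <- array(raw, c(n_frames, d[2], d[3]))
  structure(
    list(frames = frames, frame_rate = camera$f_cam,
         duration_s = n_frames / camera$f_cam,
         metadata = list(plan = plan, lsa = lsa, camera = camera,
                         detection = detection, noiseless = noiseless,
                         seed = camera$rng_seed)),
    class = "frame_sequence"
  )
}

#' Advect a flowing phantom
#'
#' Translates the density along `x` by `flow_velocity * dt` with linear
#' interpolation at sub-voxel shifts; content leaving the grid is lost and
#' zeros flow in at the upstream face (mass is conserved away from the
#' boundaries).
#'
#' @param ph a [phantom()] with `flow_velocity_um_s` set.
#' @param dt_s time step (s).
#' @return The advected [phantom()].
#' @export
flow_update <- function(ph, dt_s) {
  stopifnot(inherits(ph, "phantom"))
  if (is.null(ph$flow_velocity_um_s)) {
    clam_abort("invalid_spec", "phantom has no flow_velocity_um_s")
  }
  shift_vox <- ph$flow_velocity_um_s * dt_s / ph$voxel_um[3]
  d <- dim(ph$density)
  s0 <- floor(shift_vox)
  frac <- shift_vox - s0
  src <- seq_len(d[3])
  take <- function(offset) {
    idx <- src - offset
    ok <- idx >= 1 & idx <= d[3]
    out <- array(0, d)
    out[, , ok] <- ph$density[, , idx[ok], drop = FALSE]
    out
  }
  new_density <- (1 - frac) * take(s0) + frac * take(s0 + 1)
  ph$density <- new_density
  ph
}

#' One photobleaching step
#'
#' Pointwise first-order decay `F <- F * exp(-k_b * I^gamma * dt)`. With
#' `gamma = 1` bleaching depends only on the delivered dose `I * t`, so
#' redistributing a fixed dose over time changes nothing; with `gamma > 1`
#' concentrating the dose into `N`-fold higher intensity for `1/N` of the
#' time multiplies the bleaching rate by `N^(gamma - 1)` - the mechanism by
#' which parallelised illumination photobleaches less.
#'
#' @param fluor non-negative 3D fluorophore field.
#' @param excitation non-negative 3D excitation intensity.
#' @param k_b bleaching rate constant (per (intensity^gamma) per s).
#' @param gamma intensity exponent, `>= 1`.
#' @param dt_s step duration (s).
#' @return Updated fluorophore field.
#' @export
photobleach_step <- function(fluor, excitation, k_b, gamma = 1, dt_s) {
  if (k_b < 0 || gamma < 1 || dt_s < 0 || any(fluor < 0) || any(excitation < 0)) {
    clam_abort("domain",
               "photobleach_step requires k_b >= 0, gamma >= 1, dt >= 0 and non-negative fields")
  }
  fluor * exp(-k_b * excitation^gamma * dt_s)
}
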