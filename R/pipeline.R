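# High-level drivers composing the modules from a run configuration. These
# back the command-line interface but are ordinary exported functions.

#' Build optics, plan, phantom, detection and camera from a configuration
#'
#' @param cfg a `clam_config`.
#' @return A list with `geom`, `vsa`, `lsa`, `plan`, `ph`, `detection`,
#'   `camera`, `L_c_um`.
#' @export
build_scene <- function(cfg) {
  stopifnot(inherits(cfg, "clam_config"))
  geom <- mirror_pair(cfg$mirror$L_mm, cfg$mirror$S_mm, cfg$mirror$alpha_rad,
                      cfg$mirror$R, cfg$mirror$dtheta_rad)
  vsa <- virtual_sources(geom, keep_highest = cfg$sheets$n_keep)
  cs <- coherence_spec(cfg$source$lambda_nm, cfg$source$dlambda_nm,
                       cfg$source$lineshape)
  L_c_um <- coherence_length(cs)
  lsa <- light_sheet_array(vsa, cfg$sheets$z0_um, cfg$sheets$w_ls_um,
                           cfg$sheets$height_um, cfg$sheets$confocal_b_um,
                           equalize_power = cfg$sheets$equalize_power,
                           L_c_um = L_c_um)
  plan <- make_plan(cfg$plan$f_cam, cfg$plan$f_vol, cfg$plan$n_channels, cfg$plan$f_H,
                    cfg$plan$waveform)
  ph <- build_phantom(cfg)
  focal <- cfg$detection$focal_plane_z_um
  if (is.null(focal)) focal <- stats::median(lsa$depth_z_um)
  detection <- detection_model(cfg$detection$na, cfg$detection$lambda_em_nm,
                               dof_scale = cfg$detection$dof_scale,
                               focal_plane_z_um = focal)
  exposure <- cfg$camera$exposure_s
  if (is.null(exposure)) exposure <- 1 / cfg$plan$f_cam
  camera <- camera_model(cfg$plan$f_cam, exposure, cfg$camera$pixel_um,
                         cfg$camera$photon_scale, cfg$camera$read_noise_sigma,
                         cfg$camera$bit_depth, cfg$rng_seed)
  list(geom = geom, vsa = vsa, lsa = lsa, plan = plan, ph = ph,
       detection = detection, camera = camera, L_c_um = L_c_um)
}

#' @rdname build_scene
#' @export
build_phantom <- function(cfg) {
  pc <- cfg$phantom
  scat <- NULL
  if (!is.null(pc$mu_s_prime_cm)) {
    scat <- list(mu_s_prime_cm = pc$mu_s_prime_cm, mu_a_cm = pc$mu_a_cm)
  }
  grid <- phantom_grid(pc$grid_dim, pc$voxel_um)
  if (identical(pc$kind, "uniform")) {
    return(phantom(array(pc$brightness, grid$dim), grid$voxel_um,
                   scattering = scat,
                   flow_velocity_um_s = pc$flow_velocity_um_s))
  }
  spec <- bead_field_spec(pc$n_beads, pc$bead_diameter_um, pc$placement,
                          pc$tilt_deg, pc$brightness, cfg$rng_seed)
  make_bead_phantom(spec, grid, scattering = scat,
                    flow_velocity_um_s = pc$flow_velocity_um_s)
}

#' Design-rule report for a configuration
#'
#' Computes the mirror-pair design quantities (sheet count, effective NA,
#' coherence length, path-delay separation, coherence grouping) and runs
#' the encoding-plan validators.
#'
#' @param cfg a `clam_config`.
#' @return A list report; `$plan_report$violations` is empty for a valid
#'   design.
#' @export
clam_design_check <- function(cfg) {
  sc <- build_scene(cfg)
  beta <- sc$lsa$depth_z_um[2] - sc$lsa$depth_z_um[1]
  beta <- if (is.na(beta)) NULL else beta / sc$plan$delta_f
  list(
    n_sheets_supported = num_sheets(cfg$mirror$dtheta_rad, cfg$mirror$alpha_rad),
    n_sheets_used = nrow(sc$lsa),
    effective_na = as.numeric(effective_na(cfg$mirror$L_mm, cfg$mirror$S_mm,
                                           cfg$mirror$alpha_rad)),
    coherence_length_um = sc$L_c_um,
    source_separation_mm = 2 * cfg$mirror$S_mm,
    all_sheets_incoherent = all(table(sc$lsa$coherence_group) == 1),
    channel_capacity = channel_capacity(sc$plan$f_H, sc$plan$f_vol),
    plan_report = validate_plan(sc$plan, w_ls_um = cfg$sheets$w_ls_um,
                                beta_um_per_hz = beta)
  )
}

#' Simulate a multiplexed acquisition from a configuration
#'
#' @param cfg a `clam_config`.
#' @param out optional TIFF path; when given, frames (and the resolved
#'   config echo) are written next to it.
#' @param duration_s acquisition length; default one demodulation window.
#' @return The `frame_sequence`, invisibly when written to disk.
#' @export
clam_simulate <- function(cfg, out = NULL, duration_s = NULL) {
  sc <- build_scene(cfg)
  if (is.null(duration_s)) duration_s <- sc$plan$window_T
  fs <- render_frames(sc$ph, sc$lsa, sc$plan, sc$detection, sc$camera,
                      duration_s)
  if (!is.null(out)) {
    write_frames(fs, out)
    save_config(cfg, paste0(out, ".config.yaml"))
    return(invisible(fs))
  }
  fs
}

#' Reconstruct volumes from simulated or stored frames
#'
#' @param x a `frame_sequence` or a TIFF path written by [write_frames()].
#' @param cfg a `clam_config` (reconstruction settings; optional for a
#'   sequence that carries its own plan).
#' @param out optional TIFF path for the first reconstructed volume.
#' @return List of `recon_volume`.
#' @export
clam_reconstruct <- function(x, cfg = default_config(), out = NULL) {
  fs <- if (is.character(x)) read_frames(x) else x
  plan <- fs$metadata$plan
  if (is.null(plan)) clam_abort("io", "frame sequence carries no encoding plan")
  psf <- NULL
  if (isTRUE(cfg$recon$deconvolve)) {
    sc_det <- detection_model(cfg$detection$na, cfg$detection$lambda_em_nm,
                              dof_scale = cfg$detection$dof_scale)
    psf <- psf_kernel(sc_det, cfg$phantom$voxel_um)
  }
  vols <- reconstruct(fs, plan, psf = psf,
                      config = list(boxcar_width = cfg$recon$boxcar_width,
                                    rl_iterations = cfg$recon$rl_iterations,
                                    window = cfg$recon$window))
  if (!is.null(out)) write_volume(vols[[1]], out, config = unclass(cfg))
  vols
}

#' Gaussian PSF kernel for deconvolution
#'
#' Separable Gaussian kernel matching the detection model's in-focus
#' lateral FWHM and axial FWHM, sampled on the reconstruction grid and
#' normalised to unit sum.
#'
#' @param detection a [detection_model()].
#' @param voxel_um voxel size `(z, y, x)` (um).
#' @param half_extent_fwhm kernel half-size in units of the FWHM.
#' @return A 3D array with odd dimensions summing to 1.
#' @export
psf_kernel <- function(detection, voxel_um, half_extent_fwhm = 1.5) {
  if (length(voxel_um) == 1) voxel_um <- rep(voxel_um, 3)
  fw <- c(detection$axial_fwhm0_um, detection$lateral_fwhm0_um,
          detection$lateral_fwhm0_um)
  k1 <- lapply(1:3, function(i) {
    r <- max(1L, ceiling(half_extent_fwhm * fw[i] / voxel_um[i]))
    g <- gaussian_profile((-r:r) * voxel_um[i], 0, fw[i])
    g / sum(g)
  })
  k <- k1[[1]] %o% k1[[2]] %o% k1[[3]]
  k / sum(k)
}

#' Run a frequency-to-depth calibration acquisition
#'
#' Renders a calibration acquisition over several demodulation windows: a
#' thin fluorescent plane tilted at 45 degrees to both arms (the standard
#' calibration target), so each sheet / frequency channel lights up its own
#' lateral patch of the image. Each channel's spectral centre frequency is
#' then measured per pixel and the frequency-to-depth line is fitted
#' against the configured sheet depths.
#'
#' @param cfg a `clam_config`.
#' @return A list with the [calibrate_depth()] `fit`, the per-channel
#'   `peaks` table, and the configured `beta_um_per_hz`.
#' @export
clam_calibrate <- function(cfg) {
  sc <- build_scene(cfg)
  cam <- camera_model(sc$plan$f_cam, 1 / sc$plan$f_cam, cfg$camera$pixel_um,
                      cfg$calibration$photon_scale,
                      cfg$calibration$read_noise_sigma,
                      cfg$camera$bit_depth, cfg$rng_seed)
  vox <- cfg$phantom$voxel_um
  zmax <- max(sc$lsa$depth_z_um)
  nz <- ceiling(zmax / vox[1]) + 4
  nx <- ceiling(zmax / vox[3]) + 4
  ny <- cfg$phantom$grid_dim[2]
  zc <- (0:(nz - 1)) * vox[1]
  xc <- (0:(nx - 1)) * vox[3]
  # thin 45-degree plane: z = x (+ one-voxel Gaussian thickness)
  sheet <- outer(zc, xc, function(z, x) gaussian_profile(z - x, 0, vox[1]))
  den <- aperm(array(sheet, c(nz, nx, ny)), c(1, 3, 2))
  target <- phantom(den, vox)
  fs <- render_frames(target, sc$lsa, sc$plan, sc$detection, cam,
                      duration_s = cfg$calibration$duration_windows *
                        sc$plan$window_T)
  peaks <- peak_frequencies(fs, sc$plan)
  ok <- !peaks$missing
  fit <- calibrate_depth(peaks$f_centre_hz[ok], sc$lsa$depth_z_um[ok])
  list(fit = fit, peaks = peaks,
       beta_um_per_hz = attr(sc$lsa, "z0_um") / sc$plan$delta_f)
}
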