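#' Default run configuration
#'
#' Nested sections mirror the pipeline modules. All physical quantities
#' carry their unit in the key name. The defaults describe the reference
#' configuration: a 200 mm / 50 mm mirror pair at 1 mrad misalignment, a
#' 532 nm narrow-line source, 24 carriers in the 1.1-1.4 kHz band at a
#' 3183 fps camera, and a small bead phantom.
#'
#' @return A nested list of class `clam_config`.
#' @export
default_config <- function() {
  structure(list(
    mirror = list(L_mm = 200, S_mm = 50, alpha_rad = 1e-3, R = 0.998,
                  dtheta_rad = 0.04),
    source = list(lambda_nm = 532, dlambda_nm = 44.5e-3,
                  lineshape = "gaussian"),
    sheets = list(n_keep = 24, z0_um = 1.2, w_ls_um = 1.5, height_um = 50,
                  confocal_b_um = 50, equalize_power = TRUE),
    plan = list(n_channels = 24, f_cam = 3183, f_vol = 13, f_H = 1399,
                waveform = "cosine"),
    detection = list(na = 0.25, lambda_em_nm = 590, dof_scale = 1,
                     focal_plane_z_um = NULL),
    camera = list(exposure_s = NULL, pixel_um = 6.5, photon_scale = 0,
                  read_noise_sigma = 0, bit_depth = 16),
    phantom = list(kind = "beads", n_beads = 8, bead_diameter_um = 1,
                   placement = "tilted_plane_45deg", tilt_deg = 45,
                   brightness = 1, grid_dim = c(32, 24, 32),
                   voxel_um = c(0.9, 1, 1), mu_s_prime_cm = NULL,
                   mu_a_cm = 0, flow_velocity_um_s = NULL),
    recon = list(boxcar_width = 3, rl_iterations = 20, window = "rect",
                 deconvolve = FALSE),
    calibration = list(duration_windows = 3, read_noise_sigma = 0.5,
                       photon_scale = 200),
    bleach = list(n_volumes = 12, t_vol_s = 0.077, intensity = 1,
                  gamma = 1.4, k_b = 0.5),
    output = list(dir = "."),
    rng_seed = 1L,
    log_level = "info"
  ), class = "clam_config")
}

check_config_keys <- function(cfg, ref, path = "") {
  for (key in names(cfg)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(ref)) {
      clam_abort("config_schema", "unknown configuration key `%s`", full)
    }
    if (is.list(ref[[key]]) && !is.null(names(ref[[key]])) &&
        !is.null(cfg[[key]])) {
      if (!is.list(cfg[[key]])) {
        clam_abort("config_schema", "`%s` must be a section (mapping)", full)
      }
      check_config_keys(cfg[[key]], ref[[key]], full)
    }
  }
  invisible(TRUE)
}

#' Load a run configuration from YAML (or JSON)
#'
#' Unknown keys are rejected (fail-fast against typos); known keys override
#' the defaults of [default_config()].
#'
#' @param path YAML or JSON file.
#' @return A validated `clam_config` with defaults filled in.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) clam_abort("io", "config file not found: %s", path)
  user <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(user)) user <- list()
  ref <- default_config()
  check_config_keys(user, ref)
  cfg <- utils::modifyList(ref, user, keep.null = TRUE)
  class(cfg) <- "clam_config"
  cfg
}

#' Write a configuration to YAML
#'
#' @param cfg a `clam_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
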