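#' Bead-field phantom specification
#'
#' @param n_beads number of beads.
#' @param bead_diameter_um bead FWHM (um); beads are rendered as Gaussian
#'   blobs of this FWHM.
#' @param placement `"tilted_plane_45deg"` (all centres on the plane
#'   `z = tan(tilt) * x + c`, the classic tilted-coverslip PSF target),
#'   `"random_3d"`, or `"flow_channel"` (random in a central channel along
#'   `x`).
#' @param tilt_deg plane tilt (degrees), default 45.
#' @param brightness peak density per bead.
#' @param seed integer seed; generation is bit-reproducible per seed.
#' @param min_sep_um minimum centre separation (um).
#' @return An object of class `bead_field_spec`.
#' @export
bead_field_spec <- function(n_beads, bead_diameter_um,
                            placement = c("tilted_plane_45deg", "random_3d",
                                          "flow_channel"),
                            tilt_deg = 45, brightness = 1, seed = 1L,
                            min_sep_um = 2) {
  placement <- match.arg(placement)
  if (n_beads < 0) clam_abort("invalid_spec", "n_beads must be >= 0")
  if (n_beads > 0) check_positive(bead_diameter_um, "bead_diameter_um", "invalid_spec")
  structure(list(n_beads = as.integer(n_beads),
                 bead_diameter_um = bead_diameter_um, placement = placement,
                 tilt_deg = tilt_deg, brightness = brightness,
                 seed = as.integer(seed), min_sep_um = min_sep_um),
            class = "bead_field_spec")
}

#' Simulation grid
#'
#' @param dim grid size `(z, y, x)` in voxels.
#' @param voxel_um voxel size `(z, y, x)` in um (scalar recycled).
#' @return A list with `dim` and `voxel_um`.
#' @export
phantom_grid <- function(dim, voxel_um) {
  check_positive(dim, "dim", "invalid_spec")
  check_positive(voxel_um, "voxel_um", "invalid_spec")
  if (length(voxel_um) == 1) voxel_um <- rep(voxel_um, 3)
  list(dim = as.integer(dim), voxel_um = voxel_um)
}

#' Generate a bead phantom
#'
#' Places `n_beads` Gaussian blobs on the grid according to the placement
#' rule, enforcing the minimum centre separation by rejection sampling
#' (bounded retries, then a placement error). The bead centres are attached
#' as attribute `centres_um` (data frame with `z_um`, `y_um`, `x_um`).
#'
#' @param spec a [bead_field_spec()].
#' @param grid a [phantom_grid()].
#' @param scattering,flow_velocity_um_s passed through to [phantom()].
#' @return A [phantom()].
#' @export
make_bead_phantom <- function(spec, grid, scattering = NULL,
                              flow_velocity_um_s = NULL) {
  stopifnot(inherits(spec, "bead_field_spec"))
  d <- grid$dim
  vox <- grid$voxel_um
  ext <- (d - 1) * vox  # physical extents (z, y, x)
  centres <- withr::with_seed(spec$seed, place_beads(spec, ext))
  den <- array(0, d)
  if (spec$n_beads > 0) {
    s <- spec$bead_diameter_um / FWHM_SIGMA
    axz <- (seq_len(d[1]) - 1) * vox[1]
    axy <- (seq_len(d[2]) - 1) * vox[2]
    axx <- (seq_len(d[3]) - 1) * vox[3]
    for (b in seq_len(nrow(centres))) {
      gz <- gaussian_profile(axz, centres$z_um[b], spec$bead_diameter_um)
      gy <- gaussian_profile(axy, centres$y_um[b], spec$bead_diameter_um)
      gx <- gaussian_profile(axx, centres$x_um[b], spec$bead_diameter_um)
      den <- den + spec$brightness * (gz %o% gy %o% gx)
    }
    rm(s)
  }
  ph <- phantom(den, vox, scattering = scattering,
                flow_velocity_um_s = flow_velocity_um_s)
  attr(ph, "centres_um") <- centres
  ph
}

place_beads <- function(spec, ext, max_tries = 2000) {
  n <- spec$n_beads
  centres <- matrix(NA_real_, 0, 3)
  if (n == 0) {
    return(data.frame(z_um = numeric(0), y_um = numeric(0), x_um = numeric(0)))
  }
  margin <- spec$bead_diameter_um
  lo <- rep(margin, 3)
  hi <- ext - margin
  if (any(hi <= lo)) clam_abort("placement", "grid too small for the bead size")
  tries <- 0
  while (nrow(centres) < n) {
    tries <- tries + 1
    if (tries > max_tries) {
      clam_abort("placement",
                 "could not place %d beads with %g um separation in %d tries",
                 n, spec$min_sep_um, max_tries)
    }
    x <- runif(1, lo[3], hi[3])
    y <- runif(1, lo[2], hi[2])
    z <- switch(spec$placement,
      tilted_plane_45deg = {
        # plane through the volume centre: z - z_mid = tan(tilt) (x - x_mid)
        ext[1] / 2 + tan(spec$tilt_deg * pi / 180) * (x - ext[3] / 2)
      },
      random_3d = runif(1, lo[1], hi[1]),
      flow_channel = runif(1, lo[1], hi[1])
    )
    if (spec$placement == "flow_channel") {
      y <- runif(1, ext[2] * 0.35, ext[2] * 0.65)
    }
    if (z < lo[1] || z > hi[1]) next
    if (nrow(centres) > 0) {
      dist2 <- (centres[, 1] - z)^2 + (centres[, 2] - y)^2 + (centres[, 3] - x)^2
      if (min(dist2) < spec$min_sep_um^2) next
    }
    centres <- rbind(centres, c(z, y, x))
  }
  data.frame(z_um = centres[, 1], y_um = centres[, 2], x_um = centres[, 3])
}

#' Scattering-phantom specification
#'
#' Defaults describe a TiO2-nanoparticle agarose phantom: anatase particles
#' (refractive index 2.55 at 532 nm, density 4.23 g/cm^3) suspended in a
#' water-like gel (n = 1.33).
#'
#' @param particle_diameter_nm particle diameter (nm).
#' @param particle_ri particle refractive index.
#' @param medium_ri medium refractive index.
#' @param particle_density_gcm3 particle bulk density (g/cm^3).
#' @param mass_concentration_mg_ml suspension concentration (mg/mL).
#' @param wavelength_nm illumination wavelength in vacuum (nm).
#' @return An object of class `scattering_phantom_spec`.
#' @export
scattering_phantom_spec <- function(particle_diameter_nm = 160,
                                    particle_ri = 2.55, medium_ri = 1.33,
                                    particle_density_gcm3 = 4.23,
                                    mass_concentration_mg_ml = 1.2,
                                    wavelength_nm = 532) {
  check_positive(particle_diameter_nm, "particle_diameter_nm", "invalid_spec")
  check_positive(wavelength_nm, "wavelength_nm", "invalid_spec")
  check_positive(mass_concentration_mg_ml, "mass_concentration_mg_ml", "invalid_spec")
  if (particle_ri <= medium_ri) {
    clam_abort("invalid_spec", "particle_ri must exceed medium_ri")
  }
  structure(list(particle_diameter_nm = particle_diameter_nm,
                 particle_ri = particle_ri, medium_ri = medium_ri,
                 particle_density_gcm3 = particle_density_gcm3,
                 mass_concentration_mg_ml = mass_concentration_mg_ml,
                 wavelength_nm = wavelength_nm),
            class = "scattering_phantom_spec")
}

#' Mie scattering and asymmetry efficiencies
#'
#' Bohren-Huffman series for a homogeneous sphere: logarithmic-derivative
#' downward recurrence for the internal field, upward Riccati-Bessel
#' recurrence for the external one. Returns the scattering efficiency
#' `Q_sca` and the asymmetry parameter `g = <cos theta>`.
#'
#' @param m relative refractive index (particle / medium), real or complex.
#' @param x size parameter `pi * d * n_medium / lambda`.
#' @return List with `q_sca` and `g`.
#' @export
mie_efficiencies <- function(m, x) {
  check_positive(x, "x", "invalid_spec")
  if (x > 50) clam_warn("series_truncation", "size parameter x = %g is large; series accuracy degrades", x)
  nmax <- ceiling(x + 4 * x^(1 / 3) + 2)
  nmx <- max(nmax, ceiling(Mod(m * x))) + 16
  mx <- m * x
  D <- complex(length.out = nmx + 1)
  for (n in nmx:1) {
    D[n] <- n / mx - 1 / (D[n + 1] + n / mx)
  }
  psi0 <- cos(x); psi1 <- sin(x)
  chi0 <- -sin(x); chi1 <- cos(x)
  a <- complex(length.out = nmax)
  b <- complex(length.out = nmax)
  for (n in seq_len(nmax)) {
    psi <- (2 * n - 1) / x * psi1 - psi0
    chi <- (2 * n - 1) / x * chi1 - chi0
    xi <- complex(real = psi, imaginary = -chi)
    xi1 <- complex(real = psi1, imaginary = -chi1)
    da <- D[n + 1] / m + n / x   # D[n + 1] holds the order-n log derivative
    db <- D[n + 1] * m + n / x
    a[n] <- (da * psi - psi1) / (da * xi - xi1)
    b[n] <- (db * psi - psi1) / (db * xi - xi1)
    psi0 <- psi1; psi1 <- psi
    chi0 <- chi1; chi1 <- chi
  }
  n <- seq_len(nmax)
  q_sca <- (2 / x^2) * sum((2 * n + 1) * (Mod(a)^2 + Mod(b)^2))
  asy <- 0
  if (nmax > 1) {
    k <- seq_len(nmax - 1)
    asy <- sum((k * (k + 2) / (k + 1)) *
                 Re(a[k] * Conj(a[k + 1]) + b[k] * Conj(b[k + 1])))
  }
  asy <- asy + sum(((2 * n + 1) / (n * (n + 1))) * Re(a * Conj(b)))
  list(q_sca = q_sca, g = 4 / (x^2 * q_sca) * asy)
}

#' Reduced scattering coefficient of a particle suspension
#'
#' Computes Mie efficiencies at the suspension's size parameter, converts
#' the mass concentration to a number density, and returns
#' `mu_s = rho_N * Q_sca * pi d^2 / 4`, `mu_s' = mu_s (1 - g)` and the
#' transport mean free path `1 / mu_s'`.
#'
#' @param spec a [scattering_phantom_spec()].
#' @return List with `mu_s_cm`, `mu_s_prime_cm`, `g`, `q_sca`,
#'   `transport_mfp_um`, `number_density_cm3`, `size_parameter`.
#' @export
mie_reduced_scattering <- function(spec) {
  stopifnot(inherits(spec, "scattering_phantom_spec"))
  x <- pi * spec$particle_diameter_nm * spec$medium_ri / spec$wavelength_nm
  eff <- mie_efficiencies(spec$particle_ri / spec$medium_ri, x)
  d_cm <- spec$particle_diameter_nm * 1e-7
  vol_cm3 <- pi / 6 * d_cm^3
  conc_g_cm3 <- spec$mass_concentration_mg_ml * 1e-3
  rho_n <- conc_g_cm3 / (spec$particle_density_gcm3 * vol_cm3)
  mu_s <- rho_n * eff$q_sca * pi * d_cm^2 / 4
  mu_sp <- mu_s * (1 - eff$g)
  list(mu_s_cm = mu_s, mu_s_prime_cm = mu_sp, g = eff$g, q_sca = eff$q_sca,
       transport_mfp_um = 1e4 / mu_sp, number_density_cm3 = rho_n,
       size_parameter = x)
}
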