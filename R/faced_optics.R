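#' Angle-misaligned mirror-pair geometry
#'
#' Describes the "infinity mirror": a pair of high-reflectivity plane mirrors
#' of length `L_mm`, separated by `S_mm`, with a small relative misalignment
#' angle `alpha_rad`. A line-focused input cone of full angle `dtheta_rad`
#' entering the pair breaks into discrete zig-zag beamlets that are
#' retroreflected to the entrance, behaving as an array of virtual sources
#' with progressively longer path delays.
#'
#' @param L_mm mirror length (mm).
#' @param S_mm mirror separation (mm).
#' @param alpha_rad misalignment angle between the mirrors (rad).
#' @param R mirror reflectivity (fraction in (0, 1]).
#' @param dtheta_rad full opening angle of the input light cone (rad).
#' @return An object of class `mirror_pair`.
#' @examples
#' geom <- mirror_pair(L_mm = 200, S_mm = 50, alpha_rad = 1e-3,
#'                     R = 0.998, dtheta_rad = 0.04)
#' num_sheets(geom$dtheta_rad, geom$alpha_rad)
#' @export
mirror_pair <- function(L_mm, S_mm, alpha_rad, R = 0.998, dtheta_rad) {
  check_positive(L_mm, "L_mm")
  check_positive(S_mm, "S_mm")
  check_positive(alpha_rad, "alpha_rad")
  check_positive(dtheta_rad, "dtheta_rad")
  if (!is.numeric(R) || R <= 0 || R > 1) {
    clam_abort("invalid_geometry", "reflectivity `R` must be in (0, 1], got %s", R)
  }
  structure(
    list(L_mm = L_mm, S_mm = S_mm, alpha_rad = alpha_rad, R = R,
         dtheta_rad = dtheta_rad),
    class = "mirror_pair"
  )
}

#' Number of light sheets supported by an input cone
#'
#' The input cone of full angle `dtheta_rad` is subdivided by the mirror
#' misalignment into beamlets spaced `alpha_rad` apart, so the number of
#' sheets (virtual sources) is the ratio of the two angles, taken as a floor
#' to count complete beamlets.
#'
#' @param dtheta_rad input cone full angle (rad).
#' @param alpha_rad mirror misalignment (rad).
#' @return Integer count of light sheets.
#' @export
num_sheets <- function(dtheta_rad, alpha_rad) {
  check_positive(dtheta_rad, "dtheta_rad")
  check_positive(alpha_rad, "alpha_rad")
  # tolerate floating division landing a hair under an integer
  as.integer(floor(dtheta_rad / alpha_rad + 1e-9))
}

#' Effective numerical aperture of the mirror pair
#'
#' The largest input cone that is still retroreflected (instead of leaking
#' past the far end of the mirrors) has effective numerical aperture
#' `NA = sqrt(L * alpha / (2 * S))`. The corresponding maximum acceptance
#' half-angle `asin(NA)` is attached as attribute `theta_max_rad`.
#'
#' @inheritParams mirror_pair
#' @return The numerical aperture (dimensionless), with attribute
#'   `theta_max_rad`.
#' @export
effective_na <- function(L_mm, S_mm, alpha_rad) {
  check_positive(L_mm, "L_mm")
  check_positive(S_mm, "S_mm")
  check_positive(alpha_rad, "alpha_rad")
  na <- sqrt(L_mm * alpha_rad / (2 * S_mm))
  if (na >= 1) {
    clam_abort("invalid_geometry",
               "unphysical aperture: NA = %.3f >= 1 for L = %g mm, S = %g mm, alpha = %g rad",
               na, L_mm, S_mm, alpha_rad)
  }
  structure(na, theta_max_rad = asin(na))
}

#' Virtual-source array of the mirror pair
#'
#' Beamlet `k` (0-based) undergoes `2k` reflections before being
#' retroreflected to the entrance, so it carries an extra path delay `2*k*S`
#' and a power fraction `R^(2k)`. Its exit angle is the centre of the k-th
#' angular bin of the input cone, `(k + 1/2) * alpha`. The `keep_highest`
#' highest-order modes are flagged `selected` (the high-order modes have the
#' most uniform relative intensities and are the ones projected into light
#' sheets).
#'
#' @param geom a [mirror_pair()].
#' @param keep_highest how many highest-order modes to select (default: all).
#' @return A data frame of class `virtual_source_array` with columns `k`,
#'   `exit_angle_rad`, `path_delay_mm`, `power_fraction`, `selected`.
#' @export
virtual_sources <- function(geom, keep_highest = NULL) {
  stopifnot(inherits(geom, "mirror_pair"))
  n <- num_sheets(geom$dtheta_rad, geom$alpha_rad)
  if (is.null(keep_highest)) keep_highest <- n
  if (keep_highest > n) {
    clam_abort("capacity",
               "cannot select %d modes: the geometry supports only %d",
               keep_highest, n)
  }
  if (keep_highest < 1) clam_abort("capacity", "keep_highest must be >= 1")
  k <- 0:(n - 1)
  vsa <- data.frame(
    k = k,
    exit_angle_rad = (k + 0.5) * geom$alpha_rad,
    path_delay_mm = 2 * k * geom$S_mm,
    power_fraction = geom$R^(2 * k),
    selected = k >= (n - keep_highest)
  )
  structure(vsa, class = c("virtual_source_array", "data.frame"),
            geom = geom)
}

#' Light-source coherence specification
#'
#' @param lambda_nm centre wavelength (nm).
#' @param dlambda_nm spectral bandwidth (nm); full width for the rectangular
#'   lineshape, FWHM for the Gaussian one.
#' @param lineshape `"rectangular"` (default) or `"gaussian"`.
#' @return An object of class `coherence_spec`.
#' @export
coherence_spec <- function(lambda_nm, dlambda_nm,
                           lineshape = c("rectangular", "gaussian")) {
  check_positive(lambda_nm, "lambda_nm", "invalid_spec")
  check_positive(dlambda_nm, "dlambda_nm", "invalid_spec")
  lineshape <- match.arg(lineshape)
  structure(list(lambda_nm = lambda_nm, dlambda_nm = dlambda_nm,
                 lineshape = lineshape),
            class = "coherence_spec")
}

#' Coherence length of the source
#'
#' For a rectangular spectrum the coherence length is `lambda^2 / dlambda`.
#' For a Gaussian spectrum of FWHM `dlambda` the usual FWHM-based convention
#' carries a prefactor `sqrt(2 * log(2) / pi)` (about 0.664). Both
#' conventions are exposed because narrow-line sources are conventionally
#' quoted with the Gaussian prefactor while broadband sources are usually
#' quoted with the bare ratio.
#'
#' @param spec a [coherence_spec()].
#' @return Coherence length in micrometres.
#' @examples
#' coherence_length(coherence_spec(712, 5))            # ~101 um
#' coherence_length(coherence_spec(532, 44.5e-3, "gaussian")) # ~4.2 mm
#' @export
coherence_length <- function(spec) {
  stopifnot(inherits(spec, "coherence_spec"))
  base_um <- spec$lambda_nm^2 / spec$dlambda_nm * 1e-3  # nm^2/nm -> um
  if (spec$lineshape == "gaussian") {
    sqrt(2 * log(2) / pi) * base_um
  } else {
    base_um
  }
}

#' Group virtual sources by mutual coherence
#'
#' Two adjacent sources interfere only when their path-delay difference is
#' within the coherence length; runs of sources linked by delays `<= L_c`
#' share a group label, and labels change wherever the gap exceeds `L_c`.
#' With the standard geometry (delay increment `2S` much longer than `L_c`)
#' every source is its own group, which is what makes the summed light-sheet
#' array speckle-free.
#'
#' @param x a [virtual_sources()] array, or a numeric vector of path delays
#'   in mm (need not be uniformly spaced).
#' @param L_c_um coherence length in micrometres.
#' @return Integer group labels (1-based, in delay order).
#' @export
coherence_groups <- function(x, L_c_um) {
  delays_mm <- if (is.data.frame(x)) x$path_delay_mm else as.numeric(x)
  if (length(delays_mm) == 0) return(integer(0))
  if (L_c_um < 0) clam_abort("invalid_spec", "L_c_um must be >= 0")
  ord <- order(delays_mm)
  gaps_um <- diff(delays_mm[ord]) * 1e3
  lab <- cumsum(c(1L, as.integer(gaps_um > L_c_um)))
  out <- integer(length(delays_mm))
  out[ord] <- lab
  out
}

#' Project selected virtual sources into a light-sheet array
#'
#' Relay optics image each selected virtual source into one light sheet. The
#' full relay prescription is collapsed into a single uniform sheet spacing
#' `z0_um`: re-indexed selected sources `k' = 0, 1, ...` land at depths
#' `k' * z0_um`. Sheet thickness, height and confocal parameter are common
#' to all sheets (the array is uniform across the field of view).
#'
#' @param vsa a [virtual_sources()] array with at least one selected source.
#' @param z0_um adjacent sheet separation (um).
#' @param w_ls_um sheet thickness FWHM (um).
#' @param height_um sheet height along y (um).
#' @param confocal_b_um confocal parameter along the propagation axis (um).
#' @param equalize_power if `TRUE` (default) all sheets get relative power 1,
#'   mirroring the intensity-equalised high-order mode selection; otherwise
#'   powers follow `R^(2k)` renormalised to a maximum of 1.
#' @param L_c_um coherence length used to label coherence groups
#'   (default 0: all sheets mutually incoherent).
#' @return A data frame of class `light_sheet_array` with columns
#'   `depth_z_um`, `thickness_w_ls_um`, `height_y_um`, `confocal_b_um`,
#'   `relative_power`, `path_delay_mm`, `coherence_group`.
#' @export
light_sheet_array <- function(vsa, z0_um, w_ls_um, height_um = 50,
                              confocal_b_um = 50, equalize_power = TRUE,
                              L_c_um = 0) {
  stopifnot(is.data.frame(vsa))
  check_positive(z0_um, "z0_um", "invalid_spec")
  check_positive(w_ls_um, "w_ls_um", "invalid_spec")
  sel <- vsa[vsa$selected, , drop = FALSE]
  if (nrow(sel) == 0) clam_abort("empty_array", "no selected virtual sources")
  sel <- sel[order(sel$k), , drop = FALSE]
  groups <- coherence_groups(sel$path_delay_mm, L_c_um)
  power <- if (equalize_power) rep(1, nrow(sel)) else
    sel$power_fraction / max(sel$power_fraction)
  lsa <- data.frame(
    depth_z_um = (seq_len(nrow(sel)) - 1) * z0_um,
    thickness_w_ls_um = w_ls_um,
    height_y_um = height_um,
    confocal_b_um = confocal_b_um,
    relative_power = power,
    path_delay_mm = sel$path_delay_mm,
    coherence_group = groups
  )
  structure(lsa, class = c("light_sheet_array", "data.frame"),
            z0_um = z0_um)
}
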