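#' Per-bead PSF FWHM measurement
#'
#' For each supplied bead centre, snaps to the brightest voxel in a small
#' neighbourhood and measures the FWHM of the axis-aligned intensity
#' profiles through it by linear interpolation of the half-maximum
#' crossings. Beads touching the volume boundary, or closer to another bead
#' than `isolation_um`, are flagged and excluded rather than measured.
#'
#' @param x a `recon_volume` or a 3D `(z, y, x)` array.
#' @param centres_um data frame with `z_um`, `y_um`, `x_um` (for instance
#'   the `centres_um` attribute of [make_bead_phantom()]).
#' @param voxel_um voxel size `(z, y, x)` in um. For a `recon_volume` the z
#'   spacing defaults to the calibrated depth axis pitch.
#' @param isolation_um minimum allowed distance to the nearest other bead;
#'   default `3 *` the median measured lateral FWHM is applied post hoc when
#'   `NULL`.
#' @param search_vox half-width of the centre-refinement window (voxels).
#' @return Data frame with `fwhm_z_um`, `fwhm_y_um`, `fwhm_x_um`, `ok`,
#'   `reason`.
#' @export
measure_psf <- function(x, centres_um, voxel_um = NULL, isolation_um = NULL,
                        search_vox = 2L) {
  vol <- if (inherits(x, "recon_volume")) x$volume else x
  if (inherits(x, "recon_volume") && is.null(voxel_um)) {
    clam_abort("invalid_spec",
               "supply voxel_um = c(z, y, x); lateral pitch is not stored in the volume")
  }
  if (length(voxel_um) == 1) voxel_um <- rep(voxel_um, 3)
  d <- dim(vol)
  n <- nrow(centres_um)
  res <- data.frame(fwhm_z_um = rep(NA_real_, n), fwhm_y_um = NA_real_,
                    fwhm_x_um = NA_real_, ok = FALSE, reason = "")
  if (n == 0) return(res)
  pos <- as.matrix(centres_um[, c("z_um", "y_um", "x_um")])
  for (b in seq_len(n)) {
    if (!is.null(isolation_um) && n > 1) {
      dd <- sqrt(rowSums((pos[-b, , drop = FALSE] -
                            matrix(pos[b, ], n - 1, 3, byrow = TRUE))^2))
      if (min(dd) < isolation_um) {
        res$reason[b] <- "not isolated"
        next
      }
    }
    idx <- round(pos[b, ] / voxel_um) + 1
    if (any(idx < 1 + search_vox) || any(idx > d - search_vox)) {
      res$reason[b] <- "touches boundary"
      next
    }
    # refine to the local maximum
    win <- lapply(1:3, function(i) (idx[i] - search_vox):(idx[i] + search_vox))
    sub <- vol[win[[1]], win[[2]], win[[3]], drop = FALSE]
    mx <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    idx <- idx - search_vox - 1 + mx
    prof <- list(
      z = vol[, idx[2], idx[3]],
      y = vol[idx[1], , idx[3]],
      x = vol[idx[1], idx[2], ]
    )
    f <- vapply(1:3, function(i) {
      fwhm_interp((seq_along(prof[[i]]) - 1) * voxel_um[i], prof[[i]])
    }, numeric(1))
    if (any(is.na(f))) {
      res$reason[b] <- "profile not resolved"
      next
    }
    res$fwhm_z_um[b] <- f[1]
    res$fwhm_y_um[b] <- f[2]
    res$fwhm_x_um[b] <- f[3]
    res$ok[b] <- TRUE
  }
  res
}

#' Depth-of-field estimate from FWHM-versus-depth samples
#'
#' Fits a quadratic to the measured FWHM(z) curve and reports the depth of
#' field as the width of the region where the fitted curve stays within
#' `sqrt(2)` times its fitted minimum, in closed form from the fit
#' coefficients. Non-positive curvature yields an unbounded-DOF flag.
#'
#' @param z_um depth samples (um), at least 5 spanning the minimum.
#' @param fwhm_um measured FWHM at each depth (um).
#' @return List of class `dof_curve`: `coefficients` (c0, c1, c2),
#'   `min_fwhm_um`, `dof_um`, `unbounded`, plus the input samples.
#' @export
estimate_dof <- function(z_um, fwhm_um) {
  if (length(z_um) < 5 || length(z_um) != length(fwhm_um)) {
    clam_abort("invalid_spec", "need >= 5 matched (z, FWHM) samples")
  }
  if (any(fwhm_um <= 0)) clam_abort("domain", "FWHM samples must be > 0")
  fit <- stats::lm(fwhm_um ~ z_um + I(z_um^2))
  cf <- unname(coef(fit))
  c0 <- cf[1]; c1 <- cf[2]; c2 <- cf[3]
  if (c2 <= 0) {
    return(structure(list(z_um = z_um, fwhm_um = fwhm_um,
                          coefficients = cf, min_fwhm_um = NA_real_,
                          dof_um = Inf, unbounded = TRUE),
                     class = "dof_curve"))
  }
  fmin <- c0 - c1^2 / (4 * c2)
  disc <- c1^2 - 4 * c2 * (c0 - sqrt(2) * fmin)
  dof <- if (disc > 0) sqrt(disc) / c2 else 0
  structure(list(z_um = z_um, fwhm_um = fwhm_um, coefficients = cf,
                 min_fwhm_um = fmin, dof_um = dof, unbounded = FALSE),
            class = "dof_curve")
}

#' Signal-to-noise ratio in decibels
#'
#' `SNR_dB = 10 * log10( (mean(signal) - mean(background)) / sd(background) )`.
#' This fixes one explicit convention for a quantity that is reported in
#' many inconsistent ways; it is invariant to uniform intensity rescaling.
#'
#' @param image numeric array or matrix.
#' @param signal_mask,background_mask logical masks of the same shape,
#'   disjoint and non-empty.
#' @return SNR in dB (`Inf` with a flag attribute if the background has
#'   zero variance).
#' @export
snr_db <- function(image, signal_mask, background_mask) {
  if (!any(signal_mask) || !any(background_mask)) {
    clam_abort("invalid_spec", "masks must be non-empty")
  }
  if (any(signal_mask & background_mask)) {
    clam_abort("invalid_spec", "signal and background masks must be disjoint")
  }
  sb <- sd(image[background_mask])
  if (sb == 0) {
    return(structure(Inf, flag = "zero background variance"))
  }
  10 * log10((mean(image[signal_mask]) - mean(image[background_mask])) / sb)
}

#' Speckle contrast of an intensity region
#'
#' Standard deviation over mean: ~1 for fully developed coherent speckle,
#' ~`1/sqrt(M)` after averaging `M` independent patterns, 0 for a constant
#' field.
#'
#' @param region numeric vector/array of intensities (>= 1000 samples for a
#'   stable estimate; fewer only warns).
#' @return The contrast (dimensionless fraction).
#' @export
speckle_contrast <- function(region) {
  v <- as.numeric(region)
  if (length(v) < 1000) {
    clam_warn("small_region", "contrast estimated from only %d samples", length(v))
  }
  m <- mean(v)
  if (m == 0) clam_abort("undefined_contrast", "zero-mean region")
  sd(v) / m
}

#' Photobleaching decay curve under a multiplexed or scanned schedule
#'
#' Acquires `n_volumes` successive volumes from the same fluorophore field
#' and returns the mean ROI intensity per volume, normalised to the first.
#' Both modes deliver the same signal per volume (equal intensity x dwell
#' product): the multiplexed mode (`"CLAM"`) illuminates every plane at
#' intensity `I` for the whole volume time `T`; the sequentially scanned
#' mode (`"SLS"`) illuminates at `N * I` for `T / N`. With bleaching
#' exponent `gamma = 1` the two decay identically; with `gamma > 1` the
#' scanned mode bleaches `N^(gamma - 1)` times faster.
#'
#' @param mode `"CLAM"` or `"SLS"`.
#' @param ph a [phantom()]; its density is the fluorophore field and ROI.
#' @param schedule list with `n_volumes`, `t_vol_s` (volume period),
#'   `intensity` (multiplexed-mode illumination intensity), `N` (number of
#'   planes).
#' @param gamma bleaching intensity exponent (>= 1).
#' @param k_b bleaching rate constant.
#' @return Data frame with `volume` and `intensity_norm` (non-increasing,
#'   starting at 1).
#' @export
bleaching_experiment <- function(mode = c("CLAM", "SLS"), ph, schedule,
                                 gamma = 1, k_b = 0.1) {
  mode <- match.arg(mode)
  stopifnot(inherits(ph, "phantom"))
  needed <- c("n_volumes", "t_vol_s", "intensity", "N")
  if (!all(needed %in% names(schedule))) {
    clam_abort("invalid_spec", "schedule needs fields %s",
               paste(needed, collapse = ", "))
  }
  fluor <- ph$density
  exc <- array(schedule$intensity, dim(fluor))
  signal <- numeric(schedule$n_volumes)
  for (v in seq_len(schedule$n_volumes)) {
    signal[v] <- mean(fluor)
    if (mode == "CLAM") {
      fluor <- photobleach_step(fluor, exc, k_b, gamma, schedule$t_vol_s)
    } else {
      # each voxel sees its own sheet once per volume: N-fold intensity
      # for 1/N of the volume period
      fluor <- photobleach_step(fluor, schedule$N * exc, k_b, gamma,
                                schedule$t_vol_s / schedule$N)
    }
  }
  data.frame(volume = seq_len(schedule$n_volumes),
             intensity_norm = signal / signal[1])
}
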