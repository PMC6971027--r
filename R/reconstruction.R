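#' Short-time Fourier demodulation of a frame sequence
#'
#' Per pixel and per window, the amplitude of channel `k` is the matched
#' filter at the exact carrier frequency,
#' `(2 / W) * | sum_t w(t) I(t) exp(-i 2 pi f_k t) |`, where `w` is the
#' window (`W = sum w`). The carriers are known from the plan, so no bin
#' picking is needed; for bin-aligned plans the matched filter and the DFT
#' bin coincide. The DC term is implicitly discarded (only carrier
#' frequencies are evaluated). Successive windows advance by `hop_s`
#' (default one window, non-overlapping), producing one demodulated volume
#' per `1 / f_vol` of data.
#'
#' @param fs a [render_frames()] sequence (or a compatible list with
#'   `frames` and `frame_rate`).
#' @param plan the [make_plan()] used for encoding.
#' @param window `"rect"` (default; preserves the `1.21 / T` channel width)
#'   or `"hann"` (more robust to carrier jitter).
#' @param hop_s hop between successive windows (s); default `plan$window_T`.
#' @return An object of class `channel_spectrum`: `amplitudes` is a 4D array
#'   `(window, channel, y, x)`; also carries `channel_freqs_hz`, `window_T`,
#'   `window_starts_s`.
#' @export
stft_demodulate <- function(fs, plan, window = c("rect", "hann"),
                            hop_s = NULL) {
  stopifnot(inherits(plan, "encoding_plan"))
  window <- match.arg(window)
  frames <- fs$frames
  f_cam <- fs$frame_rate
  n_frames <- dim(frames)[1]
  M <- round(plan$window_T * f_cam)
  if (plan$window_T < 1 / plan$delta_f - 1e-9) {
    clam_abort("frequency_resolution",
               "window %g s is shorter than 1/delta_f = %g s: channels unresolvable",
               plan$window_T, 1 / plan$delta_f)
  }
  if (n_frames < M) {
    clam_abort("frequency_resolution",
               "sequence has %d frames but one window needs %d", n_frames, M)
  }
  if (is.null(hop_s)) hop_s <- plan$window_T
  hop_M <- max(1L, round(hop_s * f_cam))
  starts <- seq(1L, n_frames - M + 1L, by = hop_M)

  w <- if (window == "hann") 0.5 - 0.5 * cos(2 * pi * (0:(M - 1)) / (M - 1))
       else rep(1, M)
  d <- dim(frames)
  npix <- d[2] * d[3]
  amps <- array(0, c(length(starts), plan$N, d[2], d[3]))
  for (wi in seq_along(starts)) {
    idx <- starts[wi]:(starts[wi] + M - 1L)
    t <- (idx - 1L) / f_cam
    # (channels x M) complex matched-filter bank
    Ebank <- exp(-2i * pi * outer(plan$freqs_hz, t)) *
      matrix(w, plan$N, M, byrow = TRUE)
    Fw <- matrix(frames[idx, , ], M, npix)
    amps[wi, , , ] <- array(abs(Ebank %*% Fw) * (2 / sum(w)),
                            c(plan$N, d[2], d[3]))
  }
  structure(
    list(amplitudes = amps, channel_freqs_hz = plan$freqs_hz,
         window_T = plan$window_T,
         window_starts_s = (starts - 1L) / f_cam, plan = plan),
    class = "channel_spectrum"
  )
}

#' Measured centre frequency and bandwidth of each channel
#'
#' Per-pixel spectral characterisation of a calibration-style acquisition.
#' For each channel the pixel with the strongest matched-filter response is
#' selected (each depth plane dominates its own patch of the image), and a
#' finely sampled discrete-time Fourier magnitude of that pixel's
#' mean-subtracted series over the *whole* sequence is evaluated in a band
#' of one carrier spacing around the nominal carrier. The centre is refined
#' by parabolic interpolation around the maximum; the bandwidth is the FWHM
#' of the magnitude peak (about `1.21 / T` for a rectangular window of
#' length `T`). Channels whose peak stays below `missing_rel` of the
#' strongest channel's are flagged `missing` rather than raising.
#'
#' @param fs a [render_frames()] sequence.
#' @param plan the encoding plan.
#' @param oversample frequency-grid oversampling relative to `1/T`.
#' @param missing_rel relative amplitude below which a channel is flagged
#'   absent.
#' @return Data frame with `channel`, `f_nominal_hz`, `f_centre_hz`,
#'   `bandwidth_hz`, `amplitude`, `missing`.
#' @export
peak_frequencies <- function(fs, plan, oversample = 16, missing_rel = 0.05) {
  stopifnot(inherits(plan, "encoding_plan"))
  d <- dim(fs$frames)
  npix <- d[2] * d[3]
  Fmat <- matrix(fs$frames, d[1], npix)
  Fmat <- sweep(Fmat, 2, colMeans(Fmat))
  t <- (0:(d[1] - 1)) / fs$frame_rate
  T_full <- d[1] / fs$frame_rate
  df <- 1 / T_full / oversample
  # matched filter over the whole sequence picks each channel's pixel
  bank <- exp(-2i * pi * outer(plan$freqs_hz, t))
  resp <- abs(bank %*% Fmat)
  out <- lapply(seq_len(plan$N), function(k) {
    s <- Fmat[, which.max(resp[k, ])]
    f0 <- plan$freqs_hz[k]
    grid <- seq(f0 - 0.75 * plan$delta_f, f0 + 0.75 * plan$delta_f, by = df)
    mag <- as.vector(abs(exp(-2i * pi * outer(grid, t)) %*% s)) * (2 / d[1])
    m <- which.max(mag)
    centre <- grid[m]
    if (m > 1 && m < length(grid)) {
      den <- mag[m - 1] - 2 * mag[m] + mag[m + 1]
      if (abs(den) > 0) {
        centre <- grid[m] + 0.5 * (mag[m - 1] - mag[m + 1]) / den * df
      }
    }
    data.frame(channel = k, f_nominal_hz = f0, f_centre_hz = centre,
               bandwidth_hz = fwhm_interp(grid, mag), amplitude = mag[m])
  })
  out <- do.call(rbind, out)
  out$missing <- out$amplitude < missing_rel * max(out$amplitude)
  out
}

#' Frequency-to-depth calibration
#'
#' Ordinary least-squares fit of `depth = beta * f + c` to measured channel
#' centre frequencies at known depths. The slope `beta` (um/Hz) is the
#' conversion factor used to place demodulated channel images on the depth
#' axis.
#'
#' @param centre_freqs_hz measured channel centre frequencies (Hz).
#' @param known_depths_um corresponding known depths (um).
#' @return An object of class `calibration_fit` with `slope_beta_um_per_hz`,
#'   `intercept_um`, `r_squared`, `residuals_um`.
#' @export
calibrate_depth <- function(centre_freqs_hz, known_depths_um) {
  if (length(centre_freqs_hz) < 2 ||
      length(centre_freqs_hz) != length(known_depths_um)) {
    clam_abort("singular_fit", "need >= 2 matched (frequency, depth) pairs")
  }
  if (stats::sd(centre_freqs_hz) == 0) {
    clam_abort("singular_fit", "all centre frequencies identical: fit is singular")
  }
  fit <- stats::lm(known_depths_um ~ centre_freqs_hz)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((known_depths_um - mean(known_depths_um))^2)
  structure(
    list(slope_beta_um_per_hz = unname(coef(fit)[2]),
         intercept_um = unname(coef(fit)[1]),
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
         residuals_um = unname(stats::residuals(fit))),
    class = "calibration_fit"
  )
}

#' Stack demodulated channels into a depth-calibrated volume
#'
#' Orders channel images by calibrated depth, stacks them along `z`, and
#' applies a centred moving average of `boxcar_width` channels along the
#' depth axis (shrinking to the valid range at the edges). The boxcar
#' suppresses the discreteness of the frequency channels at a known cost in
#' axial resolution.
#'
#' @param spectrum a [stft_demodulate()] result.
#' @param fit a [calibrate_depth()] fit.
#' @param boxcar_width odd integer `>= 1`; 1 disables smoothing.
#' @param window which demodulation window to assemble (default 1).
#' @return An object of class `recon_volume`: `volume` `(z, y, x)`,
#'   `depth_axis_um`, and a `log` of processing steps.
#' @export
assemble_volume <- function(spectrum, fit, boxcar_width = 3, window = 1) {
  stopifnot(inherits(spectrum, "channel_spectrum"),
            inherits(fit, "calibration_fit"))
  if (boxcar_width < 1 || boxcar_width %% 2 == 0) {
    clam_abort("parameter", "boxcar_width must be odd and >= 1, got %s",
               boxcar_width)
  }
  vol <- spectrum$amplitudes[window, , , , drop = TRUE]
  dd <- dim(spectrum$amplitudes)[-1]
  vol <- array(vol, dd)
  depth <- fit$slope_beta_um_per_hz * spectrum$channel_freqs_hz +
    fit$intercept_um
  ord <- order(depth)
  vol <- vol[ord, , , drop = FALSE]
  depth <- depth[ord]
  if (boxcar_width > 1) {
    h <- (boxcar_width - 1) / 2
    n <- dim(vol)[1]
    sm <- vol
    for (i in seq_len(n)) {
      rng <- max(1, i - h):min(n, i + h)
      sm[i, , ] <- apply(vol[rng, , , drop = FALSE], c(2, 3), mean)
    }
    vol <- sm
  }
  structure(
    list(volume = vol, depth_axis_um = depth,
         log = list(list(step = "assemble_volume",
                         boxcar_width = boxcar_width, window = window))),
    class = "recon_volume"
  )
}

#' Richardson-Lucy deconvolution
#'
#' Standard multiplicative Richardson-Lucy updates with FFT convolution:
#' `est <- est * ( (data / (est (*) psf)) (*) psf_flipped )`. The iteration
#' preserves non-negativity and (for interior objects) total intensity.
#' Stops early when the relative change drops below `tol`.
#'
#' @param x a `recon_volume` or a non-negative 3D array.
#' @param psf 3D kernel, will be checked to sum to ~1.
#' @param iterations maximum iterations (1-200, default 20).
#' @param tol early-stop threshold on the relative update norm.
#' @return Same type as `x`, deconvolved; a `recon_volume` gains a log entry.
#' @export
rl_deconvolve <- function(x, psf, iterations = 20, tol = 1e-4) {
  is_rv <- inherits(x, "recon_volume")
  vol <- if (is_rv) x$volume else x
  if (iterations < 1 || iterations > 200) {
    clam_abort("parameter", "iterations must be in [1, 200]")
  }
  s <- sum(psf)
  if (s <= 0) clam_abort("normalization", "PSF must have positive sum")
  if (abs(s - 1) > 1e-6) psf <- psf / s
  kd <- dim(psf)
  if (any(kd > dim(vol))) {
    clam_abort("shape", "PSF (%s) larger than the volume (%s)",
               paste(kd, collapse = "x"), paste(dim(vol), collapse = "x"))
  }
  psf_m <- psf[rev(seq_len(kd[1])), rev(seq_len(kd[2])), rev(seq_len(kd[3])),
               drop = FALSE]
  eps <- 1e-12 * max(vol) + 1e-300
  est <- pmax(vol, 0) + eps
  used <- 0
  for (it in seq_len(iterations)) {
    blur <- pmax(fft_convolve(est, psf), 0) + eps
    est_new <- est * pmax(fft_convolve(vol / blur, psf_m), 0)
    rel <- sqrt(sum((est_new - est)^2) / (sum(est^2) + eps))
    est <- est_new
    used <- it
    if (rel < tol) break
  }
  est <- pmax(est, 0)
  if (is_rv) {
    x$volume <- est
    x$log <- c(x$log, list(list(step = "rl_deconvolve",
                                iterations = used, tol = tol)))
    x
  } else {
    est
  }
}

#' Full reconstruction pipeline
#'
#' Demodulate, calibrate (or apply a stored calibration), assemble and
#' optionally deconvolve, returning one volume per demodulation window.
#' Known sheet depths are taken, in order of preference, from
#' `config$calibration` (a [calibrate_depth()] fit), `config$known_depths_um`,
#' the sheet depths stored in the frame metadata, or unit channel spacing.
#'
#' @param fs a [render_frames()] sequence (or one read back from disk).
#' @param plan the encoding plan.
#' @param psf optional 3D kernel for Richardson-Lucy deconvolution.
#' @param config list of options: `window` (`"rect"`/`"hann"`),
#'   `boxcar_width` (default 3), `rl_iterations` (default 20),
#'   `calibration`, `known_depths_um`.
#' @return A list of `recon_volume`, one per window.
#' @export
reconstruct <- function(fs, plan, psf = NULL, config = list()) {
  boxcar <- config$boxcar_width %||% 3
  win <- config$window %||% "rect"
  rl_it <- config$rl_iterations %||% 20

  spectrum <- with_stage("stft_demodulate",
                         stft_demodulate(fs, plan, window = win))
  fit <- config$calibration
  if (is.null(fit)) {
    depths <- config$known_depths_um
    if (is.null(depths) && !is.null(fs$metadata$lsa)) {
      depths <- fs$metadata$lsa$depth_z_um
    }
    if (is.null(depths)) depths <- seq_len(plan$N) - 1
    fit <- with_stage("calibrate_depth",
                      calibrate_depth(plan$freqs_hz, depths))
  }
  lapply(seq_along(spectrum$window_starts_s), function(wi) {
    rv <- with_stage("assemble_volume",
                     assemble_volume(spectrum, fit, boxcar_width = boxcar,
                                     window = wi))
    if (!is.null(psf)) {
      rv <- with_stage("rl_deconvolve",
                       rl_deconvolve(rv, psf, iterations = rl_it))
    }
    rv
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

with_stage <- function(stage, expr) {
  tryCatch(expr, clam_error = function(e) {
    clam_abort("pipeline", "[%s] %s", stage, conditionMessage(e))
  })
}
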