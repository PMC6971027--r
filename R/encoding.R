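#' Build an OFDM encoding plan
#'
#' Allocates one frequency carrier per light sheet. The carrier spacing
#' equals the volumetric frame rate (`delta_f = f_vol`), carriers run from
#' `f_L = f_H - (N - 1) * delta_f` up to `f_H`, and the demodulation window
#' is one volume period `window_T = 1 / f_vol`. Carriers that are integer
#' multiples of `1 / window_T` are *bin-aligned*: over one window they are
#' exactly orthogonal.
#'
#' @param f_cam camera frame rate (frames/s).
#' @param f_vol volumetric frame rate (volumes/s), equal to the carrier
#'   spacing `delta_f`.
#' @param N number of channels (light sheets).
#' @param f_H highest carrier frequency (Hz).
#' @param waveform `"cosine"` (the reconstruction model) or `"square"`
#'   (faithful to the sgn-pattern spinning reticle).
#' @param phases per-channel carrier phases (rad), default all zero.
#' @return An object of class `encoding_plan`.
#' @examples
#' plan <- make_plan(f_cam = 3183, f_vol = 13, N = 24, f_H = 1399)
#' plan$f_L  # 1100 Hz: the 1.1-1.4 kHz fast-mode band
#' @export
make_plan <- function(f_cam, f_vol, N, f_H,
                      waveform = c("cosine", "square"), phases = NULL) {
  check_positive(f_cam, "f_cam", "infeasible_plan")
  check_positive(f_vol, "f_vol", "infeasible_plan")
  check_positive(N, "N", "infeasible_plan")
  check_positive(f_H, "f_H", "infeasible_plan")
  waveform <- match.arg(waveform)
  N <- as.integer(N)
  delta_f <- f_vol
  f_L <- f_H - (N - 1) * delta_f
  if (f_L <= 0) {
    clam_abort("infeasible_plan",
               "N = %d channels at delta_f = %g Hz do not fit below f_H = %g Hz (f_L = %g <= 0)",
               N, delta_f, f_H, f_L)
  }
  if (is.null(phases)) phases <- rep(0, N)
  if (length(phases) != N) {
    clam_abort("infeasible_plan", "need %d phases, got %d", N, length(phases))
  }
  window_T <- 1 / f_vol
  freqs <- f_L + (0:(N - 1)) * delta_f
  structure(
    list(N = N, f_L = f_L, f_H = f_H, delta_f = delta_f, f_vol = f_vol,
         f_cam = f_cam, waveform = waveform, freqs_hz = freqs,
         phases_rad = phases, window_T = window_T,
         bin_aligned = all(abs(freqs * window_T - round(freqs * window_T)) < 1e-6)),
    class = "encoding_plan"
  )
}

#' Check a plan against the encoding design rules
#'
#' Three rules govern a workable carrier plan:
#' * `nyquist`: the highest carrier must be below half the camera frame rate,
#'   `f_H < f_cam / 2`, or it aliases.
#' * `harmonic`: the lowest carrier must exceed half of the highest,
#'   `f_L > f_H / 2`, so that second/third harmonics of the (square-wave)
#'   modulation fall outside the signal band.
#' * `depth_sampling`: the depth pitch of the frequency channels,
#'   `delta_d = beta * delta_f`, should not exceed the sheet thickness
#'   `w_LS`. Real systems run this rule right at its edge, so by default a
#'   pitch up to `1.2 * w_LS` is reported as a warning rather than a
#'   violation; `strict = TRUE` enforces `delta_d < w_LS` exactly.
#'
#' Validation never raises: it returns a report.
#'
#' @param plan an [make_plan()] object.
#' @param w_ls_um light-sheet thickness FWHM (um), for the depth rule.
#' @param beta_um_per_hz calibrated depth-per-frequency slope (um/Hz).
#' @param strict enforce the strict depth-sampling inequality.
#' @return A list with `violations` and `warnings` (character vectors) and a
#'   `checks` data frame; valid plans have `length(violations) == 0`.
#' @export
validate_plan <- function(plan, w_ls_um = NULL, beta_um_per_hz = NULL,
                          strict = FALSE) {
  stopifnot(inherits(plan, "encoding_plan"))
  checks <- list()
  violations <- character(0)
  warnings <- character(0)

  ny_ok <- plan$f_H < plan$f_cam / 2
  checks$nyquist <- data.frame(rule = "nyquist", value = plan$f_H,
                               limit = plan$f_cam / 2, pass = ny_ok)
  if (!ny_ok) violations <- c(violations, "nyquist")

  ha_ok <- plan$f_L > plan$f_H / 2
  checks$harmonic <- data.frame(rule = "harmonic", value = plan$f_L,
                                limit = plan$f_H / 2, pass = ha_ok)
  if (!ha_ok) violations <- c(violations, "harmonic")

  if (!is.null(w_ls_um) && !is.null(beta_um_per_hz)) {
    dd <- beta_um_per_hz * plan$delta_f
    ok_strict <- dd < w_ls_um
    ok_loose <- dd <= 1.2 * w_ls_um
    checks$depth_sampling <- data.frame(rule = "depth_sampling", value = dd,
                                        limit = w_ls_um, pass = ok_strict)
    if (strict) {
      if (!ok_strict) violations <- c(violations, "depth_sampling")
    } else {
      if (!ok_loose) violations <- c(violations, "depth_sampling")
      else if (!ok_strict) warnings <- c(warnings, "depth_sampling")
    }
  }
  list(violations = violations, warnings = warnings,
       checks = do.call(rbind, checks))
}

#' Carrier waveform of one channel
#'
#' Returns the zero-mean carrier `m_k(t)` in `[-1, 1]`: a cosine
#' `cos(2 pi f_k t + phi_k)`, or its sign for the square (reticle-faithful)
#' waveform. The physical transmission applied to the light sheet is
#' `(1 + m_k(t)) / 2`, which lies in `[0, 1]`.
#'
#' @param plan an [make_plan()] object.
#' @param channel channel index, 1-based.
#' @param t numeric vector of times (s).
#' @return Samples of the carrier.
#' @export
modulation_waveform <- function(plan, channel, t) {
  stopifnot(inherits(plan, "encoding_plan"))
  if (channel < 1 || channel > plan$N) {
    clam_abort("index", "channel %d outside 1..%d", channel, plan$N)
  }
  ph <- 2 * pi * plan$freqs_hz[channel] * t + plan$phases_rad[channel]
  m <- cos(ph)
  if (plan$waveform == "square") m <- sign(m) + (m == 0)
  m
}

#' Gram matrix of the carrier set
#'
#' Computes `(2 / M) * sum_t m_k(t) m_j(t)` over one demodulation window on
#' the discrete camera time grid. The `2/M` normalisation gives a unit
#' cosine carrier unit diagonal. For a bin-aligned cosine plan the result is
#' the identity (off-diagonal leakage below 1e-2); square waves leak into
#' odd-harmonic pairs (for `f_j = 3 f_k` the continuous-time cross term is
#' exactly `-2/3` under this normalisation, i.e. 1/3 of the square diagonal).
#'
#' @param plan an [make_plan()] object.
#' @return `N x N` numeric matrix.
#' @export
orthogonality_gram <- function(plan) {
  stopifnot(inherits(plan, "encoding_plan"))
  M <- round(plan$window_T * plan$f_cam)
  t <- (0:(M - 1)) / plan$f_cam
  W <- vapply(seq_len(plan$N), function(k) modulation_waveform(plan, k, t),
              numeric(M))
  (2 / M) * crossprod(W)
}

#' Spinning-reticle specification
#'
#' The reticle carries the binary pattern
#' `T(r, phi) = 1/2 + 1/2 * sgn(cos(omega * phi))` with `omega = 2 pi r`
#' spokes per revolution at radius `r` (r in mm), so a beamlet hitting the
#' disc at radius `r_k` is intensity-modulated at `f_k = 2 pi r_k` cycles
#' per revolution times the rotation rate.
#'
#' @param rotation_rev_s rotation rate (revolutions per second). The
#'   reference motor covers 2-33.3 rev/s (120-2000 rpm); rates outside that
#'   range only warn.
#' @param r_mm increasing radial positions of the beamlets on the disc (mm).
#' @return An object of class `reticle_spec`.
#' @export
reticle_spec <- function(rotation_rev_s, r_mm) {
  check_positive(rotation_rev_s, "rotation_rev_s", "invalid_spec")
  check_positive(r_mm, "r_mm", "invalid_spec")
  if (is.unsorted(r_mm, strictly = TRUE)) {
    clam_abort("invalid_spec", "`r_mm` must be strictly increasing")
  }
  rpm <- rotation_rev_s * 60
  if (rpm < 120 || rpm > 2000) {
    clam_warn("motor_range", "rotation %g rpm outside the 120-2000 rpm motor range", rpm)
  }
  structure(list(rotation_rev_s = rotation_rev_s, r_mm = r_mm),
            class = "reticle_spec")
}

#' Reticle transmission pattern
#'
#' @param r_mm radius on the disc (mm).
#' @param phi azimuthal angle (rad).
#' @return Transmission in `{0, 1/2, 1}` (1/2 only on the spoke edges).
#' @export
reticle_transmission <- function(r_mm, phi) {
  0.5 + 0.5 * sign(cos(2 * pi * r_mm * phi))
}

#' Modulation frequencies imposed by the reticle
#'
#' A beamlet at radius `r_k` sees `2 pi r_k` spokes per revolution, hence
#' `f_k = 2 pi r_k * rotation_rate`. The map is linear in radius, which is
#' what produces the linear frequency chirp across the beamlet array.
#'
#' @param reticle a [reticle_spec()].
#' @return Channel frequencies (Hz), one per radial position.
#' @export
reticle_frequencies <- function(reticle) {
  stopifnot(inherits(reticle, "reticle_spec"))
  2 * pi * reticle$r_mm * reticle$rotation_rev_s
}

#' Per-plane exposure of the equivalent sequentially scanned acquisition
#'
#' A scanned single-light-sheet system matching the multiplexed volume rate
#' must divide the camera exposure among the `N` planes, so each plane gets
#' `t_cam / N`. This is the exposure-accounting used when comparing
#' photobleaching between the two modes.
#'
#' @param t_cam_s camera exposure per multiplexed frame (s).
#' @param N number of planes.
#' @return Per-plane exposure (s).
#' @export
equivalent_sls_exposure <- function(t_cam_s, N) {
  check_positive(t_cam_s, "t_cam_s", "invalid_spec")
  if (N < 1) clam_abort("invalid_spec", "N must be >= 1, got %s", N)
  t_cam_s / N
}

#' Channel capacity of a frequency band
#'
#' With the harmonic rule pinning `f_L` at `f_H / 2`, the usable bandwidth
#' is `f_H - f_L` and the number of channels that fit at spacing `f_vol` is
#' `floor((f_H - f_L) / f_vol)`.
#'
#' @param f_H highest carrier (Hz).
#' @param f_vol volume rate = carrier spacing (Hz).
#' @param f_L lowest carrier (Hz); defaults to the harmonic-rule bound.
#' @return Integer channel count.
#' @examples
#' channel_capacity(1400, 10)  # 70 sheets at 10 vol/s
#' @export
channel_capacity <- function(f_H, f_vol, f_L = f_H / 2) {
  check_positive(f_H, "f_H", "infeasible_plan")
  check_positive(f_vol, "f_vol", "infeasible_plan")
  if (f_L >= f_H) clam_abort("infeasible_plan", "f_L must be below f_H")
  as.integer(floor((f_H - f_L) / f_vol + 1e-9))
}
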