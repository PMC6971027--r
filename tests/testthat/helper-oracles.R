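# Independent oracles and shared fixtures, kept free of the package's own
# formula paths.

# --- zig-zag ray trace through the misaligned mirror cavity ---------------
# Mirror A: y = 0, x in [0, L]. Mirror B: through (0, S), tilted by -alpha
# (cavity converges along +x). A ray enters at (0, S/2) crossing the gap
# with drift angle delta; it is retroreflected if it turns around (drift
# reverses) before drifting past x = L. Returns the turning depth, or Inf
# if the ray leaks out of the far end.
trace_turning_depth <- function(L, S, alpha, delta, max_bounce = 20000) {
  p <- c(0, S / 2)
  d <- c(sin(delta), cos(delta))
  nB <- c(sin(alpha), cos(alpha))
  pB <- c(0, S)
  xmax <- 0
  for (i in seq_len(max_bounce)) {
    if (d[2] > 0) {
      t <- sum((pB - p) * nB) / sum(d * nB)
      p <- p + t * d
      d <- d - 2 * sum(d * nB) * nB
    } else {
      t <- -p[2] / d[2]
      p <- p + t * d
      d[2] <- -d[2]
    }
    xmax <- max(xmax, p[1])
    if (p[1] > L) return(Inf)
    if (d[1] < 0) return(xmax)
  }
  xmax
}

# largest full-cone entry angle still retroreflected, by bisection
raytrace_acceptance_angle <- function(L, S, alpha) {
  lo <- 0
  hi <- 0.5
  for (i in 1:50) {
    mid <- (lo + hi) / 2
    if (is.finite(trace_turning_depth(L, S, alpha, mid))) lo <- mid else hi <- mid
  }
  lo
}

# --- brute-force connected components of the <= L_c adjacency chain ------
brute_force_groups <- function(delays_mm, L_c_um) {
  n <- length(delays_mm)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (abs(delays_mm[i] - delays_mm[j]) * 1e3 <= L_c_um &&
            lab[j] != lab[i]) {
          lab[c(i, j)] <- min(lab[i], lab[j])
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(lab, unique(lab[order(delays_mm)]))
}

# --- least-squares sinusoid fit: independent single-tone amplitude oracle -
fit_tone_amplitude <- function(series, f_hz, f_cam) {
  t <- (seq_along(series) - 1) / f_cam
  X <- cbind(1, cos(2 * pi * f_hz * t), sin(2 * pi * f_hz * t))
  cf <- stats::lm.fit(X, series)$coefficients
  unname(sqrt(cf[2]^2 + cf[3]^2))
}

# --- small bin-aligned test scene -----------------------------------------
# 6 carriers at 1350..1400 Hz on a 3000 fps grid (window 0.1 s, 300
# samples): all carriers, their sums and differences are integer multiples
# of the bin, so discrete orthogonality is exact.
aligned_plan <- function(N = 6) make_plan(3000, 10, N, 1400)

aligned_scene <- function(N = 6, bead_channels = seq_len(N), z0_um = 2,
                          w_ls_um = 1.5, dof_scale = 50, brightness = 1) {
  plan <- aligned_plan(N)
  geom <- mirror_pair(200, 50, 1e-3, 0.998, dtheta_rad = N * 1e-3)
  vsa <- virtual_sources(geom)
  lsa <- light_sheet_array(vsa, z0_um = z0_um, w_ls_um = w_ls_um)
  d <- c(N + 2, 5, 4 * N + 2)
  vox <- c(z0_um, 1, 1)
  den <- array(0, d)
  for (k in bead_channels) den[k, 3, 4 * k] <- brightness
  ph <- phantom(den, vox)
  det <- detection_model(0.25, 590, dof_scale = dof_scale,
                         focal_plane_z_um = (N - 1) * z0_um / 2)
  cam <- camera_model(plan$f_cam)  # noiseless
  list(plan = plan, lsa = lsa, ph = ph, det = det, cam = cam,
       bead_pix = cbind(z = bead_channels, y = 3, x = 4 * bead_channels))
}
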