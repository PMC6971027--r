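# synthetic single-tone frame stack at pixel (y, x) on the aligned grid
tone_frames <- function(plan, channel, a = 2, b = 0.7, ny = 2, nx = 2,
                        n_windows = 1) {
  M <- round(plan$window_T * plan$f_cam) * n_windows
  t <- (0:(M - 1)) / plan$f_cam
  px <- a + b * cos(2 * pi * plan$freqs_hz[channel] * t)
  frames <- array(rep(px, ny * nx), c(M, ny, nx))
  list(frames = frames, frame_rate = plan$f_cam, duration_s = M / plan$f_cam)
}

test_that("matched-filter demodulation recovers single-tone amplitudes exactly", {
  plan <- aligned_plan(5)
  fs <- tone_frames(plan, channel = 3, a = 2, b = 0.7)
  spec <- stft_demodulate(fs, plan)
  amp <- spec$amplitudes[1, , 1, 1]
  expect_equal(amp[3], 0.7, tolerance = 1e-9)
  expect_lt(max(amp[-3]), 1e-6 * 0.7)   # leakage floor, DC rejected

  # constant (unmodulated) pixel: all channels ~0
  fs0 <- fs
  fs0$frames[] <- 5
  expect_lt(max(stft_demodulate(fs0, plan)$amplitudes), 1e-9)

  # linearity in the input brightness
  fs3 <- fs
  fs3$frames <- 3 * fs3$frames
  expect_equal(stft_demodulate(fs3, plan)$amplitudes, 3 * spec$amplitudes,
               tolerance = 1e-12)
})

test_that("demodulation emits one volume per window and guards resolution", {
  plan <- aligned_plan(4)
  fs <- tone_frames(plan, 2, n_windows = 3)
  spec <- stft_demodulate(fs, plan)
  expect_equal(dim(spec$amplitudes)[1], 3)
  expect_equal(spec$window_starts_s, c(0, 0.1, 0.2))

  short <- plan
  short$window_T <- plan$window_T / 2   # shorter than 1/delta_f
  expect_error(stft_demodulate(fs, short),
               class = "clam_frequency_resolution")
  tiny <- tone_frames(plan, 2)
  tiny$frames <- tiny$frames[1:100, , , drop = FALSE]
  expect_error(stft_demodulate(tiny, plan),
               class = "clam_frequency_resolution")
})

test_that("peak measurement: centre within 0.5 Hz, rect bandwidth 1.21/T", {
  plan <- make_plan(3183, 2.5, 1, 450)
  M <- round(0.4 * 3183)
  t <- (0:(M - 1)) / 3183
  fs <- list(frames = array(1 + 0.5 * cos(2 * pi * 450 * t), c(M, 2, 2)),
             frame_rate = 3183)
  pk <- peak_frequencies(fs, plan)
  expect_false(pk$missing)
  expect_equal(pk$f_centre_hz, 450, tolerance = 0.5 / 450)
  expect_equal(pk$bandwidth_hz, 1.21 / 0.4, tolerance = 0.05)

  # two tones one bin apart over exactly one bin-width window: resolved
  plan2 <- make_plan(3183, 13, 2, 463)
  M2 <- round(3 / 13 * 3183)
  t2 <- (0:(M2 - 1)) / 3183
  sig <- cos(2 * pi * 450 * t2) + cos(2 * pi * 463 * t2) + 2
  fs2 <- list(frames = array(sig, c(M2, 1, 1)), frame_rate = 3183)
  pk2 <- peak_frequencies(fs2, plan2)
  expect_equal(pk2$f_centre_hz, c(450, 463), tolerance = 1e-3)
})

test_that("depth calibration fits the line and survives depth jitter", {
  f <- seq(450, 750, length.out = 40)
  depth <- 0.23 * f - 100
  fit <- calibrate_depth(f, depth)
  expect_equal(fit$slope_beta_um_per_hz, 0.23, tolerance = 1e-9)
  expect_equal(fit$intercept_um, -100, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  withr::with_seed(3, {
    jit <- depth * (1 + rnorm(40, sd = 0.01))
    expect_gte(calibrate_depth(f, jit)$r_squared, 0.995)
  })
  expect_error(calibrate_depth(rep(450, 5), 1:5), class = "clam_singular_fit")
  expect_error(calibrate_depth(450, 5), class = "clam_singular_fit")
})

test_that("volume assembly orders by depth and boxcar-averages the z axis", {
  plan <- aligned_plan(5)
  amps <- array(0, c(1, 5, 2, 2))
  amps[1, 3, , ] <- 1   # impulse in channel 3
  spec <- structure(list(amplitudes = amps, channel_freqs_hz = plan$freqs_hz,
                         window_T = plan$window_T, window_starts_s = 0,
                         plan = plan),
                    class = "channel_spectrum")
  fit <- calibrate_depth(plan$freqs_hz, (0:4) * 2)

  ident <- assemble_volume(spec, fit, boxcar_width = 1)
  expect_equal(ident$volume[, 1, 1], c(0, 0, 1, 0, 0))
  expect_equal(ident$depth_axis_um, (0:4) * 2)

  sm <- assemble_volume(spec, fit, boxcar_width = 3)
  expect_equal(sm$volume[, 1, 1], c(0, 1 / 3, 1 / 3, 1 / 3, 0))
  expect_error(assemble_volume(spec, fit, boxcar_width = 2),
               class = "clam_parameter")

  # axial resolution cost is monotone: FWHM grows (or holds) under smoothing
  bead <- array(0, c(1, 9, 3, 3))
  bead[1, , 2, 2] <- gaussian_profile(0:8, 4, 2.2)
  spec2 <- structure(list(amplitudes = bead, channel_freqs_hz = 100 + 0:8,
                          window_T = 1, window_starts_s = 0),
                     class = "channel_spectrum")
  fit2 <- calibrate_depth(100 + 0:8, 0:8)
  w1 <- fwhm_interp(0:8, assemble_volume(spec2, fit2, 1)$volume[, 2, 2])
  w3 <- fwhm_interp(0:8, assemble_volume(spec2, fit2, 3)$volume[, 2, 2])
  expect_gte(w3, w1)
})

test_that("Richardson-Lucy sharpens, conserves flux and stays non-negative", {
  # delta kernel: identity at any iteration count
  delta <- array(0, c(3, 3, 3)); delta[2, 2, 2] <- 1
  vol <- array(runif(11 * 11 * 11), c(11, 11, 11))
  expect_equal(rl_deconvolve(vol, delta, iterations = 7), vol,
               tolerance = 1e-9)

  # Gaussian-blurred point: FWHM strictly decreases, flux within 1%
  psf1 <- gaussian_profile(-3:3, 0, 2.5); psf1 <- psf1 / sum(psf1)
  psf <- psf1 %o% psf1 %o% psf1
  pt <- array(0, c(15, 15, 15)); pt[8, 8, 8] <- 1
  blurred <- fft_convolve(pt, psf)
  dec <- rl_deconvolve(blurred, psf, iterations = 20)
  expect_lt(fwhm_interp(1:15, dec[, 8, 8]), fwhm_interp(1:15, blurred[, 8, 8]))
  expect_equal(sum(dec), sum(blurred), tolerance = 0.01)
  expect_gte(min(dec), 0)

  # non-negativity on arbitrary non-negative inputs
  withr::with_seed(9, {
    noisy <- array(rexp(15^3), c(15, 15, 15))
    expect_gte(min(rl_deconvolve(noisy, psf, iterations = 10)), 0)
  })
  expect_error(rl_deconvolve(vol, array(0, c(3, 3, 3))),
               class = "clam_normalization")
})

test_that("end-to-end: every well-separated bead lands in its own plane", {
  sc <- aligned_scene(N = 6, bead_channels = c(1, 3, 5))
  fs <- render_frames(sc$ph, sc$lsa, sc$plan, sc$det, sc$cam, 0.1)
  vols <- reconstruct(fs, sc$plan, config = list(boxcar_width = 1))
  expect_length(vols, 1)
  v <- vols[[1]]
  expect_equal(v$depth_axis_um, sc$lsa$depth_z_um)
  hits <- vapply(c(1, 3, 5), function(k) {
    which.max(v$volume[, 3, 4 * k]) == k
  }, logical(1))
  expect_true(all(hits))

  # cross-talk: energy two or more channels away stays below 1%
  sc1 <- aligned_scene(N = 6, bead_channels = 3)
  fs1 <- render_frames(sc1$ph, sc1$lsa, sc1$plan, sc1$det, sc1$cam, 0.1)
  v1 <- reconstruct(fs1, sc1$plan, config = list(boxcar_width = 1))[[1]]
  per_plane <- apply(v1$volume, 1, sum)
  expect_lt(max(per_plane[c(1, 5, 6)]) / per_plane[3], 0.01)

  # end-to-end linearity before deconvolution
  ph2 <- sc1$ph; ph2$density <- 4 * ph2$density
  fs4 <- render_frames(ph2, sc1$lsa, sc1$plan, sc1$det, sc1$cam, 0.1)
  v4 <- reconstruct(fs4, sc1$plan, config = list(boxcar_width = 1))[[1]]
  expect_equal(v4$volume, 4 * v1$volume, tolerance = 1e-9)

  # zero input, zero output
  fs0 <- fs1; fs0$frames[] <- 0
  expect_equal(max(reconstruct(fs0, sc1$plan)[[1]]$volume), 0)
})

test_that("reconstructed in-focus bead width matches the detection model", {
  sc <- aligned_scene(N = 4, bead_channels = 2, dof_scale = 50)
  fs <- render_frames(sc$ph, sc$lsa, sc$plan, sc$det, sc$cam, 0.1)
  v <- reconstruct(fs, sc$plan, config = list(boxcar_width = 1))[[1]]
  prof <- v$volume[2, 3, ]
  w <- fwhm_interp(seq_along(prof) * sc$ph$voxel_um[3], prof)
  expect_equal(w, sc$det$lateral_fwhm0_um, tolerance = 0.15)
})

test_that("reconstructed signal decays monotonically with penetration depth", {
  # one bead per sheet marching along +x through an attenuating medium
  N <- 5
  plan <- aligned_plan(N)
  vsa <- virtual_sources(mirror_pair(200, 50, 1e-3, 0.998, N * 1e-3))
  lsa <- light_sheet_array(vsa, z0_um = 2, w_ls_um = 1.5)
  d <- c(N + 2, 3, 100)
  den <- array(0, d)
  for (k in seq_len(N)) den[k, 2, 18 * k] <- 1
  ph <- phantom(den, c(2, 1, 2), scattering = list(mu_s_prime_cm = 60))
  det <- detection_model(0.25, 590, dof_scale = 50, focal_plane_z_um = 4)
  fs <- render_frames(ph, lsa, plan, det, camera_model(plan$f_cam), 0.1)
  v <- reconstruct(fs, plan, config = list(boxcar_width = 1))[[1]]
  peaks <- vapply(seq_len(N), function(k) max(v$volume[k, , ]), numeric(1))
  expect_true(all(diff(peaks) < 0))
})
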