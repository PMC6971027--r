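test_that("each sheet excites a Gaussian axial slab of the right width", {
  vsa <- virtual_sources(mirror_pair(200, 50, 1e-3, 0.998, 0.004))
  lsa <- light_sheet_array(vsa, z0_um = 6, w_ls_um = 3)
  ph <- phantom(array(0, c(60, 3, 3)), c(0.5, 1, 1))  # zero density is fine
  exc <- excitation_profiles(lsa, ph)
  expect_length(exc, 4)
  zax <- (0:59) * 0.5
  for (k in 1:4) {
    prof <- exc[[k]][, 2, 2]
    expect_equal(zax[which.max(prof)], lsa$depth_z_um[k], tolerance = 0.5)
    # sheet 1 sits at z = 0 where the grid cuts its lower half
    if (k > 1) expect_equal(fwhm_interp(zax, prof), 3, tolerance = 0.05)
  }
})

test_that("dense incoherent sheet arrays superpose into smooth illumination", {
  vsa <- virtual_sources(mirror_pair(200, 50, 1e-3, 0.998, 0.04))
  lsa <- light_sheet_array(vsa, z0_um = 1, w_ls_um = 1.5)
  ph <- phantom(array(0, c(200, 2, 2)), c(0.25, 1, 1))
  exc <- excitation_profiles(lsa, ph)
  total <- Reduce(`+`, exc)[, 1, 1]
  interior <- total[41:120]  # away from the array edges
  ripple <- (max(interior) - min(interior)) / mean(interior)
  expect_lt(ripple, 0.05)
})

test_that("Beer-Lambert attenuation follows exp(-mu_t x) along propagation", {
  vsa <- virtual_sources(mirror_pair(200, 50, 1e-3, 0.998, 0.001))
  lsa <- light_sheet_array(vsa, z0_um = 1, w_ls_um = 2)
  mu <- 22  # 1/cm
  ph <- phantom(array(0, c(3, 2, 50)), c(1, 1, 10),
                scattering = list(mu_s_prime_cm = mu))
  exc <- excitation_profiles(lsa, ph)[[1]]
  xax <- (0:49) * 10
  expect_equal(exc[1, 1, ] / exc[1, 1, 1], exp(-mu * 1e-4 * xax),
               tolerance = 1e-12)
})

test_that("speckle contrast is ~1 for one coherent group, ~1/sqrt(M) for M", {
  mk_lsa <- function(n) {
    vsa <- virtual_sources(mirror_pair(200, 50, 1e-3, 0.998, n * 1e-3))
    light_sheet_array(vsa, z0_um = 0.1, w_ls_um = 50)
  }
  ph <- phantom(array(0, c(1, 48, 48)), c(1, 1, 1),
                scattering = list(mu_s_prime_cm = 0.05))
  one <- excitation_profiles(mk_lsa(1), ph, mode = "coherent", seed = 11)
  c1 <- speckle_contrast(one[[1]])
  expect_gt(c1, 0.9)
  expect_lt(c1, 1.1)
  M <- 16
  many <- excitation_profiles(mk_lsa(M), ph, mode = "coherent", seed = 12)
  cM <- speckle_contrast(Reduce(`+`, many))
  expect_gt(cM, 0.8 / sqrt(M))
  expect_lt(cM, 1.2 / sqrt(M))
  # incoherent mode through the same scatterers stays smooth
  smooth <- excitation_profiles(mk_lsa(M), ph, mode = "incoherent")
  expect_lt(speckle_contrast(Reduce(`+`, smooth)), 0.05)
})

test_that("coherent mode without a scattering spec degrades with a warning", {
  vsa <- virtual_sources(mirror_pair(200, 50, 1e-3, 0.998, 0.001))
  lsa <- light_sheet_array(vsa, 1, 2)
  ph <- phantom(array(0, c(4, 40, 40)), 1)
  expect_warning(exc <- excitation_profiles(lsa, ph, mode = "coherent"),
                 class = "clam_no_scattering")
  expect_lt(speckle_contrast(exc[[1]][1, , ]), 1e-10)
})

test_that("a point source images to the PSF, linearly, with sqrt(2) defocus", {
  det <- detection_model(0.25, 590)  # diffraction limit: 1.2036 um FWHM
  vox <- c(1.5, 0.25, 0.25)
  d <- c(5, 81, 81)
  exc <- array(1, d)
  mk <- function(zi) {
    den <- array(0, d)
    den[zi, 41, 41] <- 1
    phantom(den, vox)
  }
  img0 <- emission_image(mk(1), exc, det)  # z = 0: in focus
  xax <- (0:80) * 0.25
  expect_equal(fwhm_interp(xax, img0[41, ]), det$lateral_fwhm0_um,
               tolerance = 0.02)
  expect_equal(fwhm_interp(xax, img0[, 41]), det$lateral_fwhm0_um,
               tolerance = 0.02)
  # one Rayleigh range off focus: sqrt(2) wider
  zi_r <- round(det$z_r_um / vox[1]) + 1
  expect_equal(det$z_r_um, 3.0, tolerance = 0.01)
  img_r <- emission_image(mk(zi_r), exc, det)
  expect_equal(fwhm_interp(xax, img_r[41, ]),
               sqrt(2) * det$lateral_fwhm0_um, tolerance = 0.03)
  # linearity
  ph2 <- mk(1)
  ph2$density <- 2 * ph2$density
  expect_equal(emission_image(ph2, exc, det), 2 * img0, tolerance = 1e-12)
  expect_error(emission_image(mk(1), array(1, c(2, 2, 2)), det),
               class = "clam_shape")
})

test_that("a larger dof_scale flattens the defocus curve, same in-focus width", {
  flat <- detection_model(0.25, 590, dof_scale = 2)
  steep <- detection_model(0.25, 590, dof_scale = 1)
  expect_equal(lateral_fwhm_at(flat, 0), lateral_fwhm_at(steep, 0))
  expect_lt(lateral_fwhm_at(flat, 5), lateral_fwhm_at(steep, 5))
})

test_that("noiseless pixel time series are pure tones at the sheet carrier", {
  # sheets spaced 3 um at 1 um thickness: neighbour excitation ~1e-11, so
  # each bead's pixel really carries a single tone
  sc <- aligned_scene(N = 4, bead_channels = c(1, 3), z0_um = 3, w_ls_um = 1)
  fs <- render_frames(sc$ph, sc$lsa, sc$plan, sc$det, sc$cam,
                      duration_s = sc$plan$window_T)
  expect_equal(dim(fs$frames)[1], 300)
  # bead 1's pixel: amplitude from the independent least-squares tone fit
  px <- fs$frames[, 3, 4]
  b_hat <- fit_tone_amplitude(px, sc$plan$freqs_hz[1], sc$plan$f_cam)
  spec <- stft_demodulate(fs, sc$plan)
  demod <- spec$amplitudes[1, , 3, 4]
  expect_equal(demod[1], b_hat, tolerance = 1e-6)
  # all channels not containing a bead stay at the leakage floor
  expect_lt(max(demod[c(2, 4)]), 1e-6 * demod[1])

  # two beads in different sheets: exactly two tones in the pixel spectra
  total <- apply(spec$amplitudes[1, , , ], 1, max)
  expect_identical(which(total > 1e-6 * max(total)), c(1L, 3L))
})

test_that("noiseless rendering is linear and time-averages to the DC image", {
  sc <- aligned_scene(N = 3)
  fs1 <- render_frames(sc$ph, sc$lsa, sc$plan, sc$det, sc$cam, 0.1)
  ph2 <- sc$ph
  ph2$density <- 2.5 * ph2$density
  fs2 <- render_frames(ph2, sc$lsa, sc$plan, sc$det, sc$cam, 0.1)
  expect_equal(fs2$frames, 2.5 * fs1$frames, tolerance = 1e-12)

  # carriers are zero-mean over the window: mean frame = sum of half images
  exc <- excitation_profiles(sc$lsa, sc$ph)
  dc <- Reduce(`+`, lapply(exc, function(e) {
    0.5 * emission_image(sc$ph, e, sc$det)
  }))
  mean_frame <- apply(fs1$frames, c(2, 3), mean)
  expect_equal(mean_frame, dc, tolerance = 1e-9)
})

test_that("zero phantoms render to the quantised read-noise floor", {
  sc <- aligned_scene(N = 2)
  ph0 <- phantom(array(0, dim(sc$ph$density)), sc$ph$voxel_um)
  cam <- camera_model(3000, photon_scale = 10, read_noise_sigma = 1.2,
                      rng_seed = 5)
  fs <- render_frames(ph0, sc$lsa, sc$plan, sc$det, cam, 0.1)
  expect_true(all(fs$frames == round(fs$frames)))
  expect_true(all(fs$frames >= 0))
  expect_lt(mean(fs$frames), 1)  # clipped half-normal floor
})

test_that("the camera noise chain is Poissonian and seed-deterministic", {
  vsa <- virtual_sources(mirror_pair(200, 50, 1e-3, 0.998, 0.001))
  lsa <- light_sheet_array(vsa, 1, 3)
  plan <- make_plan(3000, 50, 1, 1400)
  det <- detection_model(0.25, 590)
  ph <- phantom(array(1, c(1, 100, 100)), c(1, 0.5, 0.5))
  noiseless <- render_frames(ph, lsa, plan, det, camera_model(3000), 0.02)
  cam <- camera_model(3000, photon_scale = 2e5, read_noise_sigma = 0,
                      bit_depth = 16, rng_seed = 42)
  noisy <- render_frames(ph, lsa, plan, det, cam, 0.02)
  # interior pixels only: the blur's zero-padded edge makes lambda non-uniform
  lam <- noiseless$frames[1, 21:80, 21:80] * cam$photon_scale * cam$exposure_s
  counts <- noisy$frames[1, 21:80, 21:80]
  expect_equal(mean(counts), mean(lam), tolerance = 0.02)
  # Fano factor 1 within sampling error at 3600 pixels
  expect_equal(var(as.vector(counts)) / mean(counts), 1,
               tolerance = 3 * sqrt(2 / 3600) + 0.01)
  again <- render_frames(ph, lsa, plan, det, cam, 0.02)
  expect_identical(noisy$frames, again$frames)
})

test_that("flow advection conserves mass and composes over sub-steps", {
  den <- array(0, c(3, 3, 40))
  den[2, 2, 10:12] <- c(1, 2, 1)
  ph <- phantom(den, c(1, 1, 1), flow_velocity_um_s = 20)
  dt <- 1 / 13.2
  moved <- flow_update(ph, dt)
  expect_equal(sum(moved$density), sum(den), tolerance = 1e-3)
  com0 <- sum((1:40) * den[2, 2, ]) / sum(den[2, 2, ])
  com1 <- sum((1:40) * moved$density[2, 2, ]) / sum(moved$density[2, 2, ])
  expect_equal(com1 - com0, 20 * dt, tolerance = 1e-9)  # 1.52 um shift
  # identity at zero velocity
  ph0 <- phantom(den, c(1, 1, 1), flow_velocity_um_s = 0)
  expect_identical(flow_update(ph0, dt)$density, den)
  # two half steps == one full step (linear interpolation tolerance)
  half2 <- flow_update(flow_update(ph, dt / 2), dt / 2)
  expect_equal(half2$density, moved$density, tolerance = 0.35)
  expect_error(flow_update(phantom(den, 1), dt), class = "clam_invalid_spec")
})

test_that("photobleaching depends only on dose at gamma 1, not above", {
  f0 <- array(runif(27), c(3, 3, 3))
  exc <- array(2, c(3, 3, 3))
  expect_identical(photobleach_step(f0, exc, k_b = 0, gamma = 1, dt_s = 10), f0)
  # equal dose, gamma = 1: multiplexed (I, T) == scanned (N I, T / N)
  N <- 27
  clam_end <- photobleach_step(f0, exc, 0.3, 1, 1)
  sls_end <- photobleach_step(f0, N * exc, 0.3, 1, 1 / N)
  expect_equal(clam_end, sls_end, tolerance = 1e-12)
  # gamma = 2: scanned mode bleaches N^(gamma-1) = 27x faster
  cl2 <- photobleach_step(f0, exc, 1e-3, 2, 1)
  sl2 <- photobleach_step(f0, N * exc, 1e-3, 2, 1 / N)
  rate_ratio <- log(sl2 / f0) / log(cl2 / f0)
  expect_equal(unique(round(as.vector(rate_ratio), 6)), N)
  expect_error(photobleach_step(f0, exc, -1, 1, 1), class = "clam_domain")
})
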