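test_that("readout-time map hits its endpoints and inverts the trajectory", {
  p <- sequence_params(readout_duration = 5, ramp_fraction = 0.2)
  tmap <- kspace_time_map(p)
  expect_equal(tmap(0), 0)
  expect_equal(tmap(1), 5)
  ks <- seq(0.01, 0.99, length.out = 50)
  expect_true(all(diff(tmap(ks)) > 0))
  # continuity at the ramp junction
  expect_lt(abs(tmap(0.2 - 1e-9) - tmap(0.2 + 1e-9)), 1e-6)

  # oracle: numerically invert the forward trajectory k(t) (quadratic
  # ramp, then cube-root density-adapted regime with a C1 junction)
  k0 <- 0.2; Tr <- 5
  t0 <- 6 * k0^3 * Tr / (5 * k0^3 + 1)
  kfwd <- function(t) ifelse(t <= t0, k0 * (t / t0)^2,
                             (k0^3 + 6 * k0^3 / t0 * (t - t0))^(1 / 3))
  for (k in seq(0.05, 0.95, length.out = 20)) {
    t_num <- stats::uniroot(function(t) kfwd(t) - k, c(0, Tr),
                            tol = 1e-13)$root
    expect_lt(abs(tmap(k) - t_num), 1e-9)
  }
  expect_error(sequence_params(ramp_fraction = 1.2), "ramp_fraction")
})

test_that("k-space weighting matches the biexponential closed form", {
  p <- sequence_params()
  # no decay, no apodization: w identically 1
  w1 <- kspace_weighting(relaxation_times(1e12, 1e12, 1e12, 0.6), p, "none")
  expect_equal(w1(seq(0, 1, 0.1)), rep(1, 11), tolerance = 1e-9)
  # Hanning window endpoints in the no-decay limit
  wh <- kspace_weighting(relaxation_times(1e12, 1e12, 1e12, 0.6), p,
                         "hanning")
  expect_equal(wh(0), 1, tolerance = 1e-9)
  expect_equal(wh(1), 0, tolerance = 1e-12)
  # MID tissue at a fixed readout time: direct biexponential evaluation
  mid <- relaxation_times(19.2, 14.2, 1.4, 0.6)
  w <- kspace_weighting(mid, p, "none")
  tmap <- kspace_time_map(p)
  k_at <- stats::uniroot(function(k) tmap(k) - 2.5, c(0, 1),
                         tol = 1e-14)$root
  t <- 0.1 + 2.5
  expect_equal(w(k_at),
               0.6 * exp(-t / 1.4) + 0.4 * exp(-t / 14.2),
               tolerance = 1e-12)
  # weight is positive and non-increasing
  ks <- seq(0, 1, length.out = 100)
  expect_true(all(w(ks) > 0))
  expect_true(all(diff(w(ks)) <= 1e-12))
})

test_that("simulated PSF is unit-gain, centered, isotropic and matches the analytic ball transform", {
  p <- sequence_params()
  nodecay <- relaxation_times(1e12, 1e12, 1e12, 0.6)
  psf <- simulate_psf(nodecay, p, "none", kernel_halfwidth = 10,
                      grid_size = 128)
  v <- psf$values
  ctr <- 11L
  expect_equal(sum(v), 1, tolerance = 1e-6)
  expect_equal(which.max(v), ((ctr - 1L) * 21L + ctr - 1L) * 21L + ctr)
  # isotropy: same-radius voxels across octahedral orbits
  pk <- v[ctr, ctr, ctr]
  r5 <- c(v[ctr + 5, ctr, ctr], v[ctr, ctr + 5, ctr], v[ctr, ctr, ctr + 5],
          v[ctr + 3, ctr + 4, ctr], v[ctr, ctr - 3, ctr - 4],
          v[ctr - 5, ctr, ctr])
  expect_lt((max(r5) - min(r5)) / pk, 1e-3)
  # central profile against the analytic transform of the k-space ball
  kmax <- 1 / (2 * p$nominal_resolution)
  prof <- v[ctr:(ctr + 10), ctr, ctr] / pk
  oracle <- ball_transform_oracle((0:10) * p$nominal_resolution, kmax)
  expect_lt(max(abs(prof - oracle)), 0.01)
  # FWHM close to the analytic value, measured identically on both
  fw_num <- psf_fwhm(psf)
  r <- seq(0, 4, by = 1e-4)
  fw_an <- 2 * r[which(ball_transform_oracle(r, kmax) <= 0.5)[1]]
  expect_lt(abs(fw_num - fw_an) / fw_an, 0.05)
})

test_that("PSF broadens monotonically as the short T2* component shortens", {
  p <- sequence_params()
  # monoexponential regime (fs = 1): T2s* alone controls the decay and
  # the half-maximum width shrinks monotonically as T2s* grows
  fw1 <- vapply(c(0.4, 1.4, 6, 14, 28), function(t2s)
    psf_fwhm(simulate_psf(relaxation_times(19.2, 28, t2s, 1), p,
                          "hanning", 10, grid_size = 128)), 0)
  expect_true(all(diff(fw1) < 0))
  # biexponential mixture: monotone over the physiological range; at
  # ultrashort T2s* the short component degenerates into a flat
  # pedestal below half maximum and FWHM is no longer a faithful
  # broadening metric
  fw6 <- vapply(c(1.4, 6, 14, 28), function(t2s)
    psf_fwhm(simulate_psf(relaxation_times(19.2, 28, t2s, 0.6), p,
                          "hanning", 10, grid_size = 128)), 0)
  expect_true(all(diff(fw6) <= 1e-9))
})

test_that("kernel truncation is detected and convolution with an impulse reproduces the kernel", {
  p <- sequence_params()
  nodecay <- relaxation_times(1e12, 1e12, 1e12, 0.6)
  # sinc-like tails of the undamped PSF exceed any small window
  psf <- simulate_psf(nodecay, p, "none", kernel_halfwidth = 5,
                      grid_size = 128)
  expect_true(psf$truncated)
  expect_lt(psf$coverage, 0.99)
  # convolution identity on an impulse volume
  mid <- simulate_psf(relaxation_times(19.2, 14.2, 1.4, 0.6), p, "hanning",
                      5, grid_size = 128)
  imp <- array(0, dim = c(21, 21, 21)); imp[11, 11, 11] <- 1
  out <- conv3d(imp, mid)
  expect_equal(out[6:16, 6:16, 6:16], mid$values, tolerance = 1e-10)
})

test_that("mixed-voxel relaxation averages tissue parameters arithmetically", {
  mid <- relaxation_times(19.2, 14.2, 1.4, 0.6)
  fat <- relaxation_times(25.2, 14.3, 1.4, 0.6)
  mix <- mixed_voxel_relaxation(list(mid, fat))
  expect_equal(mix$T1, 22.2)
  expect_equal(mix$T2l, 14.25)
  expect_equal(mix$T2s, 1.4)
  expect_equal(mix$fs, 0.6)
  # single tissue and ties are identity
  expect_equal(mixed_voxel_relaxation(list(mid)), mid)
  expect_equal(mixed_voxel_relaxation(list(fat, fat, fat)), fat)
  expect_error(mixed_voxel_relaxation(list()), "at least one")
  # monoexponential tissue: T2s collapses onto T2l with fs 0
  fluid <- relaxation_times(62, 28, NA)
  expect_equal(fluid$fs, 0)
  expect_equal(fluid$T2s, 28)
})

test_that("surround PSF equals the PSF of the mean surrounding tissue", {
  p <- sequence_params()
  skin <- relaxation_times(27, 7.6, 0.5, 0.6)
  fat <- relaxation_times(25.2, 14.3, 1.4, 0.6)
  muscle <- relaxation_times(25.2, 14.3, 1.4, 0.6)
  sp <- surround_psf(list(skin, fat, muscle), p, kernel_halfwidth = 5,
                     grid_size = 96)
  direct <- simulate_psf(relaxation_times((27 + 25.2 + 25.2) / 3,
                                          (7.6 + 14.3 + 14.3) / 3,
                                          (0.5 + 1.4 + 1.4) / 3, 0.6),
                         p, kernel_halfwidth = 5, grid_size = 96)
  expect_equal(sp$values, direct$values, tolerance = 1e-12)
  one <- surround_psf(list(skin), p, kernel_halfwidth = 5, grid_size = 96)
  skin_psf <- simulate_psf(skin, p, kernel_halfwidth = 5, grid_size = 96)
  expect_equal(one$values, skin_psf$values, tolerance = 1e-12)
})
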