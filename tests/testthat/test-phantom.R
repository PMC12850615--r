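test_that("phantom assigns the reference tissue concentrations", {
  bundle <- small_bundle()
  gt <- bundle$ground_truth$values
  lab <- bundle$labels$labels
  conc_of <- function(l) unique(gt[lab == l])
  expect_equal(conc_of(1), 25)     # INS
  expect_equal(conc_of(2), 15)     # MID
  expect_equal(conc_of(3), 18)     # MTJ
  expect_equal(conc_of(4), 30)     # INS tip
  expect_equal(conc_of(5), 18)     # MID spot
  expect_equal(conc_of(6), 14)     # MTJ spot
  expect_equal(conc_of(7), 34.2)   # skin
  expect_equal(conc_of(11), 81)    # blood
  expect_equal(conc_of(12), 0)     # calcaneus: sodium-free bone
  expect_equal(sort(vapply(20:23, conc_of, 0)), c(50, 75, 100, 125))
})

test_that("tendon sections are 30 mm long and the geometry is deterministic", {
  bundle <- small_bundle()
  lab <- bundle$labels$labels
  zs <- function(ls) range(which(apply(array(lab %in% ls, dim = dim(lab)),
                                       3, any)))
  z_ins <- zs(c(1, 4)); z_mid <- zs(2); z_mtj <- zs(c(3, 6))
  expect_equal(diff(z_ins) + 1, 30)
  expect_equal(diff(z_mid) + 1, 30)
  expect_equal(diff(z_mtj) + 1, 30)
  expect_equal(z_mid[1], z_ins[2] + 1)
  expect_equal(z_mtj[1], z_mid[2] + 1)
  # MID spot lies inside the MID band, MTJ spot inside the MTJ band
  expect_true(all(which(apply(array(lab == 5, dim = dim(lab)), 3, any)) %in%
                    z_mid[1]:z_mid[2]))
  # regeneration is bit-identical
  again <- generate_phantom(phantom_geometry(preset = "small"))
  expect_identical(again$labels$labels, lab)
  expect_identical(again$ground_truth$values, bundle$ground_truth$values)
})

test_that("impossible geometry is rejected with the region name", {
  expect_error(generate_phantom(phantom_geometry(preset = "small",
                                                 ref_x = -20)),
               "ref_50")
  expect_error(generate_phantom(phantom_geometry(preset = "small",
                                                 bursa_center = c(10, 48, 24))),
               "bursa")
  expect_error(phantom_geometry(grid_size = 32), "too small")
  expect_error(phantom_geometry(nonsense = 1), "unknown geometry")
})

test_that("relaxation weighting follows the saturation-decay closed form", {
  mid <- relaxation_times(19.2, 14.2, 1.4, 0.6)
  w <- relaxation_weight(mid, TR = 15, TE = 0.1)
  oracle <- (1 - exp(-15 / 19.2)) *
    (0.6 * exp(-0.1 / 1.4) + 0.4 * exp(-0.1 / 14.2))
  expect_equal(w, oracle, tolerance = 1e-12)
  # fully relaxed, no decay
  expect_equal(relaxation_weight(mid, TR = 1e12, TE = 0), 1)
  # degenerate fraction: pure long component
  mono <- relaxation_times(19.2, 14.2, 1.4, 0)
  expect_equal(relaxation_weight(mono, 15, 0.1),
               (1 - exp(-15 / 19.2)) * exp(-0.1 / 14.2), tolerance = 1e-12)
  expect_error(relaxation_weight(mid, TR = -1, TE = 0), "positive")
})

test_that("coil sensitivity decays exponentially from the coil plane", {
  geom <- phantom_geometry(preset = "small")
  s <- make_sensitivity(geom)
  x <- (seq_len(96) - 1)
  prof <- s$values[, 48, 48]
  expect_equal(prof[x == geom$coil_plane_x], 1)
  expect_equal(prof[x == geom$coil_plane_x + geom$sens_d0], exp(-1),
               tolerance = 1e-12)
  beyond <- prof[x > geom$coil_plane_x]
  expect_true(all(diff(beyond) < 0))
})

test_that("sensitivity application is a voxel-wise product on a shared grid", {
  v <- array(runif(4^3), dim = c(4, 4, 4))
  expect_equal(apply_sensitivity(v, array(1, dim = c(4, 4, 4))), v)
  # a uniform half-sensitivity field halves every value
  expect_equal(apply_sensitivity(v, array(0.5, dim = c(4, 4, 4))), v / 2,
               tolerance = 1e-12)
  s <- array(runif(4^3, 0.2, 1), dim = c(4, 4, 4))
  expect_equal(apply_sensitivity(v, s), v * s, tolerance = 1e-12)
  # un-normalized fields (max > 1) are normalized to max 1 first
  expect_equal(apply_sensitivity(v, 4 * s), v * s / max(s),
               tolerance = 1e-12)
  expect_error(apply_sensitivity(v, array(1, dim = c(3, 3, 3))),
               "do not match")
})

test_that("Rician noise delivers the target SNR and Rayleigh background", {
  v <- array(0, dim = c(40, 40, 40))
  v[15:25, 15:25, 15:25] <- 10
  roi <- v > 0
  out <- add_rician_noise(v, 10, roi, seed = 5)
  expect_equal(out$sigma, 1)
  # zero-signal background is Rayleigh: mean = sigma * sqrt(pi/2)
  bg <- out$volume[1:10, , ]
  nbg <- length(bg)
  expect_gt(nbg, 1e4)
  se <- out$sigma * sqrt((4 - pi) / 2) / sqrt(nbg)
  expect_lt(abs(mean(bg) - out$sigma * sqrt(pi / 2)), 3 * se)
  # determinism and infinite-SNR identity
  again <- add_rician_noise(v, 10, roi, seed = 5)
  expect_identical(out$volume, again$volume)
  expect_identical(add_rician_noise(v, Inf, roi)$volume, v)
  expect_error(add_rician_noise(v, 10, array(FALSE, dim = dim(v))), "empty")
})

test_that("spill-over forward model is a per-group convolution", {
  set.seed(21)
  n <- 12
  v <- array(runif(n^3), dim = c(n, n, n))
  key <- array(1L, dim = c(n, n, n)); key[7:12, , ] <- 2L
  k1 <- array(0, dim = c(3, 3, 3)); k1[2, 2, 2] <- 1
  k2 <- array(1, dim = c(3, 3, 3)) / 27
  psfs <- list(raw_psf_kernel(k1), raw_psf_kernel(k2))
  # impulse PSFs: identity
  got_id <- spillover_forward(v, key, list(raw_psf_kernel(k1),
                                           raw_psf_kernel(k1)))
  expect_equal(got_id, v, tolerance = 1e-10)
  # two groups: equals the sum of two masked brute-force convolutions
  got <- spillover_forward(v, key, psfs)
  v1 <- v; v1[key != 1L] <- 0
  v2 <- v; v2[key != 2L] <- 0
  want <- conv3d_bruteforce(v1, k1) + conv3d_bruteforce(v2, k2)
  expect_equal(got, want, tolerance = 1e-9)
  # linearity
  w <- array(runif(n^3), dim = c(n, n, n))
  lhs <- spillover_forward(2 * v + 3 * w, key, psfs)
  rhs <- 2 * spillover_forward(v, key, psfs) +
    3 * spillover_forward(w, key, psfs)
  expect_lt(max(abs(lhs - rhs)), 1e-9)
  expect_error(spillover_forward(v, key, psfs[1]), "missing PSF")
})

test_that("mixed-label grouping keys coarse voxels by their tissue content", {
  lab <- array(0L, dim = c(4, 4, 4))
  lab[1:2, , ] <- 1L; lab[3, , ] <- 1L; lab[4, , ] <- 2L
  tt <- tissue_table()
  g <- mixed_label_groups(lab, 2, tt)
  expect_equal(dim(g$key), c(2L, 2L, 2L))
  expect_equal(g$combos[[g$key[1, 1, 1]]], 1L)          # pure tissue 1
  expect_equal(g$combos[[g$key[2, 1, 1]]], c(1L, 2L))   # straddling voxel
  # sodium-free bone never contributes to the grouping
  lab2 <- lab
  lab2[3, , ] <- 12L   # calcaneus
  g2 <- mixed_label_groups(lab2, 2, tt)
  expect_equal(g2$combos[[g2$key[2, 1, 1]]], 2L)
})

test_that("acquisition chain is deterministic and collapses to a block mean when every corruption is off", {
  bundle <- small_bundle()
  params <- sequence_params(TR = 1e9, TE = 0)
  ones <- volume_grid(array(1, dim = dim(bundle$ground_truth$values)), 1)
  g2 <- cache_get("groups_f2", function()
    mixed_label_groups(bundle$labels, 2, bundle$tissues))
  bank_imp <- rep(list(impulse_psf(1, 2)), length(g2$combos))
  acq <- simulate_acquisition(bundle, params, resolution_factor = 2,
                              target_snr = Inf, sensitivity = ones,
                              psf_bank = bank_imp, groups = g2)
  want <- block_downsample(bundle$ground_truth, 2)
  expect_equal(acq$native$values, want$values, tolerance = 1e-9)
  # determinism under a fixed seed
  acq1 <- simulate_acquisition(bundle, params, resolution_factor = 2,
                               target_snr = 8, sensitivity = ones,
                               psf_bank = bank_imp, groups = g2, seed = 33)
  acq2 <- simulate_acquisition(bundle, params, resolution_factor = 2,
                               target_snr = 8, sensitivity = ones,
                               psf_bank = bank_imp, groups = g2, seed = 33)
  expect_identical(acq1$native$values, acq2$native$values)
})

test_that("corruption order is pinned: sensitivity before noise matters", {
  bundle <- small_bundle()
  g2 <- cache_get("groups_f2", function()
    mixed_label_groups(bundle$labels, 2, bundle$tissues))
  bank_imp <- rep(list(impulse_psf(1, 2)), length(g2$combos))
  sens <- make_sensitivity(bundle$geometry)
  acq <- simulate_acquisition(bundle, sequence_params(),
                              resolution_factor = 2, target_snr = 10,
                              sensitivity = sens, psf_bank = bank_imp,
                              groups = g2, seed = 12)
  # swapped order: noise added to the sensitivity-free image, then
  # sensitivity applied — a different (wrong) corruption chain
  ones <- volume_grid(array(1, dim = dim(bundle$ground_truth$values)), 1)
  acq_nosens <- simulate_acquisition(bundle, sequence_params(),
                                     resolution_factor = 2, target_snr = 10,
                                     sensitivity = ones, psf_bank = bank_imp,
                                     groups = g2, seed = 12)
  swapped <- apply_sensitivity(acq_nosens$native,
                               block_downsample(sens, 2))
  expect_gt(max(abs(swapped$values - acq$native$values)), 0.01)
})
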