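test_that("sensitivity correction inverts the coil weighting", {
  v <- array(runif(6^3, 1, 2), dim = c(6, 6, 6))
  ones <- array(1, dim = c(6, 6, 6))
  expect_equal(sensitivity_correct(v, ones)$volume, v)
  s <- array(runif(6^3, 0.3, 1), dim = c(6, 6, 6))
  weighted <- vol_values(apply_sensitivity(v, s))
  back <- sensitivity_correct(weighted, s)$volume
  expect_equal(back, v, tolerance = 1e-9)
  # deep voxels below the floor are flagged
  s2 <- s; s2[1, 1, 1] <- 0.01
  sc <- sensitivity_correct(v, s2, floor = 0.05)
  expect_true(sc$flagged[1, 1, 1])
  expect_false(sc$flagged[3, 3, 3])
  expect_error(sensitivity_correct(v, ones * 0.01), "below the floor")
})

test_that("relaxation correction is the exact inverse of the weighting", {
  agar <- relaxation_times(38.5, 13.0, 6.0, 0.6)
  sig <- 42
  w <- relaxation_weight(agar, 15, 0.1)
  expect_equal(relaxation_correct(sig * w, agar, 15, 0.1), sig,
               tolerance = 1e-12)
  oracle <- sig / ((1 - exp(-15 / 38.5)) *
                     (0.6 * exp(-0.1 / 6) + 0.4 * exp(-0.1 / 13)))
  expect_equal(relaxation_correct(sig, agar, 15, 0.1), oracle,
               tolerance = 1e-12)
  # fully relaxed regime: identity
  expect_equal(relaxation_correct(sig, agar, 1e12, 0), sig)
})

test_that("calibration fits the reference line and inverts to concentration", {
  concs <- c(50, 75, 100, 125)
  fit <- calibrate(0.31 * concs, concs)
  expect_equal(fit$slope, 0.31, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  expect_equal(fit$residual_norm, 0, tolerance = 1e-10)
  fit2 <- calibrate(0.31 * concs + 2, concs)
  expect_equal(fit2$intercept, 2, tolerance = 1e-10)
  # noisy signals against the normal-equations oracle
  set.seed(4)
  y <- 0.3 * concs + rnorm(4, 0, 0.5)
  fit3 <- calibrate(y, concs)
  X <- cbind(1, concs)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit3$intercept, beta[1], tolerance = 1e-9)
  expect_equal(fit3$slope, beta[2], tolerance = 1e-9)
  expect_error(calibrate(c(1, 2), c(50, 50)), "distinct")
  # inversion
  expect_equal(to_atsc(0.31 * 80, fit), 80, tolerance = 1e-9)
  expect_equal(to_atsc(fit2$intercept, fit2), 0, tolerance = 1e-9)
  m <- array(0.31 * c(10, 20, 30, 40), dim = c(2, 2, 1))
  expect_equal(to_atsc(m, fit), m / 0.31, tolerance = 1e-9)
  expect_warning(to_atsc(-1, fit), "negative")
  bad <- fit; bad$slope <- -1
  expect_error(to_atsc(5, bad), "positive")
})

test_that("under-reading the references inflates aTSC by the inverse factor", {
  concs <- c(50, 75, 100, 125)
  fit_true <- calibrate(0.4 * concs, concs)
  fit_low <- calibrate(0.8 * 0.4 * concs, concs)  # 20% under-read, zero intercept
  sig <- 0.4 * 90
  expect_equal(to_atsc(sig, fit_low) / to_atsc(sig, fit_true), 1 / 0.8,
               tolerance = 1e-9)
})

test_that("region-wise map scaling preserves the corrected mean and the pattern", {
  set.seed(6)
  img <- array(runif(6^3, 5, 10), dim = c(6, 6, 6))
  roi <- array(FALSE, dim = c(6, 6, 6)); roi[2:4, 2:4, 2:4] <- TRUE
  u <- mean(img[roi])
  out <- regionwise_map(img, roi, corrected_mean = 0.5 * u,
                        uncorrected_mean = u)
  expect_equal(mean(vol_values(out)[roi]), 0.5 * u, tolerance = 1e-12)
  expect_equal(vol_values(out)[roi] / img[roi],
               rep(0.5, sum(roi)), tolerance = 1e-12)
  expect_equal(vol_values(out)[!roi], img[!roi])
  expect_identical(regionwise_map(img, roi, u, u), img)
  expect_error(regionwise_map(img, roi, 1, 0), "zero")
})

test_that("ROI statistics report section means and a signal-level combined value", {
  d <- c(6, 6, 6)
  sections <- list(INS = array(FALSE, d), MID = array(FALSE, d),
                   MTJ = array(FALSE, d))
  sections$INS[1:2, , 1] <- TRUE
  sections$MID[1:2, , 2] <- TRUE
  sections$MTJ[1:2, , 3] <- TRUE
  sections$AT <- sections$INS | sections$MID | sections$MTJ
  m <- array(NA_real_, d)
  m[sections$INS] <- 25; m[sections$MID] <- 15; m[sections$MTJ] <- 18
  rep_ <- roi_statistics(m, sections, combined = 19.7)
  expect_equal(rep_$mean_mM[rep_$roi == "MID"], 15)
  expect_equal(rep_$sd_mM[rep_$roi == "MID"], 0)
  expect_equal(rep_$mean_mM[rep_$roi == "combined"], 19.7)
  # the combined value is not the average of the section means
  expect_false(isTRUE(all.equal(19.7, mean(c(25, 15, 18)))))
  expect_error(roi_statistics(m, sections[c("INS", "MID")]), "MTJ")
})

test_that("correction order is pinned: PVC before sensitivity correction", {
  # a region-level correction computed on the raw image differs from
  # one computed after sensitivity division when the coil profile is
  # non-uniform across the surroundings
  set.seed(13)
  img <- array(runif(8^3, 5, 6), dim = c(8, 8, 8))
  sens <- array(rep(seq(1, 0.3, length.out = 8), each = 1), dim = c(8, 8, 8))
  roi <- array(FALSE, dim = c(8, 8, 8)); roi[4:5, 4:5, 4:5] <- TRUE
  correct_region <- function(im) {
    S_m <- mean(im[roi])
    pssr_correct(S_m, surrounding_mean(im, roi), 0.8) / S_m
  }
  ratio_pvc_first <- correct_region(img)
  ratio_sens_first <- correct_region(vol_values(
    sensitivity_correct(img, sens)$volume))
  expect_gt(abs(ratio_pvc_first - ratio_sens_first), 1e-6)
})
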