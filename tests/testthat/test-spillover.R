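test_that("region spread functions behave as mask convolutions", {
  m <- array(FALSE, dim = c(12, 12, 12)); m[4:8, 4:8, 4:8] <- TRUE
  # impulse PSF: RSF equals the mask
  expect_equal(build_rsf(m, impulse_psf(1, 1)), array(as.numeric(m),
                                                      dim = dim(m)),
               tolerance = 1e-10)
  # whole-grid mask with a unit-gain kernel: ~1 away from the boundary
  full <- array(TRUE, dim = c(12, 12, 12))
  k <- array(1, dim = c(3, 3, 3)) / 27
  r <- build_rsf(full, raw_psf_kernel(k))
  expect_lt(max(abs(r[3:10, 3:10, 3:10] - 1)), 1e-10)
  # small mask against the brute-force convolution oracle
  set.seed(2)
  kg <- array(exp(-rnorm(27)^2), dim = c(3, 3, 3)); kg <- kg / sum(kg)
  expect_equal(build_rsf(m, raw_psf_kernel(kg)),
               conv3d_bruteforce(array(as.numeric(m), dim = dim(m)), kg),
               tolerance = 1e-9)
  # masked variant restricts to the compartment
  rm_ <- build_rsf(m, raw_psf_kernel(kg), masked = TRUE)
  expect_true(all(rm_[!m] == 0))
  expect_error(build_rsf(m, raw_psf_kernel(kg * 2)), "not normalized")
})

test_that("partition of unity: tiling masks with a shared unit-gain PSF give R = 1", {
  n <- 32
  masks <- list(a = array(FALSE, dim = c(n, n, n)),
                b = array(FALSE, dim = c(n, n, n)),
                c = array(FALSE, dim = c(n, n, n)))
  masks$a[1:10, , ] <- TRUE
  masks$b[11:22, , ] <- TRUE
  masks$c[23:32, , ] <- TRUE
  psf <- simulate_psf(relaxation_times(19.2, 14.2, 1.4, 0.6),
                      sequence_params(), "hanning", 5, grid_size = 96)
  cs <- compartment_set(masks, psf)
  hw <- 5
  interior <- (hw + 1):(n - hw)
  # full-field RSFs: their sum is the blurred all-ones field, 1 in the
  # interior by linearity
  rsf_sum <- Reduce(`+`, cs$rsf_full)
  expect_lt(max(abs(rsf_sum[interior, interior, interior] - 1)), 1e-3)
  # the masked recovery factor agrees away from compartment interfaces
  # (interfaces lose the cross-compartment share by construction)
  core <- Reduce(`|`, lapply(cs$masks, erode_mask, depth = hw))
  core[-interior, , ] <- FALSE; core[, -interior, ] <- FALSE
  core[, , -interior] <- FALSE
  expect_lt(max(abs(cs$recovery[core] - 1)), 1e-3)
  expect_error(compartment_set(list(a = masks$a, b = masks$a), psf),
               "overlap")
})

test_that("GTM recovers piecewise-constant compartment values by matrix inversion", {
  fx <- two_compartment_fixture()
  # impulse PSFs: W is the identity, corrected means equal measured means
  imp <- compartment_set(list(target = fx$tar, surround = fx$sur),
                         impulse_psf(1, 2), surround = "surround")
  v <- 7 * fx$tar + 3 * fx$sur
  g0 <- gtm_correct(v, imp)
  expect_equal(unname(g0$means), unname(g0$measured), tolerance = 1e-9)
  # blurred fixture: exact recovery (the GTM model is exact here)
  g <- gtm_correct(fx$img, fx$cs)
  expect_lt(abs(g$means["target"] - fx$c_t) / fx$c_t, 1e-6)
  expect_lt(abs(g$means["surround"] - fx$c_s) / fx$c_s, 1e-6)
  # duplicate compartments make W singular
  dup <- compartment_set(list(a = fx$tar, b = fx$tar),
                         fx$psf_t, validate = FALSE)
  expect_error(gtm_correct(fx$img, dup), "ill-conditioned")
})

test_that("STC converges on the blurred fixture and recovers the target mean", {
  fx <- two_compartment_fixture()
  s <- stc_correct(fx$img, fx$cs, tol = 1e-4, max_iter = 100)
  expect_true(s$converged)
  expect_lt(s$iterations, 100)
  expect_lt(abs(s$means["target"] - fx$c_t) / fx$c_t, 0.01)
  # impulse PSFs converge immediately to the input
  imp <- compartment_set(list(target = fx$tar, surround = fx$sur),
                         impulse_psf(1, 2), surround = "surround")
  v <- 7 * fx$tar + 3 * fx$sur
  si <- stc_correct(v, imp)
  expect_equal(si$iterations, 1L)
  expect_equal(si$corrected, v, tolerance = 1e-9)
})

test_that("STC reports a period-2 steady state with both states", {
  # kernel concentrated on the slab-normal axis: cross-spill exceeds
  # retention and the iteration locks into a two-state cycle
  k <- array(0, dim = c(3, 3, 3))
  k[2, 2, 2] <- 0.34; k[1, 2, 2] <- 0.33; k[3, 2, 2] <- 0.33
  n <- 12
  tar <- array(FALSE, dim = c(n, n, n)); tar[6, 4:9, 4:9] <- TRUE
  sur <- array(FALSE, dim = c(n, n, n)); sur[7, 4:9, 4:9] <- TRUE
  cs <- compartment_set(list(target = tar, surround = sur),
                        raw_psf_kernel(k), surround = "surround")
  s <- suppressWarnings(stc_correct(10 * tar + 20 * sur, cs,
                                    max_iter = 300))
  expect_false(s$converged)
  expect_true(s$oscillation)
  expect_length(s$states, 2)
  expect_gt(max(abs(s$states[[1]] - s$states[[2]])), 1e-3)
  # the reported image is the mean of the two states
  expect_equal(s$corrected, (s$states[[1]] + s$states[[2]]) / 2,
               tolerance = 1e-12)
})

test_that("erode-and-fill replaces edge voxels from the interior", {
  m <- array(FALSE, dim = c(9, 9, 9)); m[3:7, 3:7, 3:7] <- TRUE
  v <- array(0, dim = c(9, 9, 9))
  v[m] <- 5
  v[3, 3:7, 3:7] <- 50    # overestimated edge face
  ef <- erode_and_fill(v, m, 1)
  expect_false(ef$fallback)
  expect_equal(ef$values[3, 5, 5], 5)      # refilled from the core
  expect_equal(ef$values[5, 5, 5], 5)      # interior untouched
  expect_equal(ef$values[1, 1, 1], 0)      # outside the mask untouched
  # constant volumes are unchanged
  cst <- array(2, dim = c(9, 9, 9))
  expect_equal(erode_and_fill(cst, m)$values, cst)
  # erosion that empties the mask falls back to the uneroded values
  thin <- array(FALSE, dim = c(9, 9, 9)); thin[5, 3:7, 3:7] <- TRUE
  ef2 <- erode_and_fill(v, thin, 1)
  expect_true(ef2$fallback)
  expect_equal(ef2$values, v)
  expect_error(erode_and_fill(v, array(FALSE, dim = c(9, 9, 9))), "empty")
  # nearest-survivor assignment agrees with a brute-force distance scan
  set.seed(7)
  vr <- array(rnorm(9^3), dim = c(9, 9, 9))
  ef3 <- erode_and_fill(vr, m, 1)
  core <- erode_mask(m, 1)
  cw <- which(core, arr.ind = TRUE)
  lost <- which(m & !core, arr.ind = TRUE)
  for (q in sample(nrow(lost), 10)) {
    p <- lost[q, ]
    d2 <- (cw[, 1] - p[1])^2 + (cw[, 2] - p[2])^2 + (cw[, 3] - p[3])^2
    lin <- (cw[, 3] - 1) * 81 + (cw[, 2] - 1) * 9 + cw[, 1]
    best <- order(d2, lin)[1]
    expect_equal(ef3$values[p[1], p[2], p[3]], vr[lin[best]])
  }
})

test_that("eSTC corrects in a single sweep and is stable under a second sweep", {
  fx <- two_compartment_fixture()
  e <- estc_correct(fx$img, fx$cs)
  expect_lt(abs(e$means["target"] - fx$c_t) / fx$c_t, 0.01)
  s <- stc_correct(fx$img, fx$cs)
  # no worse than the iterative correction on the same fixture
  expect_lte(abs(e$means["target"] - fx$c_t),
             abs(s$means["target"] - fx$c_t) + 0.01 * fx$c_t)
  e2 <- estc_correct(fx$img, fx$cs, sweeps = 2)
  expect_lt(max(abs(e2$means - e$means) / abs(e$means)), 0.005)
  # determinism
  expect_identical(e$corrected, estc_correct(fx$img, fx$cs)$corrected)
  # impulse PSFs: exact identity on the compartments
  imp <- compartment_set(list(target = fx$tar, surround = fx$sur),
                         impulse_psf(1, 2), surround = "surround")
  v <- 7 * fx$tar + 3 * fx$sur
  ei <- estc_correct(v, imp)
  expect_equal(ei$corrected, v, tolerance = 1e-9)
})

test_that("eSTC with a zero-signal surround reduces to pure recovery division", {
  fx <- two_compartment_fixture()
  img_t <- conv3d(fx$c_t * fx$tar, fx$psf_t)   # only the target emits
  e <- estc_correct(img_t, fx$cs)
  rsf_t <- fx$cs$rsf_masked[["target"]]
  manual <- vol_values(img_t) * fx$tar / pmax(rsf_t, 0.05)
  core <- erode_mask(fx$tar, 2)   # compare away from treated edges
  expect_equal(e$corrected[core], manual[core], tolerance = 1e-6)
})
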