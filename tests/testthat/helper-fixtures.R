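# Shared fixtures, independent oracles, and a session-level cache for
# the expensive phantom/Monte-Carlo objects (built once, reused by
# several test files).

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# --- independent oracles ---------------------------------------------

# Continuous 3D Fourier transform of the radially weighted k-space ball
# (radius kmax, weight w(k/kmax)), evaluated at radius r by quadrature.
radial_psf_oracle <- function(r, wfun, kmax, nq = 4096) {
  q <- seq(0, kmax, length.out = nq + 1)[-1]
  dq <- kmax / nq
  vapply(r, function(ri) {
    if (ri < 1e-12) return(sum(wfun(q / kmax) * 4 * pi * q^2) * dq)
    u <- 2 * pi * q * ri
    sum(wfun(q / kmax) * sin(u) / u * 4 * pi * q^2) * dq
  }, 0)
}

# Normalized transform of the unweighted unit ball (jinc-like profile).
ball_transform_oracle <- function(r, kmax) {
  u <- 2 * pi * kmax * r
  ifelse(u < 1e-8, 1, 3 * (sin(u) - u * cos(u)) / u^3)
}

# Brute-force zero-padded convolution by direct summation.
conv3d_bruteforce <- function(v, kernel) {
  d <- dim(v); dk <- dim(kernel); hw <- (dk - 1L) %/% 2L
  out <- array(0, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    acc <- 0
    for (a in -hw[1]:hw[1]) for (b in -hw[2]:hw[2]) for (cc in -hw[3]:hw[3]) {
      ii <- i - a; jj <- j - b; kk <- k - cc
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
          kk >= 1 && kk <= d[3])
        acc <- acc + v[ii, jj, kk] *
          kernel[a + hw[1] + 1, b + hw[2] + 1, cc + hw[3] + 1]
    }
    out[i, j, k] <- acc
  }
  out
}

# Hand-built PSF kernel (for degenerate/oscillation fixtures).
raw_psf_kernel <- function(values, voxel_size = 1) {
  structure(list(values = values, voxel_size = voxel_size,
                 coverage = 1, truncated = FALSE),
            class = "psf_kernel")
}

# --- standard fixtures -----------------------------------------------

# Two-compartment box-in-box fixture forward-blurred with the
# compartments' own realistic PSFs, plus the truth for recovery checks.
two_compartment_fixture <- function() {
  cache_get("two_comp", function() {
    p <- sequence_params()
    n <- 64
    tar <- array(FALSE, dim = c(n, n, n)); tar[25:40, 25:40, 15:50] <- TRUE
    sur <- array(FALSE, dim = c(n, n, n)); sur[10:55, 10:55, 5:60] <- TRUE
    sur <- sur & !tar
    psf_t <- simulate_psf(relaxation_times(19.2, 14.2, 1.4, 0.6), p,
                          "hanning", 10, grid_size = 128)
    psf_s <- simulate_psf(relaxation_times(25.2, 14.3, 1.4, 0.6), p,
                          "hanning", 10, grid_size = 128)
    c_t <- 15; c_s <- 25
    img <- conv3d(c_t * tar, psf_t) + conv3d(c_s * sur, psf_s)
    cs <- compartment_set(list(target = tar, surround = sur),
                          list(psf_t, psf_s), surround = "surround")
    list(img = img, cs = cs, tar = tar, sur = sur, c_t = c_t, c_s = c_s,
         psf_t = psf_t, psf_s = psf_s, params = p)
  })
}

small_bundle <- function() {
  cache_get("bundle", function()
    generate_phantom(phantom_geometry(preset = "small")))
}

# Full Monte Carlo evaluation at the study conditions: 96^3 phantom,
# 20 iterations at SNR 10 (the primary condition) and 10 at SNR 5 (for
# the noise-scaling properties). Built once and shared between the
# acceptance checks and the statistical-property tests.
mc_report <- function() {
  cache_get("mc_report", function() {
    cf <- evaluation_config(n_iterations = c(20L, 10L), snr = c(10, 5),
                            seed = 101L)
    run_monte_carlo(cf)
  })
}
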