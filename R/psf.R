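#' Sequence parameters of a density-adapted 3D radial acquisition
#'
#' Defaults follow a typical in-vivo sodium protocol at 3 T: TR/TE of
#' 15/0.1 ms, 90 degree excitation, 5 ms readout, 2 mm nominal
#' resolution.
#'
#' @param TR repetition time, ms.
#' @param TE echo time, ms (must be < TR).
#' @param readout_duration radial readout duration, ms.
#' @param ramp_fraction fraction of k-space radius covered by the
#'   initial linear gradient ramp, in (0, 1).
#' @param nominal_resolution nominal isotropic resolution, mm.
#' @param matrix_size reconstructed matrix edge length (>= 8).
#' @param flip_angle excitation flip angle, degrees.
#' @return An object of class `sequence_params`.
#' @export
sequence_params <- function(TR = 15, TE = 0.1, readout_duration = 5,
                            ramp_fraction = 0.2, nominal_resolution = 2,
                            matrix_size = 64, flip_angle = 90) {
  if (!(TE < TR)) stop("TE must be smaller than TR")
  if (readout_duration <= 0) stop("readout_duration must be positive")
  if (!(ramp_fraction > 0 && ramp_fraction < 1))
    stop("ramp_fraction must lie strictly inside (0, 1)")
  if (nominal_resolution <= 0) stop("nominal_resolution must be positive")
  if (matrix_size < 8) stop("matrix_size must be at least 8")
  structure(list(TR = TR, TE = TE, readout_duration = readout_duration,
                 ramp_fraction = ramp_fraction,
                 nominal_resolution = nominal_resolution,
                 matrix_size = as.integer(matrix_size),
                 flip_angle = flip_angle),
            class = "sequence_params")
}

#' Biexponential relaxation parameters of a tissue
#'
#' Sodium transverse relaxation is biexponential: a short component
#' `T2s` with amplitude fraction `fs` and a long component `T2l` with
#' amplitude `1 - fs`. A monoexponential tissue (e.g. free fluid) is
#' expressed with `fs = 0`. The amplitude split is rarely reported;
#' the default `fs = 0.6` is the canonical 60/40 division of the sodium
#' signal.
#'
#' @param T1 longitudinal relaxation time, ms.
#' @param T2l long transverse component, ms.
#' @param T2s short transverse component, ms (`NA` for monoexponential
#'   decay, which forces `fs = 0`).
#' @param fs short-component amplitude fraction in \[0, 1\].
#' @return An object of class `relaxation_times`.
#' @export
relaxation_times <- function(T1, T2l, T2s = NA, fs = 0.6) {
  if (is.na(T2s)) { T2s <- T2l; fs <- 0 }
  if (any(c(T1, T2l, T2s) <= 0)) stop("relaxation times must be positive")
  if (T2s > T2l) stop("T2s must not exceed T2l")
  if (fs < 0 || fs > 1) stop("fs must lie in [0, 1]")
  structure(list(T1 = T1, T2l = T2l, T2s = T2s, fs = fs),
            class = "relaxation_times")
}

as_relaxation_times <- function(x) {
  if (inherits(x, "relaxation_times")) return(x)
  if (is.list(x) && all(c("T1", "T2l", "T2s", "fs") %in% names(x)))
    return(relaxation_times(x$T1, x$T2l, x$T2s, x$fs))
  stop("cannot interpret object as relaxation times")
}

#' Readout-time profile of the radial trajectory
#'
#' Returns the monotone map `t(k)` from normalized k-space radius
#' `k in [0, 1]` to readout time in ms for a density-adapted radial
#' spoke: a linear gradient ramp covers `k <= ramp_fraction` (so
#' `k proportional to t^2`), after which the density-adapted regime holds
#' the sampling density constant (`k proportional to t^(1/3)`). The ramp
#' duration is fixed by requiring the gradient (dk/dt) to be continuous
#' at the junction and `t(1) = readout_duration`.
#'
#' @param params a [sequence_params()] object.
#' @return A vectorized function mapping normalized radius to time (ms).
#' @export
kspace_time_map <- function(params) {
  k0 <- params$ramp_fraction
  Tr <- params$readout_duration
  # C1 junction: t0 = ramp duration such that dk/dt matches and t(1) = Tr
  t0 <- 6 * k0^3 * Tr / (5 * k0^3 + 1)
  B <- 6 * k0^3 / t0  # k^3 advance rate in the density-adapted regime
  function(k) {
    if (any(k < 0 | k > 1)) stop("normalized k-space radius must be in [0, 1]")
    ifelse(k <= k0,
           t0 * sqrt(k / k0),
           t0 + (k^3 - k0^3) / B)
  }
}

#' Radial k-space weighting from T2* decay and apodization
#'
#' Signal acquired at radius `k` is attenuated by the biexponential
#' transverse decay evaluated at `TE + t(k)`, optionally multiplied by
#' the Hanning reconstruction window `0.5 (1 + cos(pi k))` used to
#' suppress Gibbs ringing.
#'
#' @param relax a [relaxation_times()] object.
#' @param params a [sequence_params()] object.
#' @param apodization `"hanning"` or `"none"`.
#' @return A vectorized weight function `w(k)` on \[0, 1\].
#' @export
kspace_weighting <- function(relax, params,
                             apodization = c("hanning", "none")) {
  apodization <- match.arg(apodization)
  relax <- as_relaxation_times(relax)
  tmap <- kspace_time_map(params)
  TE <- params$TE
  function(k) {
    t <- TE + tmap(k)
    w <- relax$fs * exp(-t / relax$T2s) + (1 - relax$fs) * exp(-t / relax$T2l)
    if (apodization == "hanning") w <- w * 0.5 * (1 + cos(pi * k))
    w
  }
}

# Cached normalized-radius grid |k|/rmax in unshifted FFT layout; PSF
# banks evaluate many weightings on the same grid geometry.
.psf_cache <- new.env(parent = emptyenv())

normalized_radius_grid <- function(N, rmax) {
  key <- sprintf("%d_%g", N, rmax)
  if (!is.null(.psf_cache[[key]])) return(.psf_cache[[key]])
  fc <- c(0:(N / 2), -((N / 2 - 1):1))          # signed frequency bins
  kn <- sqrt(outer(outer(fc^2, fc^2, `+`), fc^2, `+`)) / rmax
  dim(kn) <- c(N, N, N)
  # keep at most two cached geometries (native and zerofilled grids)
  if (length(ls(.psf_cache)) >= 2) rm(list = ls(.psf_cache)[1], envir = .psf_cache)
  .psf_cache[[key]] <- kn
  kn
}

#' Simulate the image-space point spread function
#'
#' Fills a Cartesian k-space grid with the radial weighting `w(|k|)`
#' inside the sampled ball `|k| <= 1` (zero outside), inverse Fourier
#' transforms it, takes the real part, crops the result to a compact
#' odd-sized kernel window and normalizes it to unit sum (unit DC gain).
#' The sampled ball radius corresponds to the Nyquist frequency of the
#' acquisition's nominal resolution; setting `voxel_size` below
#' `nominal_resolution` samples the same band-limited PSF on a finer
#' grid, as needed when correcting zerofilled images.
#'
#' @param relax a [relaxation_times()] object.
#' @param params a [sequence_params()] object.
#' @param apodization `"hanning"` or `"none"`; all reconstructions this
#'   package corrects are Hanning-filtered, so the PSFs default to it.
#' @param kernel_halfwidth kernel support halfwidth in voxels (>= 3);
#'   the returned kernel has edge `2 * kernel_halfwidth + 1`.
#' @param voxel_size kernel voxel size in mm; defaults to the nominal
#'   resolution.
#' @param grid_size simulation grid edge (even); larger grids reduce the
#'   discretization anisotropy of the voxelized k-space ball.
#' @return A `psf_kernel`: list with `values` (unit-sum 3D array),
#'   `voxel_size`, `coverage` (fraction of PSF mass inside the window)
#'   and `truncated` (TRUE when coverage < 0.99).
#' @export
simulate_psf <- function(relax, params, apodization = c("hanning", "none"),
                         kernel_halfwidth = 10,
                         voxel_size = params$nominal_resolution,
                         grid_size = 128) {
  apodization <- match.arg(apodization)
  if (kernel_halfwidth < 3) stop("kernel_halfwidth must be at least 3")
  N <- as.integer(grid_size)
  if (N %% 2L != 0L) stop("grid_size must be even")
  os <- params$nominal_resolution / voxel_size
  if (os < 1) stop("voxel_size must not exceed the nominal resolution")
  rmax <- N / (2 * os)  # ball radius in frequency bins
  if (rmax > N / 2) stop("oversampling too small for grid")
  if (2 * kernel_halfwidth + 1 > N)
    stop("kernel window exceeds the simulation grid")

  w <- kspace_weighting(relax, params, apodization)
  kn <- normalized_radius_grid(N, rmax)
  wk <- array(0, dim = c(N, N, N))
  inside <- kn <= 1
  wk[inside] <- w(kn[inside])
  rm(kn, inside)

  psf <- Re(fft(wk, inverse = TRUE)) / N^3
  rm(wk)
  # center the origin, then crop the kernel window
  sh <- c((N / 2 + 1):N, 1:(N / 2))
  psf <- psf[sh, sh, sh]
  ctr <- N / 2 + 1
  win <- (ctr - kernel_halfwidth):(ctr + kernel_halfwidth)
  kern <- psf[win, win, win]
  coverage <- sum(abs(kern)) / sum(abs(psf))
  kern <- kern / sum(kern)
  structure(list(values = kern, voxel_size = voxel_size,
                 coverage = coverage, truncated = coverage < 0.99),
            class = "psf_kernel")
}

#' @export
print.psf_kernel <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<psf_kernel> %dx%dx%d @ %g mm, FWHM %.2f mm, coverage %.1f%%%s\n",
              d[1], d[2], d[3], x$voxel_size, psf_fwhm(x),
              100 * x$coverage,
              if (isTRUE(x$truncated)) " [truncated]" else ""))
  invisible(x)
}

#' Unit impulse kernel (identity convolution)
#'
#' @param halfwidth kernel halfwidth in voxels.
#' @param voxel_size voxel size in mm.
#' @return A `psf_kernel` that leaves any volume unchanged under
#'   convolution.
#' @export
impulse_psf <- function(halfwidth = 1L, voxel_size = 1) {
  n <- 2L * halfwidth + 1L
  v <- array(0, dim = c(n, n, n))
  v[halfwidth + 1L, halfwidth + 1L, halfwidth + 1L] <- 1
  structure(list(values = v, voxel_size = voxel_size, coverage = 1,
                 truncated = FALSE),
            class = "psf_kernel")
}

#' Full width at half maximum of a PSF kernel
#'
#' Measured on the central axis profiles (average of the three axes)
#' with linear interpolation at half the peak value; returned in mm.
#'
#' @param psf a `psf_kernel`.
#' @return FWHM in mm.
#' @export
psf_fwhm <- function(psf) {
  v <- psf$values
  d <- dim(v)
  ctr <- (d + 1L) %/% 2L
  prof <- (v[, ctr[2], ctr[3]] + v[ctr[1], , ctr[3]] + v[ctr[1], ctr[2], ]) / 3
  x <- (seq_along(prof) - ctr[1]) * psf$voxel_size
  # spline-refined profile: voxel sampling is too coarse for direct
  # linear interpolation of the half-maximum crossing
  fine <- stats::spline(x, prof, n = 200L * length(prof))
  peak <- max(fine$y)
  half <- peak / 2
  ipk <- which.max(fine$y)
  up <- which(fine$y[ipk:length(fine$y)] <= half)[1]
  dn <- which(rev(fine$y[1:ipk]) <= half)[1]
  if (is.na(up) || is.na(dn)) return(NA_real_)
  fine$x[ipk + up - 1L] - fine$x[ipk - dn + 1L]
}

#' Mean relaxation parameters of a tissue mixture
#'
#' Voxels containing several tissues are assigned the arithmetic mean of
#' the tissues' T1, T2l and T2s relaxation times. The short-component
#' fraction is shared by all biexponential tissues and passes through
#' unchanged; when monoexponential tissues (fs = 0) are mixed in, the
#' arithmetic mean of the fractions is used.
#'
#' @param specs list of [relaxation_times()] objects (or rows of a
#'   tissue table with `T1`, `T2l`, `T2s`, `fs` entries).
#' @return A [relaxation_times()] object.
#' @export
mixed_voxel_relaxation <- function(specs) {
  if (!length(specs)) stop("at least one tissue is required")
  rl <- lapply(specs, as_relaxation_times)
  relaxation_times(T1 = mean(vapply(rl, `[[`, 0, "T1")),
                   T2l = mean(vapply(rl, `[[`, 0, "T2l")),
                   T2s = mean(vapply(rl, `[[`, 0, "T2s")),
                   fs = mean(vapply(rl, `[[`, 0, "fs")))
}

#' Averaged PSF of the surrounding tissues
#'
#' The voxel-wise spill-over corrections treat everything around the
#' target as one compartment whose PSF is simulated at the mean
#' relaxation times of all surrounding tissues.
#'
#' @param specs list of relaxation parameter sets of the surrounding
#'   tissues.
#' @param params a [sequence_params()] object.
#' @param ... passed to [simulate_psf()].
#' @return A `psf_kernel`.
#' @export
surround_psf <- function(specs, params, ...) {
  simulate_psf(mixed_voxel_relaxation(specs), params, ...)
}
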