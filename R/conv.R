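# FFT-based 3D convolution with zero padding.
#
# All spill-over operations (forward blurring, RSFs, STC iterations) are
# convolutions of a volume with a compact, unit-gain PSF kernel. Volumes
# are zero-padded by the kernel halfwidth before the circular FFT
# convolution, which models an object surrounded by air: signal blurred
# past the grid edge is lost, not wrapped around.

# Highly composite padded edge length >= n (keeps R's mixed-radix FFT fast).
conv_pad_dim <- function(n) as.integer(stats::nextn(n, factors = c(2, 3, 5)))

#' Prepare a PSF kernel for repeated FFT convolution
#'
#' Embeds an odd-sized kernel, centered at the origin, into a padded grid
#' matched to the data dimensions and returns its FFT. The prepared plan
#' can be reused for any number of convolutions with volumes of the same
#' dimensions (used heavily by the iterative corrections).
#'
#' @param kernel 3D array (or `psf_kernel`) with odd edge lengths.
#' @param dim_data dimensions of the volumes to be convolved.
#' @return A convolution plan (list with the kernel FFT and geometry).
#' @export
conv3d_plan <- function(kernel, dim_data) {
  k <- vol_values(kernel)
  dk <- dim(k)
  if (any(dk %% 2L == 0L)) stop("kernel edge lengths must be odd")
  hw <- (dk - 1L) %/% 2L
  dp <- vapply(dim_data + 2L * hw, conv_pad_dim, integer(1))
  kp <- array(0, dim = dp)
  # place kernel with its center at the padded-origin voxel (circularly)
  idx <- lapply(1:3, function(a) ((seq_len(dk[a]) - 1L - hw[a]) %% dp[a]) + 1L)
  kp[idx[[1]], idx[[2]], idx[[3]]] <- k
  list(kfft = fft(kp), dim_data = as.integer(dim_data),
       dim_pad = dp, hw = hw)
}

pad_embed <- function(v, plan) {
  vp <- array(0, dim = plan$dim_pad)
  d <- plan$dim_data
  vp[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- v
  vp
}

crop_out <- function(vp, plan) {
  d <- plan$dim_data
  vp[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])]
}

#' Convolve a volume with a prepared kernel
#'
#' @param v 3D array matching the plan's data dimensions.
#' @param plan result of [conv3d_plan()].
#' @return The zero-padded convolution, cropped to the input dimensions.
#' @export
conv3d_apply <- function(v, plan) {
  vp <- pad_embed(v, plan)
  out <- Re(fft(fft(vp) * plan$kfft, inverse = TRUE)) / prod(plan$dim_pad)
  crop_out(out, plan)
}

# Two real convolutions for the price of one FFT pair: pack A + iB,
# transform once, split the spectrum by Hermitian symmetry, apply each
# kernel, and invert once. Both plans must share dim_data/dim_pad.
conv3d_apply_pair <- function(a, b, plan_a, plan_b) {
  stopifnot(all(plan_a$dim_pad == plan_b$dim_pad))
  zp <- pad_embed(a, plan_a) + 1i * pad_embed(b, plan_b)
  Fz <- fft(zp)
  dp <- plan_a$dim_pad
  ridx <- lapply(dp, function(n) c(1L, n:2L))
  Fc <- Conj(Fz[ridx[[1]], ridx[[2]], ridx[[3]]])   # conj(F(-k))
  Fa <- (Fz + Fc) / 2
  Fb <- (Fz - Fc) / 2i
  out <- fft(Fa * plan_a$kfft + 1i * (Fb * plan_b$kfft), inverse = TRUE) /
    prod(dp)
  list(a = crop_out(Re(out), plan_a), b = crop_out(Im(out), plan_b))
}

#' Convolve a volume with a PSF kernel
#'
#' One-shot zero-padded FFT convolution. For repeated convolutions with
#' the same kernel and volume dimensions build a plan once with
#' [conv3d_plan()] and use [conv3d_apply()].
#'
#' @param volume `volume_grid` or 3D array.
#' @param kernel odd-sized 3D kernel (e.g. a [simulate_psf()] result).
#' @return Convolved volume, same container type as the input.
#' @export
conv3d <- function(volume, kernel) {
  v <- vol_values(volume)
  out <- conv3d_apply(v, conv3d_plan(kernel, dim(v)))
  vol_like(out, volume)
}
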