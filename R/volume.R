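#' 3D scalar volume with isotropic voxels
#'
#' Lightweight container for a 3D scalar field (signal, concentration,
#' coil sensitivity or PSF values) on an isotropic grid. Physical
#' positions are `(index - 1) * voxel_size + origin` along each axis,
#' with 0-based array-index semantics used consistently across the
#' package.
#'
#' @param values 3D numeric array; all values must be finite.
#' @param voxel_size isotropic voxel edge length in mm (> 0).
#' @param origin physical position (mm) of the first voxel, length 3.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(values, voxel_size = 1, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("'voxel_size' must be a single positive number")
  if (!all(is.finite(values)))
    stop("'values' must be finite everywhere")
  structure(list(values = values,
                 voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(rep_len(origin, 3L))),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_grid> %d x %d x %d voxels @ %g mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$voxel_size,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Integer-labeled tissue segmentation
#'
#' Maps every voxel to a tissue class. Nonzero labels must appear in the
#' legend (a tissue table as returned by [tissue_table()]); label 0 is
#' background (air) and needs no legend entry.
#'
#' @param labels 3D integer array of tissue labels.
#' @param voxel_size isotropic voxel edge length in mm.
#' @param legend data frame with at least columns `label` and `tissue`.
#' @param origin physical origin in mm.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, voxel_size = 1, legend, origin = c(0, 0, 0)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("'labels' must be a 3D array")
  storage.mode(labels) <- "integer"
  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  missing <- setdiff(present, legend$label)
  if (length(missing))
    stop("labels absent from legend: ", paste(missing, collapse = ", "))
  structure(list(labels = labels,
                 voxel_size = as.numeric(voxel_size),
                 legend = legend,
                 origin = as.numeric(rep_len(origin, 3L))),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_map> %d x %d x %d voxels @ %g mm, %d tissue classes\n",
              d[1], d[2], d[3], x$voxel_size,
              length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}

# Accept either a volume_grid or a bare array.
vol_values <- function(x) {
  if (inherits(x, "volume_grid")) x$values
  else if (inherits(x, "psf_kernel")) x$values
  else if (inherits(x, "label_map")) x$labels
  else if (is.array(x) && length(dim(x)) == 3L) x
  else stop("expected a volume_grid, label_map or 3D array")
}

vol_voxel_size <- function(x, default = 1) {
  if (inherits(x, c("volume_grid", "label_map"))) x$voxel_size else default
}

# Rewrap values into the same container type as the template.
vol_like <- function(values, template) {
  if (inherits(template, "volume_grid"))
    volume_grid(values, template$voxel_size, template$origin)
  else values
}

#' Block-mean downsampling
#'
#' Reduces resolution by an integer factor: every output voxel is the
#' arithmetic mean of its `factor^3` block of input voxels, so the global
#' mean is preserved exactly. This is the tissue-fraction corruption step
#' of the forward model: a coarse voxel averages the signal of every fine
#' voxel it covers.
#'
#' @param volume `volume_grid` or 3D array.
#' @param factor positive integer; each grid edge must be divisible by it.
#' @return Same container type as the input, with `factor`-times larger
#'   voxels.
#' @export
block_downsample <- function(volume, factor) {
  v <- vol_values(volume)
  if (length(factor) != 1L || factor < 1 || factor != round(factor))
    stop("'factor' must be a positive integer")
  factor <- as.integer(factor)
  d <- dim(v)
  if (any(d %% factor != 0L))
    stop("grid edges ", paste(d, collapse = "x"),
         " not divisible by factor ", factor)
  if (factor == 1L) return(volume)
  dn <- d %/% factor
  # reshape to (f, n1', f, n2', f, n3') and average the three block axes
  dim(v) <- c(factor, dn[1], factor, dn[2], factor, dn[3])
  v <- aperm(v, c(1, 3, 5, 2, 4, 6))
  dim(v) <- c(factor^3, prod(dn))
  out <- colMeans(v)
  dim(out) <- dn
  if (inherits(volume, "volume_grid"))
    volume_grid(out, volume$voxel_size * factor,
                volume$origin + (factor - 1) * volume$voxel_size / 2)
  else out
}

#' Fourier zero-padding interpolation (zerofilling)
#'
#' Interpolates a volume onto an integer-factor finer grid by
#' zero-padding its discrete spectrum, the standard zerofilling step used
#' when reconstructing coarse sodium images on the segmentation grid. The
#' global mean (DC component) is preserved; for even grid sizes the
#' Nyquist bin is split symmetrically so the result stays real.
#'
#' When interpolating data that were produced by [block_downsample()],
#' the coarse sample positions sit half a coarse voxel away from the
#' parent fine grid; `align = "block"` (the default) applies the
#' corresponding half-voxel spectral phase shift so the interpolated
#' samples land exactly on the parent fine-grid voxel centers and can be
#' compared voxel-wise with the ground truth. `align = "none"` keeps the
#' plain zero-padding sample positions.
#'
#' @param volume `volume_grid` or 3D array.
#' @param factor integer upsampling factor per axis.
#' @param align `"block"` to re-center onto the parent fine grid,
#'   `"none"` for plain spectral zero-padding.
#' @return Interpolated volume on a grid `factor` times denser.
#' @export
zerofill <- function(volume, factor, align = c("block", "none")) {
  align <- match.arg(align)
  v <- vol_values(volume)
  if (length(factor) != 1L || factor < 1 || factor != round(factor))
    stop("'factor' must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(volume)
  d <- dim(v)
  dm <- d * factor
  sp <- fft(v)
  out_sp <- array(0 + 0i, dim = dm)

  # Per-axis mapping of source frequency bins into the padded spectrum.
  # Segments: DC..(n/2-1), the (even-n) Nyquist bin split in two, and the
  # negative frequencies. Each entry: source indices, target indices, weight.
  axis_map <- function(n, m) {
    half <- n %/% 2L
    segs <- list(list(src = 1:half, dst = 1:half, w = 1))
    if (n %% 2L == 0L) {
      # combined +/- Nyquist bin: split to +n/2 and -n/2 in the fine grid
      segs <- c(segs,
                list(list(src = half + 1L, dst = half + 1L, w = 0.5),
                     list(src = half + 1L, dst = m - half + 1L, w = 0.5)))
      if (half >= 2L)
        segs <- c(segs, list(list(src = (half + 2L):n,
                                  dst = (m - half + 2L):m, w = 1)))
    } else {
      segs <- c(segs, list(list(src = (half + 2L):n,
                                dst = (m - half + 1L):m, w = 1)))
      segs[[1]] <- list(src = 1:(half + 1L), dst = 1:(half + 1L), w = 1)
    }
    segs
  }

  m1 <- axis_map(d[1], dm[1]); m2 <- axis_map(d[2], dm[2]); m3 <- axis_map(d[3], dm[3])
  for (a in m1) for (b in m2) for (cc in m3) {
    blk <- as.vector(sp[a$src, b$src, cc$src, drop = FALSE]) *
      (a$w * b$w * cc$w)
    out_sp[a$dst, b$dst, cc$dst] <-
      as.vector(out_sp[a$dst, b$dst, cc$dst]) + blk
  }
  shift <- if (align == "block") (factor - 1) / 2 else 0
  if (shift != 0) {
    # sample the interpolant 'shift' fine voxels to the left along each
    # axis (shift theorem); occupied bins satisfy |nu| <= n/2 << M/2
    for (ax in 1:3) {
      M <- dm[ax]
      nu <- c(0:(M %/% 2), -((M - M %/% 2 - 1):1))
      ph <- exp(-2i * pi * nu * shift / M)
      out_sp <- out_sp * array(rep(ph, each = prod(dm[seq_len(ax - 1)])),
                               dim = dm)
    }
  }
  out <- Re(fft(out_sp, inverse = TRUE)) / prod(d)
  if (inherits(volume, "volume_grid")) {
    org <- volume$origin
    if (align == "block")
      org <- org - shift * volume$voxel_size / factor
    volume_grid(out, volume$voxel_size / factor, org)
  } else out
}
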