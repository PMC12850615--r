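# Forward corruption chain: relaxation weighting -> block-mean
# downsampling (tissue-fraction effect) -> coil sensitivity -> per-tissue
# PSF convolution (spill-over) -> Rician noise, in exactly that order.

#' Group coarse voxels by the tissue combination they contain
#'
#' After block downsampling, a coarse voxel can cover several tissues of
#' the high-resolution segmentation. Voxels are grouped by the set of
#' signal-bearing tissues they contain; each group gets one PSF,
#' simulated at the mean relaxation times of its member tissues. Air and
#' sodium-free tissues (bone) carry no signal and do not influence the
#' grouping.
#'
#' @param labels high-resolution `label_map` (or integer array).
#' @param factor integer downsampling factor.
#' @param tissues tissue table identifying which labels carry signal.
#' @return List with `key` (coarse integer array of group ids, 0 for
#'   signal-free voxels) and `combos` (list mapping group id to the
#'   member label vector).
#' @export
mixed_label_groups <- function(labels, factor, tissues = tissue_table()) {
  l <- vol_values(labels)
  signal_labels <- tissues$label[!is.na(tissues$T1)]
  signal_labels <- intersect(signal_labels, unique(as.vector(l)))
  dn <- dim(l) %/% factor
  nc <- prod(dn)
  P <- matrix(FALSE, nrow = nc, ncol = length(signal_labels))
  for (j in seq_along(signal_labels)) {
    frac <- block_downsample(array(as.numeric(l == signal_labels[j]),
                                   dim = dim(l)), factor)
    P[, j] <- frac > 0
  }
  key_num <- as.vector(P %*% 2^(seq_along(signal_labels) - 1))
  ids <- sort(setdiff(unique(key_num), 0))
  key <- array(match(key_num, ids, nomatch = 0L), dim = dn)
  combos <- lapply(ids, function(k) {
    signal_labels[bitwAnd(rep(k, length(signal_labels)),
                          2^(seq_along(signal_labels) - 1)) > 0]
  })
  list(key = key, combos = combos)
}

#' Simulate the PSF bank for a set of tissue combinations
#'
#' One PSF per tissue-combination group, simulated at the mean
#' relaxation times of the member tissues.
#'
#' @param groups result of [mixed_label_groups()].
#' @param tissues tissue table supplying relaxation times.
#' @param params a [sequence_params()] object.
#' @param ... passed to [simulate_psf()] (`kernel_halfwidth`,
#'   `voxel_size`, `grid_size`, `apodization`).
#' @return List of `psf_kernel`s indexed by group id.
#' @export
build_psf_bank <- function(groups, tissues, params, ...) {
  lapply(groups$combos, function(members) {
    rows <- tissues[match(members, tissues$label), , drop = FALSE]
    rows <- rows[!is.na(rows$T1), , drop = FALSE]
    specs <- lapply(seq_len(nrow(rows)), function(i)
      relaxation_times(rows$T1[i], rows$T2l[i], rows$T2s[i], rows$fs[i]))
    simulate_psf(mixed_voxel_relaxation(specs), params, ...)
  })
}

#' Per-tissue PSF blurring (spill-over forward model)
#'
#' Decomposes the volume by tissue group, convolves each part with its
#' group's PSF and sums the results. Linear in the input; with unit-gain
#' PSFs the global sum is preserved up to the kernel mass lost over the
#' padded boundary.
#'
#' @param volume `volume_grid` or 3D array at the coarse grid.
#' @param groups integer array of group ids (same dimensions), or the
#'   list returned by [mixed_label_groups()].
#' @param psfs list of `psf_kernel`s indexed by group id.
#' @param plans optional list of precomputed [conv3d_plan()]s indexed by
#'   group id (see [spillover_plans()]), reused across repeated forward
#'   simulations.
#' @return Blurred volume, same container type as the input.
#' @export
spillover_forward <- function(volume, groups, psfs, plans = NULL) {
  v <- vol_values(volume)
  key <- if (is.list(groups) && !is.null(groups$key)) groups$key else groups
  if (!identical(dim(key), dim(v)))
    stop("group key and volume dimensions do not match")
  ids <- sort(setdiff(unique(as.vector(key)), 0L))
  miss <- ids[ids > length(psfs)]
  if (length(miss))
    stop("missing PSF for tissue combination group(s): ",
         paste(miss, collapse = ", "))
  if (is.null(plans))
    plans <- lapply(seq_along(psfs),
                    function(i) conv3d_plan(psfs[[i]], dim(v)))
  plans <- plans[ids]
  parts <- lapply(ids, function(i) {
    p <- v
    p[key != i] <- 0
    p
  })
  out <- array(0, dim = dim(v))
  i <- 1L
  while (i <= length(ids)) {
    if (i + 1L <= length(ids) &&
        all(plans[[i]]$dim_pad == plans[[i + 1L]]$dim_pad)) {
      pr <- conv3d_apply_pair(parts[[i]], parts[[i + 1L]],
                              plans[[i]], plans[[i + 1L]])
      out <- out + pr$a + pr$b
      i <- i + 2L
    } else {
      out <- out + conv3d_apply(parts[[i]], plans[[i]])
      i <- i + 1L
    }
  }
  vol_like(out, volume)
}

#' Precompute convolution plans for a PSF bank
#'
#' @param psfs list of `psf_kernel`s.
#' @param dim_data dimensions of the volumes to be blurred.
#' @return List of [conv3d_plan()]s indexed like `psfs`.
#' @export
spillover_plans <- function(psfs, dim_data) {
  lapply(psfs, conv3d_plan, dim_data = dim_data)
}

#' Simulate a sodium acquisition of the phantom
#'
#' Applies the full forward corruption chain to the ground-truth
#' concentration volume, in the pinned order: per-tissue relaxation
#' weighting, block-mean downsampling to the acquired resolution, coil
#' sensitivity weighting, per-tissue-group PSF convolution, Rician
#' noise. The SNR reference region is the set of coarse voxels lying
#' entirely inside the MID section.
#'
#' @param bundle a [generate_phantom()] result.
#' @param params a [sequence_params()] object; its TR/TE drive the
#'   relaxation weighting.
#' @param resolution_factor integer ratio of acquired to ground-truth
#'   voxel size (default 2: 1 mm ground truth acquired at 2 mm).
#' @param target_snr SNR in the MID reference region (`Inf` disables
#'   noise).
#' @param sensitivity fine-grid sensitivity `volume_grid`, or `NULL`
#'   for the geometry's coil model; pass a uniform field of ones to
#'   disable sensitivity weighting.
#' @param psf_bank optional precomputed [build_psf_bank()] result
#'   matched to `groups`; both are built on demand when `NULL`.
#' @param groups optional precomputed [mixed_label_groups()] result.
#' @param seed integer seed for the noise realization.
#' @param kernel_halfwidth,psf_grid_size,apodization PSF simulation
#'   controls used when the bank is built on demand.
#' @param conv_plans optional [spillover_plans()] result matched to the
#'   bank and the coarse grid, reused across noise realizations.
#' @return An `na_acquisition` list: `native` (noisy coarse
#'   `volume_grid`), `noise_free`, `sigma`, `seed`, `snr_roi`,
#'   `sensitivity_coarse`, `groups`, `psfs`, `resolution_factor`,
#'   `params`.
#' @export
simulate_acquisition <- function(bundle, params = sequence_params(),
                                 resolution_factor = 2L, target_snr = 10,
                                 sensitivity = NULL, psf_bank = NULL,
                                 groups = NULL, seed = 1L,
                                 kernel_halfwidth = 10,
                                 psf_grid_size = 128,
                                 apodization = "hanning",
                                 conv_plans = NULL) {
  stopifnot(inherits(bundle, "phantom_bundle"))
  tt <- bundle$tissues
  lab <- bundle$labels$labels
  conc <- bundle$ground_truth$values

  # 1. relaxation weighting per tissue
  wmap <- rep(1, max(tt$label) + 1L)
  for (r in seq_len(nrow(tt))) {
    if (!is.na(tt$T1[r]))
      wmap[tt$label[r] + 1L] <- relaxation_weight(
        relaxation_times(tt$T1[r], tt$T2l[r], tt$T2s[r], tt$fs[r]),
        params$TR, params$TE)
  }
  weighted <- conc * array(wmap[lab + 1L], dim = dim(lab))

  # 2. tissue-fraction effect: block mean to the acquired resolution
  coarse <- block_downsample(volume_grid(weighted, bundle$ground_truth$voxel_size),
                             resolution_factor)

  # 3. coil sensitivity
  if (is.null(sensitivity)) sensitivity <- make_sensitivity(bundle$geometry)
  sens_coarse <- block_downsample(sensitivity, resolution_factor)
  coarse <- apply_sensitivity(coarse, sens_coarse)

  # 4. spill-over: per-group PSF convolution
  if (is.null(groups))
    groups <- mixed_label_groups(bundle$labels, resolution_factor, tt)
  if (is.null(psf_bank))
    psf_bank <- build_psf_bank(groups, tt, params,
                               apodization = apodization,
                               kernel_halfwidth = kernel_halfwidth,
                               voxel_size = bundle$ground_truth$voxel_size *
                                 resolution_factor,
                               grid_size = psf_grid_size)
  blurred <- spillover_forward(coarse, groups, psf_bank, plans = conv_plans)

  # 5. Rician noise, referenced to pure-MID voxels
  mid_frac <- block_downsample(array(as.numeric(lab == 2L), dim = dim(lab)),
                               resolution_factor)
  snr_roi <- mid_frac >= 1
  if (!any(snr_roi)) snr_roi <- mid_frac > 0.5
  noisy <- add_rician_noise(blurred, target_snr, snr_roi, seed = seed)

  structure(list(native = noisy$volume, noise_free = blurred,
                 sigma = noisy$sigma, seed = as.integer(seed),
                 snr_roi = snr_roi, sensitivity_coarse = sens_coarse,
                 groups = groups, psfs = psf_bank,
                 resolution_factor = as.integer(resolution_factor),
                 params = params),
            class = "na_acquisition")
}
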