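# Apparent tissue sodium content (aTSC) quantification: coil
# sensitivity correction, relaxation correction, reference-phantom
# calibration, ROI statistics. The pinned order of the post-processing
# chain is: partial volume correction first, then sensitivity
# correction, then calibration/relaxation correction into mM.

#' Correct for coil sensitivity
#'
#' Voxel-wise division by the normalized sensitivity field. Voxels with
#' sensitivity below `floor` are unreliable and flagged.
#'
#' @param image `volume_grid` or 3D array.
#' @param sensitivity sensitivity field on the same grid.
#' @param floor minimum trusted sensitivity.
#' @return List with `volume` (corrected, same container type) and
#'   `flagged` (logical array).
#' @export
sensitivity_correct <- function(image, sensitivity, floor = 0.05) {
  v <- vol_values(image); s <- vol_values(sensitivity)
  if (!identical(dim(v), dim(s)))
    stop("image and sensitivity grids do not match")
  if (max(s) > 1) s <- s / max(s)   # fields at most 1 are kept as given
  if (all(s < floor)) stop("entire sensitivity field below the floor")
  flagged <- s < floor
  out <- v / pmax(s, floor)
  list(volume = vol_like(out, image), flagged = flagged)
}

#' Correct a signal for relaxation weighting
#'
#' Divides by the steady-state relaxation weight of the tissue (see
#' [relaxation_weight()]), undoing T1 saturation and T2* decay at the
#' echo time.
#'
#' @param signal scalar, vector or array of signal values.
#' @param relax a [relaxation_times()] object.
#' @param TR,TE sequence timing, ms.
#' @return Corrected signal, same shape.
#' @export
relaxation_correct <- function(signal, relax, TR, TE) {
  w <- relaxation_weight(relax, TR, TE)
  if (w <= 0) stop("relaxation weight must be positive")
  signal / w
}

#' Calibrate signal against reference phantoms
#'
#' Ordinary least squares fit `signal = slope * concentration +
#' intercept` over the reference phantoms of known concentration.
#'
#' @param ref_means mean (sensitivity- and relaxation-corrected)
#'   signals of the reference phantoms.
#' @param ref_concs known concentrations, mM (>= 2 distinct values).
#' @return A `calibration_fit`: `slope`, `intercept`, `concentrations`,
#'   `residual_norm`.
#' @export
calibrate <- function(ref_means, ref_concs) {
  if (length(ref_means) != length(ref_concs))
    stop("signal and concentration lengths differ")
  if (length(ref_concs) < 2L || length(unique(ref_concs)) < 2L)
    stop("need at least two distinct reference concentrations")
  fit <- stats::lm(ref_means ~ ref_concs)
  co <- stats::coef(fit)
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 concentrations = sort(ref_concs),
                 residual_norm = sqrt(sum(stats::residuals(fit)^2))),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> signal = %.4g * conc %+.4g (residual %.3g)\n",
              x$slope, x$intercept, x$residual_norm))
  invisible(x)
}

#' Convert signal to apparent tissue sodium content
#'
#' Inverts the calibration fit: `aTSC = (signal - intercept) / slope`.
#' Negative concentrations are reported as-is (warned for scalar
#' input), never clamped.
#'
#' @param signal scalar, vector or array of corrected signal.
#' @param fit a [calibrate()] result.
#' @return Concentration in mM, same shape as `signal`.
#' @export
to_atsc <- function(signal, fit) {
  if (fit$slope <= 0) stop("calibration slope must be positive")
  out <- (signal - fit$intercept) / fit$slope
  if (length(out) == 1L && !is.na(out) && out < 0)
    warning("negative aTSC")
  out
}

#' Apply a region-level correction to an ROI of a map
#'
#' Scales every ROI voxel by the ratio of the corrected to the
#' uncorrected mean, preserving the within-ROI relative pattern. This
#' is how region-wise methods (PSSR, GTM) produce voxel maps.
#'
#' @param image `volume_grid` or 3D array.
#' @param roi_mask logical ROI mask.
#' @param corrected_mean region-level corrected mean.
#' @param uncorrected_mean mean of `image` over the ROI (must be
#'   nonzero).
#' @return `image` with the ROI scaled, same container type.
#' @export
regionwise_map <- function(image, roi_mask, corrected_mean,
                           uncorrected_mean) {
  if (uncorrected_mean == 0) stop("uncorrected ROI mean is zero")
  v <- vol_values(image)
  m <- vol_values(roi_mask) != 0
  v[m] <- v[m] * (corrected_mean / uncorrected_mean)
  vol_like(v, image)
}

#' ROI statistics of an aTSC map
#'
#' Mean and standard deviation (over ROI voxels) of the aTSC map in
#' each tendon section. The combined whole-tendon value is not the mean
#' of the section means: it is computed at the signal level from the
#' average tendon signal and the average tendon relaxation times and
#' passed in via `combined`; its SD is taken over all tendon voxels of
#' the map.
#'
#' @param atsc_map aTSC map (`volume_grid` or 3D array, mM; NA allowed
#'   outside the mapped region).
#' @param section_masks list of logical masks named `INS`, `MID`,
#'   `MTJ`, `AT` (see [tendon_section_masks()]).
#' @param combined combined whole-tendon aTSC computed at signal level
#'   (optional).
#' @return A data frame with columns `roi`, `mean_mM`, `sd_mM`, `n`.
#' @export
roi_statistics <- function(atsc_map, section_masks, combined = NULL) {
  v <- vol_values(atsc_map)
  rows <- lapply(c("INS", "MID", "MTJ"), function(nm) {
    m <- section_masks[[nm]]
    if (is.null(m) || !any(m)) stop("empty or missing section: ", nm)
    x <- v[m]
    data.frame(roi = nm, mean_mM = mean(x, na.rm = TRUE),
               sd_mM = stats::sd(x, na.rm = TRUE),
               n = sum(!is.na(x)))
  })
  out <- do.call(rbind, rows)
  xat <- v[section_masks$AT]
  out <- rbind(out, data.frame(
    roi = "combined",
    mean_mM = if (is.null(combined)) mean(xat, na.rm = TRUE) else combined,
    sd_mM = stats::sd(xat, na.rm = TRUE),
    n = sum(!is.na(xat))))
  rownames(out) <- NULL
  out
}
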