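#' Tissue parameters of the digital Achilles-tendon phantom
#'
#' Sodium concentrations (mM) and relaxation times (ms) of all simulated
#' tissue classes: the three tendon subsections (INS, insertion into the
#' calcaneus; MID, middle portion; MTJ, myotendinous junction), an
#' elevated-concentration INS tip, a hyperintense MID spot and a
#' hypointense MTJ spot emulating regional inhomogeneities, the
#' surrounding soft tissues, sodium-free bone, and the four agarose
#' reference phantoms (50/75/100/125 mM) used for calibration. The
#' short-fraction `fs` defaults to the canonical 0.6 biexponential
#' split; synovial fluid relaxes monoexponentially (`fs = 0`).
#'
#' @param fs short-component amplitude fraction assigned to all
#'   biexponential tissues.
#' @return A data frame with columns `tissue`, `label`, `concentration`,
#'   `T1`, `T2l`, `T2s`, `fs` and `group` (tendon / surround / bone /
#'   reference).
#' @export
tissue_table <- function(fs = 0.6) {
  tt <- data.frame(
    tissue = c("INS", "MID", "MTJ", "INS_tip", "MID_spot", "MTJ_spot",
               "skin", "fat", "muscle", "synovial_fluid", "blood",
               "calcaneus",
               "ref_50", "ref_75", "ref_100", "ref_125"),
    label = c(1:12, 20:23),
    concentration = c(25, 15, 18, 30, 18, 14,
                      34.2, 13.1, 20.3, 140, 81,
                      0,
                      50, 75, 100, 125),
    T1  = c(18.4, 19.2, 23.3, 18.4, 19.2, 23.3,
            27, 25.2, 25.2, 62, 38.4,
            NA,
            38.5, 38.5, 38.5, 38.5),
    T2l = c(14.5, 14.2, 14.6, 14.5, 14.2, 14.6,
            7.6, 14.3, 14.3, 28, 15.8,
            NA,
            13, 13, 13, 13),
    T2s = c(1.4, 1.4, 1.5, 1.4, 1.4, 1.5,
            0.5, 1.4, 1.4, NA, 2.0,
            NA,
            6, 6, 6, 6),
    fs = fs,
    group = c(rep("tendon", 6), rep("surround", 5), "bone",
              rep("reference", 4)),
    stringsAsFactors = FALSE
  )
  tt$fs[tt$tissue == "synovial_fluid"] <- 0  # monoexponential fluid
  tt$fs[tt$group == "bone"] <- NA
  tt
}

# Tendon sections and their constituent labels.
.section_labels <- list(INS = c(1L, 4L), MID = c(2L, 5L), MTJ = c(3L, 6L))
.at_labels <- 1:6

#' Geometry configuration of the synthetic phantom
#'
#' Parametric stand-in for a manually segmented lower leg: the leg is an
#' elliptical cylinder wrapped in a 2 mm skin shell over a subcutaneous
#' fat layer, with the Achilles tendon as a gently curved elliptical
#' tube running the full 90 mm of the three 30 mm subsections, the
#' calcaneus as an ellipsoid at the distal end, a retrocalcaneal bursa
#' (synovial fluid), a Kager-type fat pad, two blood vessels, and four
#' reference cylinders (1 cm diameter, 3.5 cm height) placed between the
#' coil plane and the leg. The scene is defined inside a 96 mm
#' reference box and centered in larger grids. All positions are mm in
#' 0-based physical coordinates (voxel center i sits at `i * voxel_size`).
#'
#' @param grid_size grid edge length in voxels.
#' @param voxel_size isotropic voxel size, mm.
#' @param preset `"default"` (160 voxels at 1 mm) or `"small"` (96
#'   voxels at 1 mm, used throughout the tests).
#' @param ... overrides for individual geometry fields.
#' @return A `phantom_geometry` list.
#' @export
phantom_geometry <- function(grid_size = 160, voxel_size = 1,
                             preset = c("default", "small"), ...) {
  preset <- match.arg(preset)
  if (preset == "small") grid_size <- 96
  geom <- list(
    grid_size = as.integer(grid_size),
    voxel_size = voxel_size,
    # leg cross-section (elliptical cylinder along z)
    leg_center = c(58, 48),
    leg_semiaxes = c(34, 42),
    skin_thickness = 2,
    fat_thickness = 2,
    # tendon tube: posterior edge in contact with the thin subcutis, as
    # in the ankle (the tendon lies directly beneath the skin)
    tendon_z0 = 3, section_length = 30, tip_length = 10,
    tendon_x_base = 32, tendon_x_bow = 4,
    tendon_center_y = 48, tendon_semiaxes = c(4, 8),
    # calcaneus / bursa / fat pad ellipsoids: center (x,y,z), semiaxes
    calcaneus_center = c(54, 48, 12), calcaneus_semiaxes = c(16, 14, 10),
    bursa_center = c(40, 48, 22), bursa_semiaxes = c(3, 4, 5),
    fatpad_center = c(44, 48, 34), fatpad_semiaxes = c(6, 8, 14),
    # vessels: columns x, y, radius (cylinders along z)
    vessels = rbind(c(66, 34, 2), c(70, 62, 2)),
    # regional inhomogeneity spots: ellipsoids clipped to their section
    spot_semiaxes = c(2.5, 4, 6), spot_z = c(MID = 48, MTJ = 78),
    # reference cylinders
    ref_x = 12, ref_y = c(14, 36, 58, 80), ref_z = c(30, 65), ref_radius = 5,
    # surface coil
    coil_plane_x = 2, sens_d0 = 60
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(geom))
  if (length(unknown))
    stop("unknown geometry fields: ", paste(unknown, collapse = ", "))
  geom[names(over)] <- over
  # center the 96 mm reference scene in larger grids
  geom$offset <- (grid_size * voxel_size - 96) / 2
  if (geom$offset < 0) stop("grid too small for the 96 mm reference scene")
  structure(geom, class = "phantom_geometry")
}

# Physical coordinate arrays (mm) of voxel centers, reference-scene frame.
coord_arrays <- function(geom) {
  n <- geom$grid_size
  x <- (seq_len(n) - 1) * geom$voxel_size - geom$offset
  list(X = array(x, dim = c(n, n, n)),
       Y = array(rep(x, each = n), dim = c(n, n, n)),
       Z = array(rep(x, each = n * n), dim = c(n, n, n)),
       x1d = x)
}

ellipsoid_mask <- function(co, center, semi) {
  ((co$X - center[1]) / semi[1])^2 + ((co$Y - center[2]) / semi[2])^2 +
    ((co$Z - center[3]) / semi[3])^2 <= 1
}

#' Generate the synthetic Achilles-tendon phantom
#'
#' Builds the integer label map and the ground-truth concentration
#' volume from a geometry configuration and a tissue table. The
#' construction is deterministic; `seed` is stored for provenance of
#' downstream noise realizations.
#'
#' @param geometry a [phantom_geometry()] configuration.
#' @param tissues a [tissue_table()] data frame.
#' @param seed integer recorded in the bundle.
#' @return A `phantom_bundle`: list with `ground_truth` (mM
#'   `volume_grid`), `labels` (`label_map`), `geometry`, `tissues`,
#'   `seed`.
#' @export
generate_phantom <- function(geometry = phantom_geometry(),
                             tissues = tissue_table(), seed = 1L) {
  g <- geometry
  co <- coord_arrays(g)
  n <- g$grid_size
  lab <- array(0L, dim = c(n, n, n))
  lab_of <- function(name) tissues$label[tissues$tissue == name]

  span <- n * g$voxel_size
  # leg: elliptical cylinder; skin = outer shell, fat = next layer inward
  er <- function(semi) ((co$X - g$leg_center[1]) / semi[1])^2 +
    ((co$Y - g$leg_center[2]) / semi[2])^2
  leg <- er(g$leg_semiaxes) <= 1
  inner_skin <- er(g$leg_semiaxes - g$skin_thickness) <= 1
  inner_fat <- er(g$leg_semiaxes - g$skin_thickness - g$fat_thickness) <= 1

  lab[leg] <- lab_of("muscle")
  lab[inner_skin & !inner_fat] <- lab_of("fat")

  # Kager-type fat pad between tendon, calcaneus and deep muscle
  lab[ellipsoid_mask(co, g$fatpad_center, g$fatpad_semiaxes) & inner_fat] <-
    lab_of("fat")

  # calcaneus
  calc <- ellipsoid_mask(co, g$calcaneus_center, g$calcaneus_semiaxes)
  lab[calc & inner_fat] <- lab_of("calcaneus")

  # vessels
  for (v in seq_len(nrow(g$vessels))) {
    vx <- g$vessels[v, ]
    vm <- (co$X - vx[1])^2 + (co$Y - vx[2])^2 <= vx[3]^2
    lab[vm & inner_fat & !calc] <- lab_of("blood")
  }

  # retrocalcaneal bursa
  bursa <- ellipsoid_mask(co, g$bursa_center, g$bursa_semiaxes)
  if (!all(bursa <= inner_fat))
    stop("geometry error: region 'bursa' extends outside the leg interior")
  lab[bursa] <- lab_of("synovial_fluid")

  # tendon tube with INS / MID / MTJ sections of section_length each
  z0 <- g$tendon_z0
  zlen <- 3 * g$section_length
  u <- (co$Z - z0) / zlen
  xc <- g$tendon_x_base + g$tendon_x_bow * pmin(pmax(u, 0), 1)^2
  tendon <- ((co$X - xc) / g$tendon_semiaxes[1])^2 +
    ((co$Y - g$tendon_center_y) / g$tendon_semiaxes[2])^2 <= 1 &
    co$Z >= z0 & co$Z < z0 + zlen
  if (!any(tendon)) stop("geometry error: region 'tendon' is empty")
  sec <- findInterval(co$Z, z0 + g$section_length * (0:2))
  lab[tendon & sec == 1] <- lab_of("INS")
  lab[tendon & sec == 2] <- lab_of("MID")
  lab[tendon & sec == 3] <- lab_of("MTJ")
  lab[tendon & co$Z < z0 + g$tip_length] <- lab_of("INS_tip")

  # regional inhomogeneity spots, clipped to their section
  spot_mid <- ellipsoid_mask(
    co, c(g$tendon_x_base + g$tendon_x_bow * ((g$spot_z[["MID"]] - z0) / zlen)^2,
          g$tendon_center_y, g$spot_z[["MID"]]), g$spot_semiaxes)
  spot_mtj <- ellipsoid_mask(
    co, c(g$tendon_x_base + g$tendon_x_bow * ((g$spot_z[["MTJ"]] - z0) / zlen)^2,
          g$tendon_center_y, g$spot_z[["MTJ"]]), g$spot_semiaxes)
  if (!any(spot_mid & lab == lab_of("MID")))
    stop("geometry error: region 'MID_spot' does not intersect the MID section")
  if (!any(spot_mtj & lab == lab_of("MTJ")))
    stop("geometry error: region 'MTJ_spot' does not intersect the MTJ section")
  lab[spot_mid & lab == lab_of("MID")] <- lab_of("MID_spot")
  lab[spot_mtj & lab == lab_of("MTJ")] <- lab_of("MTJ_spot")

  # skin painted after the tendon must not overwrite it
  skin <- leg & !inner_skin
  if (any(skin & tendon))
    stop("geometry error: region 'tendon' overlaps the skin shell")
  lab[skin] <- lab_of("skin")

  # reference cylinders between coil plane and leg
  ref_names <- c("ref_50", "ref_75", "ref_100", "ref_125")
  ref_masks <- vector("list", 4L)
  for (i in 1:4) {
    rm_ <- (co$X - g$ref_x)^2 + (co$Y - g$ref_y[i])^2 <= g$ref_radius^2 &
      co$Z >= g$ref_z[1] & co$Z <= g$ref_z[2]
    if (!any(rm_))
      stop("geometry error: region '", ref_names[i], "' lies outside the grid")
    lo <- c(g$ref_x - g$ref_radius, g$ref_y[i] - g$ref_radius, g$ref_z[1])
    hi <- c(g$ref_x + g$ref_radius, g$ref_y[i] + g$ref_radius, g$ref_z[2])
    if (any(lo < -g$offset) || any(hi > span - g$offset))
      stop("geometry error: region '", ref_names[i], "' exits the grid")
    if (any(rm_ & lab != 0L))
      stop("geometry error: region '", ref_names[i],
           "' overlaps another region")
    lab[rm_] <- lab_of(ref_names[i])
    ref_masks[[i]] <- rm_
  }

  conc <- array(0, dim = dim(lab))
  for (r in seq_len(nrow(tissues)))
    conc[lab == tissues$label[r]] <- tissues$concentration[r]

  structure(list(
    ground_truth = volume_grid(conc, g$voxel_size),
    labels = label_map(lab, g$voxel_size, tissues),
    geometry = g, tissues = tissues, seed = as.integer(seed)
  ), class = "phantom_bundle")
}

#' Tendon section and whole-tendon masks
#'
#' @param labels a `label_map` (or integer array) using the standard
#'   phantom labels.
#' @return List of logical arrays: `INS`, `MID`, `MTJ` (each including
#'   its sub-regions: tip and spots) and `AT` (whole tendon).
#' @export
tendon_section_masks <- function(labels) {
  l <- vol_values(labels)
  out <- lapply(.section_labels, function(ls) array(l %in% ls, dim = dim(l)))
  out$AT <- array(l %in% .at_labels, dim = dim(l))
  out
}

#' Surface-coil sensitivity field
#'
#' Smooth monotone falloff of the receive sensitivity with distance from
#' the coil plane: `exp(-d / d0)` with `d` the distance (mm) from the
#' plane `x = coil_plane_x`, value 1 in the plane.
#'
#' @param geometry a [phantom_geometry()] configuration.
#' @return A `volume_grid` with values in (0, 1].
#' @export
make_sensitivity <- function(geometry) {
  co <- coord_arrays(geometry)
  d <- abs(co$X - geometry$coil_plane_x)
  volume_grid(exp(-d / geometry$sens_d0), geometry$voxel_size)
}

#' Steady-state relaxation weighting factor
#'
#' Signal attenuation of a 90 degree spoiled acquisition from incomplete
#' longitudinal recovery and transverse decay at the echo time:
#' `(1 - exp(-TR/T1)) * (fs exp(-TE/T2s) + (1-fs) exp(-TE/T2l))`.
#'
#' @param relax a [relaxation_times()] object.
#' @param TR repetition time, ms.
#' @param TE echo time, ms.
#' @return Dimensionless factor in (0, 1\].
#' @export
relaxation_weight <- function(relax, TR, TE) {
  relax <- as_relaxation_times(relax)
  if (TR <= 0 || TE < 0) stop("TR must be positive and TE non-negative")
  (1 - exp(-TR / relax$T1)) *
    (relax$fs * exp(-TE / relax$T2s) + (1 - relax$fs) * exp(-TE / relax$T2l))
}

#' Apply a coil sensitivity field
#'
#' Voxel-wise product with the sensitivity map (normalized to maximum 1).
#'
#' @param volume `volume_grid` or 3D array.
#' @param sensitivity sensitivity field on the same grid.
#' @return Weighted volume, same container type as `volume`.
#' @export
apply_sensitivity <- function(volume, sensitivity) {
  v <- vol_values(volume); s <- vol_values(sensitivity)
  if (!identical(dim(v), dim(s)))
    stop("volume and sensitivity grids do not match")
  if (max(s) > 1) s <- s / max(s)   # fields at most 1 are kept as given
  vol_like(v * s, volume)
}

#' Add Rician noise at a target SNR
#'
#' The Gaussian channel noise level is `sigma = mean(volume over
#' snr_roi) / target_snr`; the output is the magnitude
#' `sqrt((v + n1)^2 + n2^2)` with independent zero-mean Gaussian
#' channels, i.e. Rician-distributed and Rayleigh in zero-signal
#' regions.
#'
#' @param volume noise-free `volume_grid` or 3D array.
#' @param target_snr desired SNR in the reference region (> 0);
#'   `Inf` returns the input unchanged with `sigma = 0`.
#' @param snr_roi logical mask defining the SNR reference region.
#' @param seed integer seed for the noise realization.
#' @return List with `volume` (noisy, same container type) and `sigma`.
#' @export
add_rician_noise <- function(volume, target_snr, snr_roi, seed = NULL) {
  v <- vol_values(volume)
  roi <- vol_values(snr_roi) != 0
  if (!any(roi)) stop("snr_roi is empty")
  if (target_snr <= 0) stop("target_snr must be positive")
  m <- mean(v[roi])
  if (m == 0) stop("zero mean signal in snr_roi")
  if (!is.finite(target_snr))
    return(list(volume = volume, sigma = 0))
  sigma <- m / target_snr
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(v)
  out <- sqrt((v + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  dim(out) <- dim(v)
  list(volume = vol_like(out, volume), sigma = sigma)
}
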