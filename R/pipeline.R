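# Per-method post-processing pipelines. The order is pinned: partial
# volume correction first, then coil sensitivity correction, then
# reference-phantom calibration and relaxation correction into aTSC.
#
# The tissue-fraction methods (none/PSSR/mLTS) operate on the native
# coarse sodium image, since they are driven by the size difference
# between segmentation and sodium grids; the spill-over methods
# (GTM/STC/eSTC) operate on the image zerofilled back to the
# segmentation grid. All aTSC maps are finally expressed on the fine
# grid (coarse maps by block replication) so they can be compared
# voxel-wise with the ground truth.

# Nearest-neighbor block replication of a coarse map onto the fine grid.
replicate_upsample <- function(arr, factor) {
  d <- dim(arr)
  idx <- lapply(d, function(n) rep(seq_len(n), each = factor))
  arr[idx[[1]], idx[[2]], idx[[3]]]
}

#' Precompute the shared quantification context for a phantom
#'
#' Builds everything the per-method pipelines reuse across noise
#' realizations: fine/coarse section masks, per-label relaxation
#' weights, sensitivity fields, fraction maps, eroded reference-phantom
#' ROIs, the GTM compartments with their transfer matrix, and the
#' target/surround compartment pair (with the averaged surround PSF)
#' used by STC and eSTC.
#'
#' @param bundle a [generate_phantom()] result.
#' @param params a [sequence_params()] object.
#' @param resolution_factor acquired-to-ground-truth voxel ratio.
#' @param sensitivity fine-grid sensitivity (default: the geometry's
#'   coil model).
#' @param kernel_halfwidth_fine PSF kernel halfwidth (voxels) on the
#'   zerofilled grid.
#' @param psf_grid_size simulation grid for the correction PSFs.
#' @param apodization reconstruction filter assumed in the PSFs.
#' @param ref_erosion erosion depth (coarse voxels) of the reference
#'   ROIs. The default 0 keeps the full majority ROI, so the reference
#'   phantoms carry their own partial volume losses into the
#'   calibration whenever a method does not correct them — the
#'   documented source of systematic tissue overestimation.
#' @param sens_cutoff only tissue within the coil-sensitive zone
#'   (sensitivity above this fraction of maximum) is segmented into the
#'   GTM compartments and the STC/eSTC surround.
#' @param kernel_halfwidth_coarse PSF kernel halfwidth (voxels) on the
#'   native coarse grid (reference-phantom recovery).
#' @param psf_override a single `psf_kernel` used in place of every
#'   simulated correction PSF (e.g. an impulse to disable spill-over
#'   modeling in degenerate-pipeline checks).
#' @return A `quantify_context` list.
#' @export
quantify_context <- function(bundle, params = sequence_params(),
                             resolution_factor = 2L, sensitivity = NULL,
                             kernel_halfwidth_fine = 15,
                             psf_grid_size = 128,
                             apodization = "hanning",
                             ref_erosion = 0L, sens_cutoff = 0.3,
                             kernel_halfwidth_coarse = 10,
                             psf_override = NULL) {
  tt <- bundle$tissues
  lab <- bundle$labels$labels
  f <- as.integer(resolution_factor)
  voxf <- bundle$ground_truth$voxel_size

  sections_fine <- tendon_section_masks(lab)

  # per-label relaxation weights (1 for labels without relaxation times)
  wmap <- rep(1, max(tt$label) + 1L)
  relax_of <- vector("list", max(tt$label) + 1L)
  for (r in seq_len(nrow(tt))) {
    if (!is.na(tt$T1[r])) {
      rl <- relaxation_times(tt$T1[r], tt$T2l[r], tt$T2s[r], tt$fs[r])
      relax_of[[tt$label[r] + 1L]] <- rl
      wmap[tt$label[r] + 1L] <- relaxation_weight(rl, params$TR, params$TE)
    }
  }

  # whole-tendon average relaxation times (voxel-weighted)
  at_labs <- intersect(.at_labels, unique(as.vector(lab)))
  nvox_l <- vapply(at_labs, function(l) sum(lab == l), 0)
  row_of <- match(at_labs, tt$label)
  combined_relax <- relaxation_times(
    T1 = sum(tt$T1[row_of] * nvox_l) / sum(nvox_l),
    T2l = sum(tt$T2l[row_of] * nvox_l) / sum(nvox_l),
    T2s = sum(tt$T2s[row_of] * nvox_l) / sum(nvox_l),
    fs = sum(tt$fs[row_of] * nvox_l) / sum(nvox_l))

  if (is.null(sensitivity)) sensitivity <- make_sensitivity(bundle$geometry)
  sens_coarse <- block_downsample(sensitivity, f)

  # coarse fraction maps over all labels; dominant label per coarse voxel
  fractions <- fraction_maps(lab, f)
  frv <- vapply(fractions$fractions, as.vector,
                numeric(length(fractions$fractions[[1]])))
  dn <- dim(fractions$fractions[[1]])
  dom_label <- array(fractions$labels[max.col(frv, ties.method = "first")],
                     dim = dn)
  sections_coarse <- lapply(.section_labels, function(ls)
    array(dom_label %in% ls, dim = dn))
  sections_coarse$AT <- array(dom_label %in% .at_labels, dim = dn)

  # reference-phantom ROIs on the coarse grid (majority downsizing)
  ref_rows <- which(tt$group == "reference")
  ref_labs <- tt$label[ref_rows]
  ref_masks <- lapply(ref_rows, function(r) {
    m <- block_downsample(array(as.numeric(lab == tt$label[r]), dim = dim(lab)),
                          f) >= 0.5
    if (ref_erosion > 0L) {
      me <- erode_mask(m, ref_erosion)
      if (any(me)) m <- me
    }
    m
  })
  ref_concs <- tt$concentration[ref_rows]
  ref_relax <- relaxation_times(tt$T1[ref_rows[1]], tt$T2l[ref_rows[1]],
                                tt$T2s[ref_rows[1]], tt$fs[ref_rows[1]])

  # fine masks and volume ratios of the reference rods (PSSR on refs)
  ref_fine <- lapply(ref_labs, function(l) lab == l)
  ref_vps <- vapply(seq_along(ref_masks), function(i)
    min(1, (sum(ref_fine[[i]]) * voxf^3) /
          (sum(ref_masks[[i]]) * (voxf * f)^3)), 0)

  # recovery field of the rods at the native grid: RSF of the
  # high-resolution (fractional) rod support, so dividing by it undoes
  # both the edge tissue fraction and the spill-out of the isolated
  # rods — a one-compartment GTM per rod, as the spill-over methods
  # apply it to the references
  agar_psf_coarse <- if (!is.null(psf_override)) psf_override
  else simulate_psf(ref_relax, params, apodization,
                    kernel_halfwidth = kernel_halfwidth_coarse,
                    voxel_size = voxf * f,
                    grid_size = psf_grid_size)
  ref_frac_union <- block_downsample(
    array(as.numeric(lab %in% ref_labs), dim = dim(lab)), f)
  ref_rsf <- conv3d(ref_frac_union, agar_psf_coarse)

  # tendon neighborhood and reference ROIs: where mLTS must be fitted
  at_frac <- Reduce(`+`, fractions$fractions[as.character(
    intersect(.at_labels, fractions$labels))])
  ref_frac <- Reduce(`+`, fractions$fractions[as.character(
    intersect(ref_labs, fractions$labels))])
  mlts_subset <- at_frac > 0 | ref_frac > 0

  # coil-sensitive zone: only tissue the coil actually sees is
  # segmented into compartments
  if (is.null(sensitivity)) sensitivity <- make_sensitivity(bundle$geometry)
  sens_zone <- vol_values(sensitivity) / max(vol_values(sensitivity)) >=
    sens_cutoff

  # GTM compartments: every signal-bearing tissue class, own PSF each
  gtm_labs <- tt$label[!is.na(tt$T1) & tt$group %in% c("tendon", "surround")]
  gtm_labs <- intersect(gtm_labs, unique(as.vector(lab)))
  gtm_masks <- lapply(gtm_labs, function(l) lab == l & sens_zone)
  names(gtm_masks) <- tt$tissue[match(gtm_labs, tt$label)]
  keep <- vapply(gtm_masks, any, TRUE)
  gtm_masks <- gtm_masks[keep]; gtm_labs <- gtm_labs[keep]
  gtm_psfs <- if (!is.null(psf_override)) rep(list(psf_override),
                                              length(gtm_labs))
  else lapply(gtm_labs, function(l)
    simulate_psf(relax_of[[l + 1L]], params, apodization,
                 kernel_halfwidth = kernel_halfwidth_fine,
                 voxel_size = voxf, grid_size = psf_grid_size))
  gtm_set <- compartment_set(gtm_masks, gtm_psfs)
  gtm_W <- gtm_weight_matrix(gtm_set)
  # keep only what the per-iteration solve needs
  gtm_ctx <- list(masks = gtm_set$masks, W = gtm_W, labels = gtm_labs)
  rm(gtm_set)

  # STC/eSTC compartments: whole tendon vs averaged soft-tissue surround
  at_mask <- sections_fine$AT
  sur_labs <- tt$label[tt$group == "surround"]
  sur_mask <- array(lab %in% sur_labs, dim = dim(lab)) & sens_zone
  tar_psf <- if (!is.null(psf_override)) psf_override
  else simulate_psf(combined_relax, params, apodization,
                    kernel_halfwidth = kernel_halfwidth_fine,
                    voxel_size = voxf, grid_size = psf_grid_size)
  sur_rows <- match(sur_labs, tt$label)
  sur_specs <- lapply(sur_rows, function(r)
    relaxation_times(tt$T1[r], tt$T2l[r], tt$T2s[r], tt$fs[r]))
  sur_psf <- if (!is.null(psf_override)) psf_override
  else surround_psf(sur_specs, params, apodization = apodization,
                    kernel_halfwidth = kernel_halfwidth_fine,
                    voxel_size = voxf, grid_size = psf_grid_size)
  stc_set <- compartment_set(list(AT = at_mask, surround = sur_mask),
                             list(tar_psf, sur_psf), surround = "surround")

  structure(list(
    tissues = tt, params = params, factor = f, voxel_fine = voxf,
    lab = lab, dim_fine = dim(lab), dim_coarse = dn,
    sections_fine = sections_fine, sections_coarse = sections_coarse,
    dom_label = dom_label, fractions = fractions,
    mlts_subset = mlts_subset,
    wmap = wmap, relax_of = relax_of, combined_relax = combined_relax,
    sens_fine = vol_values(sensitivity) / max(vol_values(sensitivity)),
    sens_coarse = vol_values(sens_coarse) / max(vol_values(sens_coarse)),
    ref_masks = ref_masks, ref_concs = ref_concs, ref_relax = ref_relax,
    ref_labs = ref_labs, ref_vps = ref_vps, ref_rsf = ref_rsf,
    gtm = gtm_ctx, stc_set = stc_set
  ), class = "quantify_context")
}

# GTM weight matrix W_ij = mean over mask i of full-field RSF j.
gtm_weight_matrix <- function(cs) {
  K <- length(cs$masks)
  W <- matrix(0, K, K, dimnames = list(names(cs$masks), names(cs$masks)))
  for (i in seq_len(K))
    for (j in seq_len(K))
      W[i, j] <- mean(cs$rsf_full[[j]][cs$masks[[i]]])
  W
}

#' Calibrate from the reference phantoms of an acquired image
#'
#' Measures the reference-phantom ROI means on the native image with
#' the same partial volume correction that is being applied to the
#' tissues, corrects for coil sensitivity and agarose relaxation, and
#' fits the calibration line. Without PVC the reference rods are
#' underestimated by their own spill-out, which shrinks the slope and
#' systematically inflates all tissue aTSCs — the dominant uncorrected
#' bias.
#'
#' Per-method reference treatment: `none` uses the raw ROI means;
#' `pssr` subtracts the (near-zero) surround contribution; `mlts` uses
#' the unmixed per-tissue composite (pass the fitted `mlts_result`);
#' `gtm`, `stc` and `estc` divide by the rods' region spread function —
#' for the isolated rods this equals a one-compartment GTM and a pure
#' recovery division, respectively.
#'
#' @param native coarse sodium image (`volume_grid` or 3D array).
#' @param ctx a [quantify_context()].
#' @param method correction method whose reference treatment to apply.
#' @param mlts_result an `mlts_result` covering the reference ROIs
#'   (required for `method = "mlts"`).
#' @param rsf_floor clamp for the recovery division.
#' @return A `calibration_fit`.
#' @export
calibrate_references <- function(native, ctx, method = "none",
                                 mlts_result = NULL, rsf_floor = 0.05) {
  v <- vol_values(native)
  sens <- ctx$sens_coarse
  roi_mean <- function(sig, m) mean((sig / sens)[m], na.rm = TRUE)

  ref_means <- switch(
    method,
    none = vapply(ctx$ref_masks, function(m) roi_mean(v, m), 0),
    pssr = vapply(seq_along(ctx$ref_masks), function(i) {
      m <- ctx$ref_masks[[i]]
      S_m <- mean(v[m])
      S_sur <- surrounding_mean(v, m)
      C <- pssr_correct(S_m, S_sur, ctx$ref_vps[i])
      roi_mean(v, m) * (C / S_m)
    }, 0),
    mlts = {
      if (is.null(mlts_result))
        stop("reference calibration for mLTS needs the fitted mlts_result")
      comp <- mlts_result$corrected
      vapply(seq_along(ctx$ref_masks), function(i) {
        m <- ctx$ref_masks[[i]] & !is.na(comp) &
          mlts_result$dominant == ctx$ref_labs[i]
        if (!any(m)) m <- ctx$ref_masks[[i]]
        roi_mean(ifelse(is.na(comp), v, comp), m)
      }, 0)
    },
    # gtm / stc / estc: recovery (RSF) division of the isolated rods
    vapply(ctx$ref_masks, function(m)
      roi_mean(v / pmax(ctx$ref_rsf, rsf_floor), m), 0)
  )
  ref_means <- relaxation_correct(ref_means, ctx$ref_relax,
                                  ctx$params$TR, ctx$params$TE)
  calibrate(ref_means, ctx$ref_concs)
}

# Shared tail of every pipeline: sensitivity correction, per-voxel
# relaxation correction by label, calibration into mM; plus the
# combined whole-tendon value from the average signal and average
# relaxation times.
finish_map <- function(signal, grid = c("fine", "coarse"), domain, ctx, fit) {
  grid <- match.arg(grid)
  sens <- if (grid == "fine") ctx$sens_fine else ctx$sens_coarse
  labf <- if (grid == "fine") ctx$lab
  else array(ctx$dom_label, dim = ctx$dim_coarse)
  sc <- sensitivity_correct(signal, sens)
  v <- vol_values(sc$volume)
  at <- if (grid == "fine") ctx$sections_fine$AT else ctx$sections_coarse$AT
  comb_sig <- mean(v[at & domain], na.rm = TRUE)
  combined <- to_atsc(relaxation_correct(comb_sig, ctx$combined_relax,
                                         ctx$params$TR, ctx$params$TE), fit)
  v <- v / array(ctx$wmap[labf + 1L], dim = dim(v))
  atsc <- to_atsc(v, fit)
  atsc[!domain | sc$flagged] <- NA_real_
  list(map = atsc, combined = combined)
}

#' Correct an acquired image and quantify aTSC with one method
#'
#' Runs the full post-processing chain of a single method: partial
#' volume correction, coil sensitivity correction, reference
#' calibration and relaxation correction into an aTSC map, plus the
#' combined whole-tendon value. See [evaluate_iteration()] to run
#' several methods on one image efficiently.
#'
#' @param native coarse sodium image (`volume_grid` or 3D array).
#' @param ctx a [quantify_context()].
#' @param method one of `"none"`, `"pssr"`, `"mlts"`, `"gtm"`,
#'   `"stc"`, `"estc"`.
#' @param zerofilled optional precomputed zerofilled image (fine grid).
#' @param fit optional precomputed [calibrate_references()] result.
#' @param stc_tol,stc_max_iter STC convergence controls.
#' @return A `method_result`: `method`, `map` (aTSC on the method's
#'   grid), `map_fine` (aTSC replicated onto the fine grid), `grid`,
#'   `combined`, `report` (ROI statistics), `extras` (method
#'   diagnostics).
#' @export
correct_and_quantify <- function(native, ctx,
                                 method = c("none", "pssr", "mlts", "gtm",
                                            "stc", "estc"),
                                 zerofilled = NULL,
                                 stc_tol = 1e-4, stc_max_iter = 100L) {
  method <- match.arg(method)
  v <- vol_values(native)
  needs_zf <- method %in% c("gtm", "stc", "estc")
  if (needs_zf && is.null(zerofilled))
    zerofilled <- zerofill(v, ctx$factor)
  zf <- if (needs_zf) vol_values(zerofilled)
  extras <- list()
  # each method applies its own correction to the reference phantoms
  fit <- if (method != "mlts") calibrate_references(v, ctx, method)

  if (method == "none") {
    fm <- finish_map(v, "coarse", ctx$sections_coarse$AT, ctx, fit)
  } else if (method == "pssr") {
    sig <- v
    for (nm in c("INS", "MID", "MTJ")) {
      roi <- ctx$sections_coarse[[nm]]
      fine <- ctx$sections_fine[[nm]]
      S_m <- mean(v[roi])
      S_sur <- surrounding_mean(v, roi)
      v_PS <- suppressWarnings(
        volume_ratio(fine, roi, highres_voxel = ctx$voxel_fine,
                     lowres_voxel = ctx$voxel_fine * ctx$factor))
      C <- pssr_correct(S_m, S_sur, min(v_PS, 1))
      sig <- vol_values(regionwise_map(sig, roi, C, S_m))
      extras[[nm]] <- list(S_m = S_m, S_sur = S_sur, v_PS = v_PS, C = C)
    }
    fm <- finish_map(sig, "coarse", ctx$sections_coarse$AT, ctx, fit)
  } else if (method == "mlts") {
    res <- suppressWarnings(
      mlts_correct(v, ctx$fractions, subset = ctx$mlts_subset))
    fit <- calibrate_references(v, ctx, "mlts", mlts_result = res)
    sig <- res$corrected
    domain <- ctx$sections_coarse$AT & !is.na(sig)
    sig[is.na(sig)] <- 0
    fm <- finish_map(sig, "coarse", domain, ctx, fit)
    extras$negative <- sum(res$negative)
  } else if (method == "gtm") {
    K <- length(ctx$gtm$masks)
    m <- vapply(seq_len(K), function(i) mean(zf[ctx$gtm$masks[[i]]]), 0)
    T_ <- solve(ctx$gtm$W, m)
    sig <- zf
    for (i in seq_len(K))
      if (m[i] != 0)
        sig <- vol_values(regionwise_map(sig, ctx$gtm$masks[[i]], T_[i], m[i]))
    fm <- finish_map(sig, "fine", ctx$sections_fine$AT, ctx, fit)
    extras$means <- stats::setNames(T_, names(ctx$gtm$masks))
  } else { # stc / estc
    if (method == "stc") {
      res <- stc_correct(zf, ctx$stc_set, tol = stc_tol,
                         max_iter = stc_max_iter)
      extras$iterations <- res$iterations
      extras$converged <- res$converged
      extras$oscillation <- res$oscillation
    } else {
      res <- estc_correct(zf, ctx$stc_set)
      extras$fallback <- res$fallback
    }
    domain <- ctx$sections_fine$AT & !res$flagged
    fm <- finish_map(res$corrected, "fine", domain, ctx, fit)
  }

  grid <- if (needs_zf) "fine" else "coarse"
  map_fine <- if (grid == "fine") fm$map
  else replicate_upsample(fm$map, ctx$factor)
  report <- roi_statistics(fm$map,
                           if (grid == "fine") ctx$sections_fine
                           else ctx$sections_coarse,
                           combined = fm$combined)
  structure(list(method = method, map = fm$map, map_fine = map_fine,
                 grid = grid, combined = fm$combined, report = report,
                 fit = fit, extras = extras),
            class = "method_result")
}

#' Run several correction methods on one acquired image
#'
#' Shares the zerofilled image across methods, then runs
#' [correct_and_quantify()] for each (every method calibrates its own
#' reference treatment).
#'
#' @param native coarse sodium image.
#' @param ctx a [quantify_context()].
#' @param methods character vector of method names.
#' @param ... passed to [correct_and_quantify()].
#' @return Named list of `method_result`s.
#' @export
evaluate_iteration <- function(native, ctx,
                               methods = c("none", "pssr", "mlts", "gtm",
                                           "stc", "estc"), ...) {
  v <- vol_values(native)
  zf <- if (any(methods %in% c("gtm", "stc", "estc")))
    zerofill(v, ctx$factor)
  out <- lapply(methods, function(m)
    correct_and_quantify(v, ctx, m, zerofilled = zf, ...))
  names(out) <- methods
  out
}
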