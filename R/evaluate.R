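# Monte Carlo evaluation harness: compares every correction method
# against the ground truth, reporting mean voxel-wise differences
# (positive = overestimation) with across-iteration SDs, noise-free
# per-voxel SDs, and the RMSE over all tendon voxels.

#' Mean voxel-wise difference to ground truth
#'
#' Mean and SD of `map - truth` over an ROI; positive values are
#' overestimation. NA map voxels (outside the mapped region) are
#' excluded.
#'
#' @param atsc_map aTSC map (mM).
#' @param truth ground-truth concentration volume on the same grid.
#' @param roi logical ROI mask.
#' @return List with `mean`, `sd` (over ROI voxels) and `n`.
#' @export
voxelwise_difference <- function(atsc_map, truth, roi) {
  m <- vol_values(atsc_map); tr <- vol_values(truth)
  if (!identical(dim(m), dim(tr)))
    stop("map and ground-truth grids do not match")
  r <- vol_values(roi) != 0
  d <- (m - tr)[r]
  list(mean = mean(d, na.rm = TRUE), sd = stats::sd(d, na.rm = TRUE),
       n = sum(!is.na(d)))
}

#' Root mean square error over an ROI
#'
#' @param atsc_map aTSC map (mM).
#' @param truth ground-truth concentration volume on the same grid.
#' @param roi logical ROI mask (non-empty).
#' @return RMSE in mM.
#' @export
rmse_over_roi <- function(atsc_map, truth, roi) {
  m <- vol_values(atsc_map); tr <- vol_values(truth)
  if (!identical(dim(m), dim(tr)))
    stop("map and ground-truth grids do not match")
  r <- vol_values(roi) != 0
  if (!any(r)) stop("ROI is empty")
  d <- (m - tr)[r]
  sqrt(mean(d^2, na.rm = TRUE))
}

#' Monte Carlo evaluation configuration
#'
#' @param n_iterations noise realizations per SNR level (recycled to
#'   the number of SNR levels, so each level can use its own count).
#' @param snr SNR levels in the MID reference region.
#' @param methods correction methods to evaluate.
#' @param seed base seed; iteration `i` uses `seed + i`.
#' @param geometry phantom geometry (default: the 96-voxel preset used
#'   for desk-scale evaluation).
#' @param tissues tissue table.
#' @param params sequence parameters.
#' @param resolution_factor acquired-to-ground-truth voxel ratio.
#' @param stc_tol,stc_max_iter STC convergence controls.
#' @param psf_grid_size simulation grid for all PSFs.
#' @return An `evaluation_config` list.
#' @export
evaluation_config <- function(n_iterations = 20L, snr = 10,
                              methods = c("none", "pssr", "mlts", "gtm",
                                          "stc", "estc"),
                              seed = 1L,
                              geometry = phantom_geometry(preset = "small"),
                              tissues = tissue_table(),
                              params = sequence_params(),
                              resolution_factor = 2L,
                              stc_tol = 1e-4, stc_max_iter = 100L,
                              psf_grid_size = 128) {
  stopifnot(all(n_iterations >= 1L), all(snr > 0))
  n_iterations <- rep_len(as.integer(n_iterations), length(snr))
  structure(list(n_iterations = n_iterations, snr = snr,
                 methods = methods, seed = as.integer(seed),
                 geometry = geometry, tissues = tissues, params = params,
                 resolution_factor = as.integer(resolution_factor),
                 stc_tol = stc_tol, stc_max_iter = as.integer(stc_max_iter),
                 psf_grid_size = psf_grid_size),
            class = "evaluation_config")
}

#' Run the Monte Carlo evaluation
#'
#' Generates the phantom, simulates the noise-free corrupted
#' acquisition once, evaluates every configured method on it, then adds
#' `n_iterations` independent Rician noise realizations per SNR level
#' (iteration `i` is seeded `seed + i`) and re-evaluates. Method
#' failures in single iterations are recorded, not fatal.
#'
#' @param config an [evaluation_config()].
#' @param progress print per-iteration progress lines.
#' @return An `evaluation_report`: `noise_free` (data frame: per
#'   method and ROI, mean voxel difference, per-voxel SD, RMSE over the
#'   tendon), `monte_carlo` (per method, ROI and SNR: mean of the
#'   per-iteration ROI mean differences, their SD across iterations,
#'   mean RMSE), `per_iteration` (the un-aggregated per-iteration ROI
#'   means), `convergence` (STC iteration counts), `errors`, `config`.
#' @export
run_monte_carlo <- function(config = evaluation_config(), progress = FALSE) {
  cf <- config
  bundle <- generate_phantom(cf$geometry, cf$tissues, seed = cf$seed)
  sensitivity <- make_sensitivity(cf$geometry)
  groups <- mixed_label_groups(bundle$labels, cf$resolution_factor,
                               cf$tissues)
  bank <- build_psf_bank(groups, cf$tissues, cf$params,
                         kernel_halfwidth = 10,
                         voxel_size = bundle$ground_truth$voxel_size *
                           cf$resolution_factor,
                         grid_size = cf$psf_grid_size)
  dn <- dim(bundle$ground_truth$values) %/% cf$resolution_factor
  fplans <- spillover_plans(bank, dn)
  ctx <- quantify_context(bundle, cf$params,
                          resolution_factor = cf$resolution_factor,
                          sensitivity = sensitivity,
                          psf_grid_size = cf$psf_grid_size)
  truth <- bundle$ground_truth$values
  rois <- c("INS", "MID", "MTJ", "combined")
  roi_mask <- function(nm) if (nm == "combined") ctx$sections_fine$AT
  else ctx$sections_fine[[nm]]

  eval_maps <- function(results) {
    do.call(rbind, lapply(names(results), function(me) {
      mf <- results[[me]]$map_fine
      do.call(rbind, lapply(rois, function(nm) {
        vd <- voxelwise_difference(mf, truth, roi_mask(nm))
        data.frame(method = me, roi = nm, mean_diff = vd$mean,
                   sd_vox = vd$sd, n = vd$n)
      }))
    }))
  }

  # noise-free acquisition (shared blurred image for all noise draws)
  acq0 <- simulate_acquisition(bundle, cf$params,
                               resolution_factor = cf$resolution_factor,
                               target_snr = Inf, sensitivity = sensitivity,
                               psf_bank = bank, groups = groups,
                               conv_plans = fplans, seed = cf$seed)
  res0 <- evaluate_iteration(acq0$noise_free, ctx, cf$methods,
                             stc_tol = cf$stc_tol,
                             stc_max_iter = cf$stc_max_iter)
  noise_free <- eval_maps(res0)
  noise_free$rmse <- NA_real_
  for (me in names(res0))
    noise_free$rmse[noise_free$method == me] <-
    rmse_over_roi(res0[[me]]$map_fine, truth, ctx$sections_fine$AT)

  # Monte Carlo noise realizations
  mc_rows <- list()
  conv_rows <- list()
  err_rows <- list()
  iter_rows <- list()
  for (si in seq_along(cf$snr)) {
    sn <- cf$snr[si]
    per_iter <- list()
    for (it in seq_len(cf$n_iterations[si])) {
      sd_it <- cf$seed + it
      noisy <- add_rician_noise(acq0$noise_free, sn, acq0$snr_roi,
                                seed = sd_it)
      res <- tryCatch(
        evaluate_iteration(noisy$volume, ctx, cf$methods,
                           stc_tol = cf$stc_tol,
                           stc_max_iter = cf$stc_max_iter),
        error = function(e) e)
      if (inherits(res, "error")) {
        err_rows[[length(err_rows) + 1L]] <-
          data.frame(snr = sn, iteration = it, message = conditionMessage(res))
        next
      }
      df <- eval_maps(res)
      df$iteration <- it
      df$rmse <- NA_real_
      for (me in names(res)) {
        df$rmse[df$method == me] <-
          rmse_over_roi(res[[me]]$map_fine, truth, ctx$sections_fine$AT)
        if (me == "stc")
          conv_rows[[length(conv_rows) + 1L]] <-
          data.frame(snr = sn, iteration = it,
                     iterations = res$stc$extras$iterations,
                     converged = res$stc$extras$converged,
                     oscillation = res$stc$extras$oscillation)
      }
      per_iter[[it]] <- df
      if (progress)
        message(sprintf("snr %g iteration %d/%d done", sn, it,
                        cf$n_iterations[si]))
    }
    all_it <- do.call(rbind, per_iter)
    all_it$snr <- sn
    iter_rows[[length(iter_rows) + 1L]] <- all_it
    agg <- do.call(rbind, lapply(split(
      all_it, list(all_it$method, all_it$roi), drop = TRUE),
      function(g) data.frame(method = g$method[1], roi = g$roi[1], snr = sn,
                             mean_diff = mean(g$mean_diff),
                             sd_iter = stats::sd(g$mean_diff),
                             rmse = mean(g$rmse),
                             n_iter = nrow(g))))
    mc_rows[[length(mc_rows) + 1L]] <- agg
  }
  mc <- do.call(rbind, mc_rows)
  rownames(mc) <- NULL

  structure(list(noise_free = noise_free, monte_carlo = mc,
                 per_iteration = if (length(iter_rows)) {
                   pi_ <- do.call(rbind, iter_rows)
                   rownames(pi_) <- NULL
                   pi_
                 },
                 convergence = if (length(conv_rows))
                   do.call(rbind, conv_rows) else NULL,
                 errors = if (length(err_rows))
                   do.call(rbind, err_rows) else NULL,
                 reports_noise_free = lapply(res0, `[[`, "report"),
                 config = cf),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n\nNoise-free mean voxel differences (mM):\n")
  nf <- x$noise_free
  print(format(nf[nf$roi == "combined",
                  c("method", "mean_diff", "sd_vox", "rmse")],
               digits = 3), row.names = FALSE)
  if (!is.null(x$monte_carlo)) {
    cat("\nMonte Carlo combined differences (mM):\n")
    mc <- x$monte_carlo
    print(format(mc[mc$roi == "combined",
                    c("method", "snr", "mean_diff", "sd_iter", "rmse")],
                 digits = 3), row.names = FALSE)
  }
  invisible(x)
}
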