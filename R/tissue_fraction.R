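# Tissue-fraction partial volume corrections.
#
# Coarse sodium voxels average the signal of every high-resolution
# tissue they cover. The region-level PSSR correction removes the
# contribution of signal from outside the high-resolution segmentation
# using the volume ratio of the two segmentations; the voxel-level
# 3D-mLTS correction unmixes per-tissue intensities by robust linear
# regression on per-voxel tissue fractions.

#' Volume ratio between two segmentations
#'
#' Ratio of the physical volume of the high-resolution segmentation to
#' that of its coarse (sodium-grid) counterpart; the coarse mask is the
#' larger one in practice, making the ratio the fraction of the coarse
#' ROI actually covered by tissue.
#'
#' @param highres_mask logical mask (or `volume_grid`) on the fine grid.
#' @param lowres_mask logical mask on the coarse grid.
#' @param highres_voxel,lowres_voxel voxel sizes in mm; taken from the
#'   containers when available.
#' @return The volume ratio `v_PS` (warns when > 1).
#' @export
volume_ratio <- function(highres_mask, lowres_mask,
                         highres_voxel = vol_voxel_size(highres_mask),
                         lowres_voxel = vol_voxel_size(lowres_mask)) {
  hv <- sum(vol_values(highres_mask) != 0) * highres_voxel^3
  lv <- sum(vol_values(lowres_mask) != 0) * lowres_voxel^3
  if (hv == 0) stop("high-resolution mask is empty")
  if (lv == 0) stop("low-resolution mask is empty")
  v <- hv / lv
  if (v > 1)
    warning("volume ratio exceeds 1: the low-resolution mask is smaller ",
            "than the high-resolution content")
  v
}

#' Mean signal of the voxels immediately surrounding an ROI
#'
#' Mean over the one-voxel 26-connected dilation shell of the ROI.
#'
#' @param image `volume_grid` or 3D array.
#' @param roi_mask logical ROI mask on the same grid.
#' @return Mean shell signal.
#' @export
surrounding_mean <- function(image, roi_mask) {
  v <- vol_values(image)
  m <- vol_values(roi_mask) != 0
  if (!any(m)) stop("ROI mask is empty")
  shell <- mask_shell(m)
  if (!any(shell)) stop("ROI has no surrounding shell inside the grid")
  mean(v[shell])
}

#' Region-level tissue-fraction correction (PSSR)
#'
#' Corrected mean ROI signal
#' `C = S_m - S_sur * (1 - v_PS) / v_PS`:
#' the fraction `1 - v_PS` of the coarse ROI volume lies outside the
#' high-resolution segmentation and contributes surround signal, which
#' is subtracted before rescaling. With `v_PS = 1` or `S_sur = 0` (the
#' original zero-signal-surroundings formulation) the measured mean is
#' returned unchanged.
#'
#' @param S_m mean measured ROI signal.
#' @param S_sur mean signal of the immediate surroundings.
#' @param v_PS volume ratio in (0, 1].
#' @return Corrected mean signal (may be negative; warned, not clamped).
#' @export
pssr_correct <- function(S_m, S_sur, v_PS) {
  if (v_PS <= 0) stop("v_PS must be positive")
  C <- S_m - S_sur * (1 - v_PS) / v_PS
  if (C < 0) warning("PSSR-corrected signal is negative")
  C
}

#' Per-tissue fraction maps at a coarse resolution
#'
#' Share of each tissue class inside every coarse voxel, computed by
#' block-averaging the high-resolution label indicators. Fractions
#' partition unity at every voxel (background counts as class 0).
#'
#' @param labels high-resolution `label_map` or integer array.
#' @param factor integer downscale factor.
#' @param keep_labels optional subset of labels; others (and background)
#'   are pooled into class 0.
#' @return A `fraction_maps` list: `fractions` (named list of coarse 3D
#'   arrays), `labels` (integer vector, 0 = pooled background).
#' @export
fraction_maps <- function(labels, factor, keep_labels = NULL) {
  l <- vol_values(labels)
  if (any(dim(l) %% factor != 0L))
    stop("grid edges ", paste(dim(l), collapse = "x"),
         " not divisible by factor ", factor)
  present <- sort(unique(as.vector(l)))
  if (is.null(keep_labels)) keep_labels <- setdiff(present, 0L)
  fr <- list()
  rest <- array(0, dim = dim(l) %/% factor)
  for (lb in keep_labels) {
    f <- block_downsample(array(as.numeric(l == lb), dim = dim(l)), factor)
    fr[[as.character(lb)]] <- f
    rest <- rest + f
  }
  f0 <- 1 - rest
  f0[abs(f0) < 1e-12] <- 0
  fr <- c(list("0" = f0), fr)
  structure(list(fractions = fr, labels = c(0L, as.integer(keep_labels))),
            class = "fraction_maps")
}

# Retain the h samples with smallest |residual|; ties broken by sample
# order (lowest kernel index first).
lts_retain <- function(resid, h) {
  ord <- order(abs(resid), seq_along(resid))
  sort(ord[seq_len(h)])
}

# Least-squares fit of y ~ X (no intercept) on the rows in 'keep';
# returns NULL when the design is rank deficient.
ls_fit <- function(X, y, keep) {
  Xk <- X[keep, , drop = FALSE]
  qr_ <- qr(Xk)
  if (qr_$rank < ncol(Xk)) return(NULL)
  qr.coef(qr_, y[keep])
}

#' Voxel-level tissue-fraction correction (3D-mLTS)
#'
#' At every voxel, the signals of the 3 x 3 x 3 kernel centered there
#' are modeled as `y = sum_i f_i T_i` with locally constant per-tissue
#' intensities `T_i` and known tissue fractions `f_i`. The intensities
#' are fitted by least-trimmed-squares regression: fit on all kernel
#' samples, retain the `h = round((1 - trimming) * n)` samples with the
#' smallest absolute residuals (ties broken by kernel sample order),
#' refit, and repeat until the retained subset is stable. Kernels are
#' clipped at the grid boundary, shrinking `n` accordingly. When
#' trimming leaves the design rank deficient the untrimmed fit is kept
#' and flagged; a voxel whose untrimmed design is still rank deficient
#' is marked invalid. Negative fitted intensities are kept and flagged,
#' not clamped.
#'
#' @param image coarse sodium image (`volume_grid` or 3D array).
#' @param fractions a [fraction_maps()] result on the same grid.
#' @param trimming fraction of kernel samples discarded (default 0.4).
#' @param kernel kernel edge length (odd, default 3).
#' @param max_iter maximum subset-reselection iterations.
#' @param subset optional logical mask restricting the voxels at which
#'   intensities are fitted (e.g. the tendon neighborhood); default all.
#' @return An `mlts_result`: `intensity` (named list of per-tissue
#'   fitted intensity arrays, NA where the tissue is absent from the
#'   kernel or the voxel is outside `subset`), `corrected` (array:
#'   fitted intensity of each voxel's dominant tissue), `dominant`
#'   (label array), `untrimmed` and `invalid` (flag arrays), `negative`
#'   (any fitted intensity negative).
#' @export
mlts_correct <- function(image, fractions, trimming = 0.4, kernel = 3L,
                         max_iter = 25L, subset = NULL) {
  v <- vol_values(image)
  fr <- fractions$fractions
  labs <- fractions$labels
  d <- dim(v)
  if (!identical(dim(fr[[1]]), d))
    stop("fraction maps and image grids do not match")
  if (kernel %% 2L != 1L) stop("kernel must be odd")
  hw <- (kernel - 1L) %/% 2L
  p_all <- length(fr)
  if (is.null(subset)) subset <- array(TRUE, dim = d)
  vox <- which(vol_values(subset) != 0)
  nsub <- length(vox)
  if (!nsub) stop("'subset' selects no voxels")

  # presence of each tissue anywhere in the kernel (full grid, cheap)
  present_full <- vapply(fr, function(f) as.vector(dilate_mask(f > 0, hw, "26")),
                         logical(length(v)))
  present <- present_full[vox, , drop = FALSE]
  n_pres <- rowSums(present)

  # kernel sample linear indices per subset voxel (NA outside the grid)
  off <- as.matrix(expand.grid(dx = -hw:hw, dy = -hw:hw, dz = -hw:hw))
  nk <- nrow(off)
  co <- arrayInd(vox, d)
  LIN <- matrix(NA_integer_, nk, nsub)
  for (r in seq_len(nk)) {
    i <- co[, 1] + off[r, 1]; j <- co[, 2] + off[r, 2]; k <- co[, 3] + off[r, 3]
    ok <- i >= 1L & i <= d[1] & j >= 1L & j <= d[2] & k >= 1L & k <= d[3]
    lin <- (k - 1L) * d[1] * d[2] + (j - 1L) * d[1] + i
    lin[!ok] <- NA_integer_
    LIN[r, ] <- lin
  }
  Y <- matrix(v[LIN], nk, nsub)

  intensity <- lapply(seq_len(p_all), function(i) array(NA_real_, dim = d))
  names(intensity) <- names(fr)
  untrimmed <- array(FALSE, dim = d)
  invalid <- array(FALSE, dim = d)

  # --- single-tissue kernels: partition of unity makes f identically 1,
  # so the model is a constant and LTS reduces to a trimmed location fit
  single <- which(n_pres == 1L)
  if (length(single)) {
    ti_of <- max.col(present[single, , drop = FALSE], ties.method = "first")
    ycols <- Y[, single, drop = FALSE]
    w <- !is.na(ycols)
    nv <- colSums(w)
    h <- pmax(1L, as.integer(round((1 - trimming) * nv)))
    y0 <- ycols; y0[!w] <- 0
    keep <- w
    Tfit <- colSums(y0 * keep) / colSums(keep)
    active <- seq_along(single)
    for (it in seq_len(max_iter)) {
      if (!length(active)) break
      changed <- logical(length(active))
      for (ai in seq_along(active)) {
        q <- active[ai]
        r <- abs(y0[, q] - Tfit[q]); r[!w[, q]] <- Inf
        ord <- order(r, seq_len(nk))
        kq <- logical(nk); kq[ord[seq_len(h[q])]] <- TRUE
        if (any(kq != keep[, q])) {
          keep[, q] <- kq
          changed[ai] <- TRUE
        }
      }
      active <- active[changed]
      if (length(active))
        Tfit[active] <- colSums(y0[, active, drop = FALSE] *
                                  keep[, active, drop = FALSE]) /
          colSums(keep[, active, drop = FALSE])
    }
    for (ti in unique(ti_of)) {
      sel <- ti_of == ti
      intensity[[ti]][vox[single[sel]]] <- Tfit[sel]
    }
  }

  # --- multi-tissue kernels: per-voxel trimmed least squares
  multi <- which(n_pres > 1L)
  for (qq in multi) {
    cols <- which(present[qq, ])
    valid <- which(!is.na(Y[, qq]))
    lin <- LIN[valid, qq]
    X <- vapply(cols, function(ci) fr[[ci]][lin], numeric(length(valid)))
    y <- Y[valid, qq]
    n <- length(y)
    h <- max(length(cols), as.integer(round((1 - trimming) * n)))
    keep <- seq_len(n)
    beta <- ls_fit(X, y, keep)
    if (is.null(beta)) { invalid[vox[qq]] <- TRUE; next }
    flagged <- FALSE
    for (it in seq_len(max_iter)) {
      resid <- y - as.vector(X %*% beta)
      ord <- order(abs(resid), seq_len(n))
      # smallest-residual subset of size h, grown minimally (next by
      # residual order) whenever trimming leaves the design unidentifiable
      ext <- h
      repeat {
        newkeep <- sort(ord[seq_len(ext)])
        beta2 <- ls_fit(X, y, newkeep)
        if (!is.null(beta2) || ext == n) break
        ext <- ext + 1L
      }
      if (is.null(beta2)) { flagged <- TRUE; break }  # even untrimmed deficient
      if (ext > h) flagged <- TRUE
      stable <- identical(newkeep, keep)
      keep <- newkeep
      beta <- beta2
      if (stable && it > 1L) break
    }
    untrimmed[vox[qq]] <- flagged
    for (ci in seq_along(cols))
      intensity[[cols[ci]]][vox[qq]] <- beta[ci]
  }

  # dominant tissue per voxel and composite corrected image
  frv <- matrix(vapply(fr, function(f) f[vox], numeric(nsub)),
                nrow = nsub, ncol = p_all)
  dom <- max.col(frv, ties.method = "first")
  corrected <- array(NA_real_, dim = d)
  dominant <- array(NA_integer_, dim = d)
  for (ti in seq_len(p_all)) {
    sel <- vox[dom == ti]
    corrected[sel] <- intensity[[ti]][sel]
    dominant[sel] <- labs[ti]
  }
  negative <- array(FALSE, dim = d)
  for (ti in seq_len(p_all))
    negative <- negative | (!is.na(intensity[[ti]]) & intensity[[ti]] < 0)
  if (any(negative))
    warning("mLTS fitted negative intensities at ", sum(negative), " voxels")

  structure(list(intensity = intensity,
                 corrected = corrected,
                 dominant = dominant,
                 untrimmed = untrimmed, invalid = invalid,
                 negative = negative),
            class = "mlts_result")
}
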