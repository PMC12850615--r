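# Spill-over partial volume corrections built on region spread
# functions (RSFs): region-wise GTM, iterative voxel-wise STC, and the
# single-pass estimated STC.

#' Region spread function of a compartment
#'
#' Convolution of a binary compartment mask with its unit-gain PSF: the
#' spatial distribution of where that compartment's signal lands. The
#' masked variant `m * (m conv PSF)` restricts the RSF to the
#' compartment's own voxels, as used by the recovery factor and the
#' voxel-wise corrections.
#'
#' @param mask logical 3D array.
#' @param psf `psf_kernel` (unit sum required).
#' @param masked return the mask-restricted RSF.
#' @return 3D array.
#' @export
build_rsf <- function(mask, psf, masked = FALSE) {
  m <- vol_values(mask) != 0
  k <- vol_values(psf)
  if (abs(sum(k) - 1) > 1e-6)
    stop("PSF is not normalized to unit sum")
  rsf <- conv3d(array(as.numeric(m), dim = dim(m)), psf)
  if (masked) rsf * m else rsf
}

#' Compartment set for spill-over correction
#'
#' Bundles the pairwise-disjoint compartment masks with their PSFs and
#' precomputes, for each compartment, the full-field RSF (used by the
#' GTM weights), the mask-restricted RSF (used by the voxel-wise
#' corrections), the convolution plans, and the recovery factor
#' `R = sum_i m_i * (m_i conv PSF_i)`.
#'
#' @param masks named list of logical 3D arrays (pairwise disjoint).
#' @param psfs list of `psf_kernel`s, one per compartment or a single
#'   shared kernel.
#' @param surround name or index of the surround compartment (optional;
#'   required by [stc_correct()] and [estc_correct()]).
#' @param validate check mask disjointness (disable only for
#'   constructing deliberately degenerate fixtures).
#' @return A `compartment_set`.
#' @export
compartment_set <- function(masks, psfs, surround = NULL, validate = TRUE) {
  if (length(masks) < 2L) stop("at least two compartments are required")
  if (inherits(psfs, "psf_kernel")) psfs <- list(psfs)
  if (length(psfs) == 1L) psfs <- rep(psfs, length(masks))
  if (length(psfs) != length(masks))
    stop("need one PSF per compartment (or a single shared PSF)")
  if (is.null(names(masks)))
    names(masks) <- paste0("comp", seq_along(masks))
  masks <- lapply(masks, function(m) vol_values(m) != 0)
  d <- dim(masks[[1]])
  if (!all(vapply(masks, function(m) identical(dim(m), d), TRUE)))
    stop("compartment masks must share one grid")
  if (validate) {
    tot <- Reduce(`+`, lapply(masks, as.numeric))
    if (max(tot) > 1)
      stop("compartment masks overlap")
  }
  for (k in psfs)
    if (abs(sum(vol_values(k)) - 1) > 1e-6)
      stop("PSF is not normalized to unit sum")
  plans <- lapply(psfs, conv3d_plan, dim_data = d)
  rsf_full <- vector("list", length(masks))
  i <- 1L
  while (i <= length(masks)) {
    if (i + 1L <= length(masks) &&
        all(plans[[i]]$dim_pad == plans[[i + 1L]]$dim_pad)) {
      pr <- conv3d_apply_pair(as.numeric(masks[[i]]),
                              as.numeric(masks[[i + 1L]]),
                              plans[[i]], plans[[i + 1L]])
      dim(pr$a) <- d; dim(pr$b) <- d
      rsf_full[[i]] <- pr$a; rsf_full[[i + 1L]] <- pr$b
      i <- i + 2L
    } else {
      v <- conv3d_apply(array(as.numeric(masks[[i]]), dim = d), plans[[i]])
      rsf_full[[i]] <- v
      i <- i + 1L
    }
  }
  names(rsf_full) <- names(masks)
  rsf_masked <- Map(function(m, r) r * m, masks, rsf_full)
  R <- Reduce(`+`, rsf_masked)
  sur <- if (is.null(surround)) NA_integer_
  else if (is.character(surround)) match(surround, names(masks))
  else as.integer(surround)
  if (!is.null(surround) && (is.na(sur) || sur < 1 || sur > length(masks)))
    stop("unknown surround compartment")
  structure(list(masks = masks, psfs = psfs, plans = plans,
                 rsf_full = rsf_full, rsf_masked = rsf_masked,
                 recovery = R, surround = sur, dim = d),
            class = "compartment_set")
}

#' @export
print.compartment_set <- function(x, ...) {
  cat(sprintf("<compartment_set> %d compartments on %s grid%s\n",
              length(x$masks), paste(x$dim, collapse = "x"),
              if (!is.na(x$surround))
                sprintf(", surround = '%s'", names(x$masks)[x$surround])
              else ""))
  invisible(x)
}

#' Region-wise spill-over correction (geometric transfer matrix)
#'
#' The mean measured signal of compartment `i` is modeled as
#' `m_i = sum_j W_ij T_j` with `W_ij` the mean of compartment `j`'s RSF
#' over compartment `i`'s mask: each matrix element is the fraction of
#' region `j`'s signal landing in region `i`. Inverting the linear
#' system recovers the corrected mean intensities `T`. Exact for
#' piecewise-constant images blurred with the compartments' own PSFs.
#'
#' @param image measured image (`volume_grid` or 3D array).
#' @param compartments a [compartment_set()].
#' @param cond_limit maximum acceptable condition number of `W`.
#' @return A `correction_result` with per-region `means` (corrected),
#'   `measured` means, and the transfer matrix `W`.
#' @export
gtm_correct <- function(image, compartments, cond_limit = 1e8) {
  v <- vol_values(image)
  cs <- compartments
  nm <- names(cs$masks)
  K <- length(cs$masks)
  W <- matrix(0, K, K, dimnames = list(nm, nm))
  m <- numeric(K)
  for (i in seq_len(K)) {
    mi <- cs$masks[[i]]
    m[i] <- mean(v[mi])
    for (j in seq_len(K)) W[i, j] <- mean(cs$rsf_full[[j]][mi])
  }
  kap <- kappa(W, exact = TRUE)
  if (!is.finite(kap) || kap > cond_limit)
    stop("geometric transfer matrix is ill-conditioned (condition number ",
         format(kap, digits = 3),
         "); consider merging small or duplicate compartments")
  T_ <- solve(W, m)
  names(T_) <- nm; names(m) <- nm
  structure(list(method = "gtm", means = T_, measured = m, W = W,
                 iterations = 0L, converged = TRUE, oscillation = FALSE),
            class = "correction_result")
}

# Replace negative voxels inside 'domain' by their nearest positive
# (or non-negative) neighbor value.
replace_negatives <- function(values, domain, positive = TRUE) {
  neg <- which(domain & values < 0)
  if (!length(neg)) return(values)
  src <- domain & (if (positive) values > 0 else values >= 0)
  src[neg] <- FALSE
  if (!any(src)) return(values)  # nothing to donate; keep as is
  nearest_fill(values, src, neg, tie_min_value = positive)
}

#' Iterative voxel-wise spill-over correction (single target correction)
#'
#' Corrects the partial volume effects between one target compartment
#' and its surroundings: each iteration subtracts the signal spilled
#' from the surround into the target and vice versa (convolving the
#' current estimate of either compartment with its PSF and masking the
#' contribution to the other), divides by the recovery factor `R`, and
#' replaces negative voxels by their nearest minimal positive neighbor.
#' Iteration stops when the maximum relative voxel change falls below
#' `tol`, when the state matches the state two iterations back within
#' `tol` (a period-2 steady state; both states are returned together
#' with their mean), or at `max_iter`.
#'
#' @param image measured image (`volume_grid` or 3D array).
#' @param compartments a two-compartment [compartment_set()] with a
#'   designated surround.
#' @param tol relative-change convergence tolerance.
#' @param max_iter iteration cap.
#' @param rsf_floor recovery values below this (inside the masks) are
#'   clamped for the division and flagged for exclusion from statistics.
#' @return A `correction_result`: `corrected` (3D array, zero outside
#'   the compartments), `iterations`, `converged`, `oscillation`,
#'   `states` (two arrays when oscillating), `flagged` (low-recovery
#'   voxels), per-region `means`.
#' @export
stc_correct <- function(image, compartments, tol = 1e-4, max_iter = 100L,
                        rsf_floor = 0.05) {
  cs <- compartments
  if (length(cs$masks) != 2L)
    stop("STC is formulated for exactly two compartments (target, surround)")
  if (is.na(cs$surround)) stop("no surround compartment designated")
  v <- vol_values(image)
  isur <- cs$surround; itar <- setdiff(1:2, isur)
  m_t <- cs$masks[[itar]]; m_s <- cs$masks[[isur]]
  union <- m_t | m_s
  R <- cs$recovery
  if (any(R[union] <= 0))
    stop("recovery factor has non-positive values inside the compartments")
  flagged <- union & R < rsf_floor
  Rdiv <- pmax(R, rsf_floor)

  S <- v * union
  C <- S
  prev <- NULL; prev2 <- NULL
  converged <- FALSE; oscillation <- FALSE
  states <- NULL
  eps <- 1e-12
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    pr <- conv3d_apply_pair(C * m_s, C * m_t,
                            cs$plans[[isur]], cs$plans[[itar]])
    spill_t <- pr$a * m_t   # surround spilling into target
    spill_s <- pr$b * m_s   # target spilling into surround
    Cn <- (S - spill_t - spill_s) / Rdiv * union
    Cn <- replace_negatives(Cn, union, positive = TRUE)
    dl <- max(abs(Cn - C)[union] / (abs(C)[union] + eps))
    if (dl < tol) { C <- Cn; converged <- TRUE; break }
    if (!is.null(prev2)) {
      dl2 <- max(abs(Cn - prev2)[union] / (abs(prev2)[union] + eps))
      if (dl2 < tol) {
        oscillation <- TRUE
        states <- list(C, Cn)
        C <- (C + Cn) / 2
        break
      }
    }
    prev2 <- prev; prev <- C; C <- Cn
  }
  nm <- names(cs$masks)
  means <- c(mean(C[m_t & !flagged]), mean(C[m_s & !flagged]))
  names(means) <- nm[c(itar, isur)]
  structure(list(method = "stc", corrected = C, iterations = it,
                 converged = converged, oscillation = oscillation,
                 states = states, flagged = flagged, means = means),
            class = "correction_result")
}

#' Erode a compartment and refill from its interior (operator r)
#'
#' Edge voxels of a mask are overestimated when a masked signal is
#' divided by its RSF. This operator erodes the mask by `depth` voxels
#' (face connectivity) and replaces the values of the eroded-away voxels
#' by the value of the nearest surviving voxel (Euclidean distance, ties
#' by lowest linear index). Voxels outside the mask are untouched. If
#' erosion would empty the mask entirely, the uneroded values are
#' returned with `fallback = TRUE`.
#'
#' @param volume `volume_grid` or 3D array.
#' @param mask logical compartment mask.
#' @param depth erosion depth in voxels.
#' @return List with `values` (3D array) and `fallback`.
#' @export
erode_and_fill <- function(volume, mask, depth = 1L) {
  v <- vol_values(volume)
  m <- vol_values(mask) != 0
  if (!any(m)) stop("mask is empty")
  core <- erode_mask(m, depth)
  if (!any(core))
    return(list(values = v, fallback = TRUE))
  lost <- which(m & !core)
  out <- nearest_fill(v, core, lost, tie_min_value = FALSE)
  list(values = out, fallback = FALSE)
}

#' Single-pass voxel-wise spill-over correction (estimated STC)
#'
#' Replaces the STC's repeated convolutions by explicit estimates of
#' each compartment's true signal: the surround estimate divides the
#' masked signal by the surround RSF and repairs the overestimated edge
#' voxels with [erode_and_fill()]; each target estimate removes the
#' surround spill-in before its own RSF division. A single sweep over
#' the compartments in descending size order then subtracts all
#' spilled-in contributions from each compartment's measured signal,
#' divides by its RSF, replaces negative voxels by their nearest
#' non-negative neighbor, and updates the estimate used for the
#' remaining compartments. No iteration is required.
#'
#' @param image measured image (`volume_grid` or 3D array).
#' @param compartments a [compartment_set()] with a designated surround.
#' @param erosion_depth depth of the erode-and-fill operator.
#' @param rsf_floor recovery values below this (inside a mask) are
#'   clamped for the division and flagged.
#' @param sweeps number of correction sweeps over the measured image;
#'   the default single sweep is the method (additional sweeps reuse
#'   the updated estimates and change the result only marginally, which
#'   is what makes iteration unnecessary).
#' @return A `correction_result`: `corrected`, per-region `means`,
#'   `flagged`, `fallback` (compartments where erosion emptied the
#'   mask).
#' @export
estc_correct <- function(image, compartments, erosion_depth = 1L,
                         rsf_floor = 0.05, sweeps = 1L) {
  cs <- compartments
  if (is.na(cs$surround)) stop("no surround compartment designated")
  v <- vol_values(image)
  K <- length(cs$masks)
  isur <- cs$surround
  union <- Reduce(`|`, cs$masks)
  if (any(cs$recovery[union] <= 0))
    stop("RSF has non-positive values inside the compartments")
  flagged <- array(FALSE, dim = cs$dim)
  fallback <- logical(K)

  rsf_div <- function(i) {
    r <- cs$rsf_masked[[i]]
    fl <- cs$masks[[i]] & r < rsf_floor
    flagged <<- flagged | fl
    pmax(r, rsf_floor)
  }

  S_i <- lapply(cs$masks, function(m) v * m)

  # estimate of the surround's true signal (Eq. of the surround estimate)
  E <- vector("list", K)
  ef <- erode_and_fill(S_i[[isur]] / rsf_div(isur) * cs$masks[[isur]],
                       cs$masks[[isur]], erosion_depth)
  E[[isur]] <- ef$values * cs$masks[[isur]]
  fallback[isur] <- ef$fallback

  # spill of the current estimates, cached per compartment
  spill <- vector("list", K)
  spill[[isur]] <- conv3d_apply(E[[isur]], cs$plans[[isur]])

  # target estimates: remove surround spill-in before the RSF division
  for (i in setdiff(seq_len(K), isur)) {
    est <- (S_i[[i]] - cs$masks[[i]] * spill[[isur]]) / rsf_div(i) *
      cs$masks[[i]]
    ef <- erode_and_fill(est, cs$masks[[i]], erosion_depth)
    E[[i]] <- ef$values * cs$masks[[i]]
    fallback[i] <- fallback[i] || ef$fallback
    spill[[i]] <- conv3d_apply(E[[i]], cs$plans[[i]])
  }

  # correction sweep(s), largest compartment first
  sizes <- vapply(cs$masks, sum, 0)
  ord <- order(-sizes, seq_len(K))
  corrected <- array(0, dim = cs$dim)
  for (sw in seq_len(sweeps)) {
    for (i in ord) {
      spill_in <- array(0, dim = cs$dim)
      for (j in setdiff(seq_len(K), i))
        spill_in <- spill_in + spill[[j]]
      Ci <- (S_i[[i]] - cs$masks[[i]] * spill_in) / rsf_div(i) * cs$masks[[i]]
      Ci <- replace_negatives(Ci, cs$masks[[i]], positive = FALSE)
      corrected[cs$masks[[i]]] <- Ci[cs$masks[[i]]]
      ef <- erode_and_fill(Ci, cs$masks[[i]], erosion_depth)
      E[[i]] <- ef$values * cs$masks[[i]]
      fallback[i] <- fallback[i] || ef$fallback
      spill[[i]] <- conv3d_apply(E[[i]], cs$plans[[i]])
    }
  }
  nm <- names(cs$masks)
  means <- vapply(seq_len(K), function(i)
    mean(corrected[cs$masks[[i]] & !flagged]), 0)
  names(means) <- nm
  names(fallback) <- nm
  structure(list(method = "estc", corrected = corrected, means = means,
                 flagged = flagged, fallback = fallback,
                 iterations = 1L, converged = TRUE, oscillation = FALSE),
            class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf("<correction_result> method %s", x$method))
  if (!is.null(x$iterations)) cat(sprintf(", %d iteration(s)", x$iterations))
  if (isTRUE(x$oscillation)) cat(" [period-2 steady state]")
  cat("\n")
  if (!is.null(x$means)) {
    cat("region means:\n")
    print(round(x$means, 4))
  }
  invisible(x)
}
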