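# Binary morphology and nearest-neighbor filling on 3D masks.
#
# Used for the one-voxel surround shell of the region-level
# tissue-fraction correction, the erode-and-fill operator of the
# single-pass spill-over correction, and the non-negativity replacement
# rule of the iterative correction.

# Shift an array by (dx,dy,dz), padding with 'fill'.
shift3d <- function(v, dx, dy, dz, fill = 0) {
  d <- dim(v)
  out <- array(fill, dim = d)
  src <- function(n, s) {
    if (s >= 0) list(from = seq_len(n - s), to = seq_len(n - s) + s)
    else list(from = seq_len(n + s) - s, to = seq_len(n + s))
  }
  sx <- src(d[1], dx); sy <- src(d[2], dy); sz <- src(d[3], dz)
  out[sx$to, sy$to, sz$to] <- v[sx$from, sy$from, sz$from]
  out
}

neighbor_offsets <- function(connectivity = c("6", "26")) {
  connectivity <- match.arg(as.character(connectivity), c("6", "26"))
  if (connectivity == "6") {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
          c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else {
    g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  }
}

#' Erode a binary mask
#'
#' Face-connected (6-neighborhood) erosion: a voxel survives if it and
#' all its face neighbors are inside the mask; voxels on the grid
#' boundary are treated as bordering air and are eroded.
#'
#' @param mask logical or 0/1 3D array.
#' @param depth number of erosion passes.
#' @return Logical 3D array.
#' @export
erode_mask <- function(mask, depth = 1L) {
  m <- vol_values(mask) != 0
  for (i in seq_len(depth)) {
    keep <- m
    for (r in seq_len(nrow(off <- neighbor_offsets("6"))))
      keep <- keep & shift3d(m, off[r, 1], off[r, 2], off[r, 3], fill = FALSE)
    m <- keep
  }
  m
}

#' Dilate a binary mask
#'
#' @param mask logical or 0/1 3D array.
#' @param depth number of dilation passes.
#' @param connectivity `"6"` (faces) or `"26"` (full cube neighborhood).
#' @return Logical 3D array.
#' @export
dilate_mask <- function(mask, depth = 1L, connectivity = "26") {
  m <- vol_values(mask) != 0
  off <- neighbor_offsets(connectivity)
  for (i in seq_len(depth)) {
    grown <- m
    for (r in seq_len(nrow(off)))
      grown <- grown | shift3d(m, off[r, 1], off[r, 2], off[r, 3], fill = FALSE)
    m <- grown
  }
  m
}

# Coordinates (i,j,k) of the TRUE voxels of a mask.
mask_coords <- function(mask) {
  which(mask, arr.ind = TRUE)
}

#' Nearest-source value fill
#'
#' For every voxel in `fill_idx` (linear indices), finds the nearest
#' voxel of `source_mask` by Euclidean distance and copies its value.
#' Ties are broken by the smaller value when `tie_min_value` is TRUE
#' (the "nearest minimal positive neighbor" rule), then by the lowest
#' linear index. The search expands a cubic window outward from each
#' voxel, which is fast because fill regions are thin shells in
#' practice.
#'
#' @param values 3D array of source values.
#' @param source_mask logical 3D array of allowed donor voxels.
#' @param fill_idx integer vector of linear indices to fill.
#' @param tie_min_value break exact distance ties by the minimum donor
#'   value (otherwise only by lowest linear index).
#' @return `values` with the requested voxels replaced.
#' @export
nearest_fill <- function(values, source_mask, fill_idx,
                         tie_min_value = FALSE) {
  if (!length(fill_idx)) return(values)
  d <- dim(values)
  src <- source_mask
  src[fill_idx] <- FALSE
  if (!any(src)) stop("no source voxels available for nearest-neighbor fill")
  co <- arrayInd(fill_idx, d)
  out <- values
  for (q in seq_along(fill_idx)) {
    p <- co[q, ]
    r <- 1L
    best_d2 <- Inf; best_val <- NA_real_; best_lin <- NA_integer_
    repeat {
      xr <- max(1L, p[1] - r):min(d[1], p[1] + r)
      yr <- max(1L, p[2] - r):min(d[2], p[2] + r)
      zr <- max(1L, p[3] - r):min(d[3], p[3] + r)
      sub <- src[xr, yr, zr, drop = FALSE]
      if (any(sub)) {
        w <- which(sub, arr.ind = TRUE)
        dx <- xr[w[, 1]] - p[1]; dy <- yr[w[, 2]] - p[2]; dz <- zr[w[, 3]] - p[3]
        d2 <- dx^2 + dy^2 + dz^2
        lin <- (zr[w[, 3]] - 1L) * d[1] * d[2] + (yr[w[, 2]] - 1L) * d[1] +
          xr[w[, 1]]
        vals <- values[lin]
        ord <- order(d2, if (tie_min_value) vals else lin, lin)
        b <- ord[1]
        if (d2[b] < best_d2 ||
            (d2[b] == best_d2 &&
             ((tie_min_value && vals[b] < best_val) ||
              (!tie_min_value && lin[b] < best_lin)))) {
          best_d2 <- d2[b]; best_val <- vals[b]; best_lin <- lin[b]
        }
        # a voxel outside Chebyshev radius ceil(sqrt(best_d2)) cannot be
        # Euclidean-closer; stop once the window covers that radius
        if (r >= ceiling(sqrt(best_d2))) break
      }
      r <- r + 1L
      if (r > max(d)) break
    }
    out[fill_idx[q]] <- best_val
  }
  out
}

# One-voxel 26-connected shell around a mask (inside the grid).
mask_shell <- function(mask) {
  m <- vol_values(mask) != 0
  dilate_mask(m, 1L, "26") & !m
}
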