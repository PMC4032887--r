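#' 3D image stack with anisotropic voxel sizes
#'
#' Container for a 3D grayscale intensity grid. Intensities are min-max
#' normalized to `[0, 1]`; voxel `(i, j, k)` (1-based) sits at physical
#' position `origin + ((i-1) sx, (j-1) sy, (k-1) sz)`.
#'
#' @param voxels 3D numeric array, dimension order (x, y, z).
#' @param voxel_size positive length-3 numeric `(sx, sy, sz)`, physical
#'   units per voxel. z is typically coarser in confocal/two-photon stacks.
#' @param origin physical coordinate of voxel (1, 1, 1).
#' @param normalize if `TRUE` (default), min-max normalize to `[0, 1]`.
#' @return An object of class `image_stack` with fields `voxels`,
#'   `voxel_size`, `origin`.
#' @export
image_stack <- function(voxels, voxel_size, origin = c(0, 0, 0),
                        normalize = TRUE) {
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("voxel_size must be three positive lengths (sx, sy, sz)")
  if (normalize) voxels <- normalize_intensity(voxels)
  structure(list(voxels = voxels, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack %d x %d x %d, voxel size (%g, %g, %g)>\n",
              d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

# min-max normalization to [0, 1]; idempotent
normalize_intensity <- function(voxels) {
  rng <- range(voxels, finite = TRUE)
  if (!all(is.finite(rng))) stop("stack contains no finite intensities")
  if (rng[2] - rng[1] <= 0)
    stop("zero dynamic range: all voxels have the same intensity")
  (voxels - rng[1]) / (rng[2] - rng[1])
}

#' Load a TIFF image stack
#'
#' Reads a single- or multi-page grayscale TIFF. Each page becomes one z
#' slice; page rows map to the y axis and page columns to the x axis, so the
#' returned array is indexed `[x, y, z]`. Intensities are min-max
#' normalized to `[0, 1]`.
#'
#' @param path path to a readable TIFF file.
#' @param voxel_size physical voxel dimensions `(sx, sy, sz)`.
#' @param origin physical coordinate of voxel (1, 1, 1).
#' @return An [image_stack()].
#' @export
load_stack <- function(path, voxel_size, origin = c(0, 0, 0)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2L, logical(1))))
    stop("non-grayscale TIFF: multi-channel pages are not supported")
  d <- dim(pages[[1]])
  vox <- array(0, dim = c(d[2], d[1], length(pages)))
  for (k in seq_along(pages)) vox[, , k] <- t(pages[[k]])
  image_stack(vox, voxel_size, origin = origin, normalize = TRUE)
}

#' Write a stack as a multi-page grayscale TIFF
#'
#' Inverse of [load_stack()] up to intensity quantization (pages are written
#' as 16-bit).
#'
#' @param stack an [image_stack()].
#' @param path output path.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$voxels)
  pages <- lapply(seq_len(d[3]), function(k) t(stack$voxels[, , k]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Physical coordinates of voxel indices
#'
#' @param stack an [image_stack()].
#' @param ijk integer matrix (n x 3) of 1-based voxel indices.
#' @return n x 3 matrix of physical positions.
#' @export
voxel_to_phys <- function(stack, ijk) {
  ijk <- rbind(ijk)
  sweep(sweep(ijk - 1, 2, stack$voxel_size, "*"), 2, stack$origin, "+")
}

#' Nearest voxel indices for physical positions
#'
#' @param stack an [image_stack()].
#' @param pos numeric matrix (n x 3) of physical positions.
#' @return n x 3 integer matrix of 1-based voxel indices, clamped to the
#'   stack bounds.
#' @export
phys_to_voxel <- function(stack, pos) {
  pos <- rbind(pos)
  ijk <- round(sweep(sweep(pos, 2, stack$origin, "-"), 2,
                     stack$voxel_size, "/")) + 1
  d <- dim(stack$voxels)
  for (a in 1:3) ijk[, a] <- pmin(pmax(ijk[, a], 1), d[a])
  storage.mode(ijk) <- "integer"
  ijk
}

#' Trilinear intensity interpolation at physical positions
#'
#' Positions outside the stack are clamped to the boundary faces.
#'
#' @param stack an [image_stack()].
#' @param pos numeric matrix (n x 3) of physical positions.
#' @return numeric vector of interpolated intensities.
#' @export
stack_interp <- function(stack, pos) {
  pos <- rbind(pos)
  d <- dim(stack$voxels)
  # continuous voxel coordinates, 1-based
  cc <- sweep(sweep(pos, 2, stack$origin, "-"), 2, stack$voxel_size, "/") + 1
  for (a in 1:3) cc[, a] <- pmin(pmax(cc[, a], 1), d[a])
  i0 <- pmin(floor(cc[, 1]), d[1] - 1L); i0[d[1] == 1L] <- 1L
  j0 <- pmin(floor(cc[, 2]), d[2] - 1L); j0[d[2] == 1L] <- 1L
  k0 <- pmin(floor(cc[, 3]), d[3] - 1L); k0[d[3] == 1L] <- 1L
  fx <- cc[, 1] - i0; fy <- cc[, 2] - j0; fz <- cc[, 3] - k0
  i1 <- pmin(i0 + 1, d[1]); j1 <- pmin(j0 + 1, d[2]); k1 <- pmin(k0 + 1, d[3])
  v <- stack$voxels
  at <- function(i, j, k) v[cbind(i, j, k)]
  unname(at(i0, j0, k0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(i1, j0, k0) * fx * (1 - fy) * (1 - fz) +
    at(i0, j1, k0) * (1 - fx) * fy * (1 - fz) +
    at(i0, j0, k1) * (1 - fx) * (1 - fy) * fz +
    at(i1, j1, k0) * fx * fy * (1 - fz) +
    at(i1, j0, k1) * fx * (1 - fy) * fz +
    at(i0, j1, k1) * (1 - fx) * fy * fz +
    at(i1, j1, k1) * fx * fy * fz)
}

# separable Gaussian smoothing, sigma in voxel units, reflected borders
gaussian_smooth <- function(voxels, sigma = 1) {
  if (sigma <= 0) return(voxels)
  rad <- max(1L, ceiling(3 * sigma))
  kern <- exp(-(seq(-rad, rad))^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  d <- dim(voxels)
  smooth_axis <- function(a, axis) {
    n <- dim(a)[axis]
    idx <- function(i) pmin(pmax(i, 1L), n)  # replicate-pad borders
    out <- array(0, dim(a))
    for (t in seq_along(kern)) {
      sh <- t - rad - 1L
      sl <- idx(seq_len(n) + sh)
      out <- out + kern[t] * switch(axis,
                                    a[sl, , , drop = FALSE],
                                    a[, sl, , drop = FALSE],
                                    a[, , sl, drop = FALSE])
    }
    out
  }
  smooth_axis(smooth_axis(smooth_axis(voxels, 1L), 2L), 3L)
}

#' Generate seed points along bright structures
#'
#' Seeds are local intensity maxima (26-neighborhood) of a Gaussian-smoothed
#' copy of the stack whose raw intensity exceeds `threshold`, greedily
#' thinned so that no two seeds lie within `min_separation` (physical
#' distance), and ordered by decreasing intensity.
#'
#' @param stack an [image_stack()].
#' @param threshold intensity threshold in (0, 1); default 0.3.
#' @param min_separation minimum physical distance between seeds; default
#'   `10 * sx`.
#' @param smoothing_sigma Gaussian sigma in voxels for the maxima search;
#'   default 1.
#' @param maxima_tol near-maximum tolerance on the smoothed intensity
#'   (default 0.02): a voxel within this much of its strongest neighbor
#'   still counts as a ridge maximum, so noise does not thin the candidate
#'   set along a neurite.
#' @return A list of class `seed_set` with `points` (n x 3 integer voxel
#'   indices) and `intensities`. Zero rows if no voxel exceeds the
#'   threshold.
#' @export
generate_seeds <- function(stack, threshold = 0.3,
                           min_separation = 10 * stack$voxel_size[1],
                           smoothing_sigma = 1, maxima_tol = 0.02) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly between 0 and 1")
  v <- stack$voxels
  sm <- gaussian_smooth(v, smoothing_sigma)
  d <- dim(v)
  # local maxima of the smoothed field over the 26-neighborhood
  is_max <- array(TRUE, d)
  pad <- function(a, sh) {
    # shift with +Inf... use replicate padding so borders can hold maxima
    i <- pmin(pmax(seq_len(d[1]) + sh[1], 1L), d[1])
    j <- pmin(pmax(seq_len(d[2]) + sh[2], 1L), d[2])
    k <- pmin(pmax(seq_len(d[3]) + sh[3], 1L), d[3])
    a[i, j, k, drop = FALSE]
  }
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    is_max <- is_max & (sm >= pad(sm, c(dx, dy, dz)) - maxima_tol)
  }
  cand <- which(is_max & (v > threshold), arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(structure(list(points = cand, intensities = numeric(0)),
                     class = "seed_set"))
  ints <- v[cand]
  ord <- order(ints, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  ints <- ints[ord]
  pos <- voxel_to_phys(stack, cand)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    acc <- which(keep)
    if (length(acc) == 0) { keep[i] <- TRUE; next }
    d2 <- colSums((t(pos[acc, , drop = FALSE]) - pos[i, ])^2)
    if (min(d2) > min_separation^2) keep[i] <- TRUE
  }
  structure(list(points = cand[keep, , drop = FALSE],
                 intensities = ints[keep]),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("<seed_set: %d seeds>\n", nrow(x$points)))
  invisible(x)
}
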