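# Intensity normalization to [-1, 1], 24^3 patch extraction, and
# whole-volume augmentation (coronal/sagittal flips, feet-head rotation).

.CT_HU_MIN <- -1024
.CT_HU_MAX <- 3071

#' Normalize an MR magnitude volume
#'
#' Clips intensities beyond the given per-volume percentile (to suppress
#' hyperintense outliers such as the fluid surrounding a HIFU transducer)
#' and maps `[0, p]` affinely to `[-1, 1]`: magnitude data have a physical
#' zero, so the lower anchor is 0, not the volume minimum. The percentile
#' uses linear interpolation between order statistics (R's default type 7).
#'
#' @param volume nonnegative MR magnitude volume.
#' @param percentile clip percentile, default 95.
#' @param spacing voxel spacing in mm carried along for later stages.
#' @return A [NormalizedVolume-class] whose record holds the clip value.
#' @export
normalizeMR <- function(volume, percentile = 95,
                        spacing = attr(volume, "spacing")) {
  if (min(volume) < 0) stop("MR magnitudes must be nonnegative")
  p <- unname(quantile(volume, percentile / 100, type = 7))
  if (p <= 0)
    stop("degenerate volume: clip percentile is zero (constant-zero input?)")
  v <- pmin(volume, p)
  out <- array(2 * v / p - 1, dim(volume))
  new("NormalizedVolume", values = out, source = "mr",
      record = list(clipValue = p, percentile = percentile),
      spacing = if (is.null(spacing)) c(1, 1, 1) else spacing)
}

#' Normalize a CT volume
#'
#' Maps the Hounsfield range `[-1024, 3071]` affinely to `[-1, 1]`; values
#' outside the range are clipped first (the range is treated as
#' exhaustive).
#'
#' @param volume HU volume.
#' @param spacing voxel spacing in mm.
#' @return A [NormalizedVolume-class]; its record is the fixed HU range, so
#'   the map is exactly invertible via [denormalizeCT()].
#' @export
normalizeCT <- function(volume, spacing = attr(volume, "spacing")) {
  v <- pmin(pmax(volume, .CT_HU_MIN), .CT_HU_MAX)
  out <- array(2 * (v - .CT_HU_MIN) / (.CT_HU_MAX - .CT_HU_MIN) - 1,
               dim(volume))
  new("NormalizedVolume", values = out, source = "ct",
      record = list(huMin = .CT_HU_MIN, huMax = .CT_HU_MAX),
      spacing = if (is.null(spacing)) c(1, 1, 1) else spacing)
}

#' Invert CT normalization
#'
#' @param x a CT-style [NormalizedVolume-class], or a plain numeric
#'   array on the `[-1, 1]` scale (the fixed HU range is then assumed).
#' @return HU volume; round-trips with [normalizeCT()] to floating
#'   tolerance.
#' @export
denormalizeCT <- function(x) {
  if (is(x, "NormalizedVolume")) {
    if (x@source != "ct" || is.null(x@record$huMin))
      stop("not a CT-style normalization record")
    lo <- x@record$huMin; hi <- x@record$huMax
    v <- x@values
  } else {
    lo <- .CT_HU_MIN; hi <- .CT_HU_MAX
    v <- x
  }
  (v + 1) / 2 * (hi - lo) + lo
}

# Cumulative sum of a 3D array along one axis, dims preserved.
cumsumAxis <- function(a, axis) {
  switch(axis,
         apply(a, c(2, 3), cumsum),
         aperm(apply(a, c(1, 3), cumsum), c(2, 1, 3)),
         aperm(apply(a, c(1, 2), cumsum), c(2, 3, 1)))
}

# Sliding-window sums via a 3D summed-area table; used to find patch
# origins whose window intersects the bone mask without scanning windows.
windowSums <- function(mask, size) {
  s <- cumsumAxis(cumsumAxis(cumsumAxis(mask + 0, 1L), 2L), 3L)
  d <- dim(mask)
  pad <- array(0, d + 1)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- s
  n <- d - size + 1
  i0 <- seq_len(n[1]); j0 <- seq_len(n[2]); k0 <- seq_len(n[3])
  i1 <- i0 + size; j1 <- j0 + size; k1 <- k0 + size
  pad[i1, j1, k1] - pad[i0, j1, k1] - pad[i1, j0, k1] - pad[i1, j1, k0] +
    pad[i0, j0, k1] + pad[i0, j1, k0] + pad[i1, j0, k0] - pad[i0, j0, k0]
}

#' Extract aligned MR/CT patch pairs
#'
#' Samples cubic patches at random origins (with replacement when
#' `nPatches` exceeds the number of distinct origins). At least
#' `boneFractionMin` of the patches have windows intersecting the bone
#' mask; the rest are drawn anywhere. Origins are recorded per patch.
#'
#' @param mrEcho1,mrEcho2,ct [NormalizedVolume-class] objects on one grid.
#' @param boneMask logical volume on the same grid.
#' @param size patch edge length in voxels, default 24.
#' @param nPatches number of patches to draw.
#' @param boneFractionMin minimum fraction of bone-intersecting patches.
#' @param seed integer seed.
#' @return List of patch pairs; each has `mr` (size^3 x 2 array), `ct`
#'   (size^3 array) and `origin` (voxel index triple).
#' @export
extractPatches <- function(mrEcho1, mrEcho2, ct, boneMask, size = 24L,
                           nPatches = 32L, boneFractionMin = 0.8,
                           seed = 1L) {
  vols <- lapply(list(mrEcho1, mrEcho2, ct), function(v)
    if (is(v, "NormalizedVolume")) v@values else v)
  d <- dim(vols[[1]])
  for (v in vols) stopifnot(identical(dim(v), d))
  if (any(d < size))
    stop(sprintf("volume %s smaller than patch size %d",
                 paste(d, collapse = "x"), size))
  ws <- windowSums(boneMask, size)
  boneOrigins <- which(ws > 0)
  allOrigins <- seq_len(prod(dim(ws)))
  if (!length(boneOrigins))
    stop("no patch window intersects the bone mask")
  nBone <- ceiling(boneFractionMin * nPatches)
  picks <- withSeed(seed, c(
    sample(boneOrigins, nBone, replace = TRUE),
    if (nPatches > nBone)
      sample(allOrigins, nPatches - nBone, replace = TRUE)))
  od <- dim(ws)
  lapply(picks, function(p) {
    p0 <- p - 1L
    i <- p0 %% od[1] + 1L
    j <- (p0 %/% od[1]) %% od[2] + 1L
    k <- p0 %/% (od[1] * od[2]) + 1L
    ix <- i:(i + size - 1L); jx <- j:(j + size - 1L); kx <- k:(k + size - 1L)
    mr <- array(c(vols[[1]][ix, jx, kx], vols[[2]][ix, jx, kx]),
                c(size, size, size, 2L))
    list(mr = mr, ct = array(vols[[3]][ix, jx, kx], c(size, size, size)),
         origin = c(i, j, k))
  })
}

#' Draw augmentation parameters
#'
#' Coronal and sagittal flips each with probability 1/2; rotation angle
#' uniform in `[-45, 45]` degrees about the feet-head axis.
#'
#' @param seed integer seed.
#' @return List with `flipSagittal`, `flipCoronal`, `angleDeg`.
#' @export
randomAugmentation <- function(seed) {
  withSeed(seed, list(flipSagittal = runif(1) < 0.5,
                      flipCoronal = runif(1) < 0.5,
                      angleDeg = runif(1, -45, 45)))
}

#' Apply one augmentation to aligned volumes
#'
#' The identical geometric transform is applied to every volume: optional
#' flip along the sagittal (x) and coronal (y) axes, then rotation about
#' the feet-head (z) axis through the volume center. Images use linear
#' interpolation, masks nearest neighbour. Flips are exact involutions;
#' `angleDeg = 0` with no flips is the identity.
#'
#' @param volumes named list of 3D arrays on one grid.
#' @param params from [randomAugmentation()], or a hand-built list.
#' @param spacing voxel spacing in mm.
#' @param isMask logical vector (recycled) marking mask volumes.
#' @return List of transformed volumes in the same order.
#' @export
augmentVolumes <- function(volumes, params, spacing = c(1, 1, 1),
                           isMask = FALSE) {
  isMask <- rep_len(isMask, length(volumes))
  d <- dim(volumes[[1]])
  out <- volumes
  for (i in seq_along(out)) {
    v <- out[[i]]
    if (isTRUE(params$flipSagittal)) v <- v[rev(seq_len(d[1])), , , drop = FALSE]
    if (isTRUE(params$flipCoronal)) v <- v[, rev(seq_len(d[2])), , drop = FALSE]
    out[[i]] <- array(v, d)
  }
  if (!is.null(params$angleDeg) && params$angleDeg != 0) {
    ctr <- (d - 1) * spacing / 2
    rot <- composeTransform(
      rigidTransform(translation = ctr),
      composeTransform(axisRotation(params$angleDeg, axis = 3L),
                       rigidTransform(translation = -ctr)))
    for (i in seq_along(out))
      out[[i]] <- resampleVolume(
        out[[i]], rot, spacing,
        interpolation = if (isMask[i]) "nearest" else "linear",
        background = 0)
  }
  out
}
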