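# Rigid initialization of CT-to-MR alignment: bone surfaces as point
# clouds in physical mm, iterative closest point with a closed-form
# (cross-covariance SVD, reflection-guarded) rigid fit, and resampling
# under the recovered transform. The study pipeline's subsequent deformable
# stage is deliberately a pluggable external hook (`deformableHook` in
# `runPipeline`), not reimplemented here.

#' Bone surface as a point cloud
#'
#' Returns the physical-space centers (mm) of mask voxels having at least
#' one 6-neighbour outside the mask; voxels beyond the volume edge count as
#' outside. Anisotropic spacing scales each coordinate axis.
#'
#' @param mask logical volume (nonempty).
#' @param spacing voxel spacing in mm.
#' @return n x 3 matrix of mm coordinates.
#' @export
maskToSurface <- function(mask, spacing = attr(mask, "spacing")) {
  if (!any(mask)) stop("cannot extract a surface from an empty mask")
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  b <- cpp_boundary6(as.logical(mask), dim(mask))
  idx <- which(array(b, dim(mask)), arr.ind = TRUE)
  sweep(idx - 1, 2, spacing, "*")
}

# Closed-form least-squares rigid fit moving -> target (Kabsch/Umeyama,
# reflection-guarded SVD of the cross-covariance).
fitRigid <- function(moving, target) {
  cm <- colMeans(moving); ct <- colMeans(target)
  H <- crossprod(sweep(moving, 2, cm), sweep(target, 2, ct))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigidTransform(R, ct - as.numeric(R %*% cm))
}

#' Iterative closest point rigid registration
#'
#' Alternates nearest-neighbour correspondence (moving to fixed, ties to
#' the lowest fixed-point index) with the closed-form rigid fit, starting
#' from a centroid-aligning translation. Stops when the RMS correspondence
#' distance changes by less than `tolMm` or after `maxIter` iterations.
#' The logged per-iteration RMS sequence is non-increasing by construction.
#'
#' @param moving,fixed n x 3 point matrices in mm (>= 3 non-collinear
#'   points each).
#' @param maxIter iteration cap.
#' @param tolMm RMS-change convergence tolerance in mm.
#' @param maxPoints clouds larger than this are regularly subsampled
#'   (deterministic) before matching.
#' @return List: `transform` ([RigidTransform-class], moving to fixed),
#'   `rms` (final RMS in mm), `rmsLog`, `iterations`, `converged`.
#' @export
icpRigid <- function(moving, fixed, maxIter = 100L, tolMm = 1e-3,
                     maxPoints = 4000L) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  for (cloud in list(moving, fixed)) {
    if (nrow(cloud) < 3) stop("ICP needs at least 3 points per cloud")
    if (!all(is.finite(cloud))) stop("non-finite point coordinates")
  }
  sub <- function(p) {
    if (nrow(p) <= maxPoints) return(p)
    p[seq(1, nrow(p), length.out = maxPoints), , drop = FALSE]
  }
  movingS <- sub(moving); fixedS <- sub(fixed)
  if (svd(sweep(movingS, 2, colMeans(movingS)))$d[2] < 1e-8)
    stop("degenerate (collinear) moving cloud")

  transform <- rigidTransform(translation = colMeans(fixedS) -
                                colMeans(movingS))
  rmsLog <- numeric(0)
  rmsPrev <- Inf
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    cur <- applyTransform(transform, movingS)
    nn <- cpp_nearest_neighbours(cur, fixedS)
    target <- fixedS[nn$index, , drop = FALSE]
    transform <- fitRigid(movingS, target)
    resid <- applyTransform(transform, movingS) - target
    rms <- sqrt(mean(rowSums(resid^2)))
    rmsLog <- c(rmsLog, rms)
    if (is.finite(rmsPrev) && abs(rmsPrev - rms) < tolMm) {
      converged <- TRUE
      break
    }
    rmsPrev <- rms
  }
  if (!converged)
    warning("ICP did not converge within maxIter; returning best transform")
  list(transform = transform, rms = rmsLog[length(rmsLog)], rmsLog = rmsLog,
       iterations = length(rmsLog), converged = converged)
}

#' RMS registration residual
#'
#' RMS of nearest-neighbour distances from the transformed moving cloud to
#' the fixed cloud; a QC companion to [icpRigid()].
#'
#' @param transform a [RigidTransform-class].
#' @param moving,fixed point matrices in mm.
#' @return RMS distance in mm.
#' @export
registrationResidual <- function(transform, moving, fixed) {
  cur <- applyTransform(transform, as.matrix(moving))
  nn <- cpp_nearest_neighbours(cur, as.matrix(fixed))
  sqrt(mean(nn$distance^2))
}

#' Resample a volume under a rigid transform
#'
#' The transform is applied to the image content: the object at physical
#' position `p` moves to `transform(p)`. Image volumes default to cubic
#' B-spline interpolation (with the exact interpolation prefilter); masks
#' should use `"nearest"`. Voxels sampled outside the source field of view
#' receive `background` (-1024 for CT, 0 for MR and masks).
#'
#' @param volume 3D array.
#' @param transform a [RigidTransform-class].
#' @param spacing source voxel spacing in mm.
#' @param targetDim,targetSpacing output grid; default the source grid.
#' @param interpolation `"bspline"`, `"linear"` or `"nearest"`.
#' @param background fill value outside the field of view.
#' @return Resampled volume with a `"spacing"` attribute.
#' @export
resampleVolume <- function(volume, transform = rigidTransform(),
                           spacing = attr(volume, "spacing"),
                           targetDim = dim(volume),
                           targetSpacing = spacing,
                           interpolation = c("bspline", "linear", "nearest"),
                           background = 0) {
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  if (is.null(targetSpacing)) targetSpacing <- spacing
  interpolation <- match.arg(interpolation)
  mode <- c(bspline = 3L, linear = 1L, nearest = 0L)[[interpolation]]
  validObject(transform)
  # sample source at transform^-1(target position)
  A <- transformToMatrix(invertTransform(transform))
  out <- cpp_resample(as.numeric(volume), dim(volume), spacing,
                      as.integer(targetDim), targetSpacing, A, mode,
                      background)
  attr(out, "spacing") <- targetSpacing
  out
}

#' Register the CT arm of a case to its MR frame
#'
#' Extracts bone surfaces from the CT-frame and MR-frame bone masks, runs
#' [icpRigid()], and returns the recovered transform together with the CT
#' resampled into the MR frame.
#'
#' @param case a [PhantomCase-class] (typically after
#'   [applyMisalignment()]).
#' @param interpolation CT interpolation for the final resampling.
#' @param ... passed to [icpRigid()].
#' @return List: `transform`, `icp` (full ICP result), `ct` (realigned CT),
#'   `ctBoneMask` (realigned CT bone mask).
#' @export
registerCase <- function(case, interpolation = "bspline", ...) {
  moving <- maskToSurface(case@ctBoneMask, case@spacing)
  fixed <- maskToSurface(case@boneMask, case@spacing)
  icp <- icpRigid(moving, fixed, ...)
  ct <- resampleVolume(case@ct, icp$transform, case@spacing,
                       interpolation = interpolation, background = -1024)
  mask <- resampleVolume(case@ctBoneMask + 0, icp$transform, case@spacing,
                         interpolation = "nearest", background = 0)
  list(transform = icp$transform, icp = icp, ct = ct,
       ctBoneMask = array(mask > 0.5, dim(mask)))
}
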