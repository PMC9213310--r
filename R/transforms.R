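#' Construct a rigid transform
#'
#' @param rotation 3x3 proper orthonormal matrix.
#' @param translation numeric length-3, mm.
#' @return A [RigidTransform-class].
#' @examples
#' rigidTransform()                     # identity
#' rigidTransform(translation = c(3, 0, 0))
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

#' Rotation about a coordinate axis
#'
#' @param angleDeg rotation angle in degrees (right-handed).
#' @param axis 1, 2 or 3 for x, y, z.
#' @param translation optional mm translation.
#' @return A [RigidTransform-class].
#' @export
axisRotation <- function(angleDeg, axis = 3L, translation = c(0, 0, 0)) {
  a <- angleDeg * pi / 180
  ca <- cos(a); sa <- sin(a)
  R <- diag(3)
  ix <- setdiff(1:3, axis)
  R[ix[1], ix[1]] <- ca; R[ix[2], ix[2]] <- ca
  R[ix[1], ix[2]] <- -sa; R[ix[2], ix[1]] <- sa
  rigidTransform(R, translation)
}

#' Compose two rigid transforms
#'
#' `composeTransform(a, b)` is the transform applying `b` first, then `a`:
#' \eqn{x \mapsto R_a (R_b x + t_b) + t_a}.
#'
#' @param a,b [RigidTransform-class] objects.
#' @return A [RigidTransform-class].
#' @export
composeTransform <- function(a, b) {
  rigidTransform(a@rotation %*% b@rotation,
                 as.numeric(a@rotation %*% b@translation) + a@translation)
}

#' Invert a rigid transform
#' @param transform a [RigidTransform-class].
#' @return The inverse [RigidTransform-class].
#' @export
invertTransform <- function(transform) {
  Rt <- t(transform@rotation)
  rigidTransform(Rt, -as.numeric(Rt %*% transform@translation))
}

#' Apply a rigid transform to points
#' @param transform a [RigidTransform-class].
#' @param points n x 3 matrix of mm coordinates.
#' @return n x 3 matrix of transformed coordinates.
#' @export
applyTransform <- function(transform, points) {
  points <- matrix(points, ncol = 3)
  sweep(points %*% t(transform@rotation), 2, transform@translation, "+")
}

#' Rotation angle of a rigid transform
#' @param transform a [RigidTransform-class].
#' @return Angle in degrees of the single-axis (angle-axis) representation.
#' @export
rotationAngle <- function(transform) {
  tr <- sum(diag(transform@rotation))
  acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
}

#' Translation magnitude of a rigid transform
#' @param transform a [RigidTransform-class].
#' @return Euclidean norm of the translation, mm.
#' @export
translationMagnitude <- function(transform)
  sqrt(sum(transform@translation^2))

#' Homogeneous-matrix representation
#' @param transform a [RigidTransform-class].
#' @return 4x4 homogeneous matrix.
#' @export
transformToMatrix <- function(transform) {
  m <- diag(4)
  m[1:3, 1:3] <- transform@rotation
  m[1:3, 4] <- transform@translation
  m
}

#' Build a rigid transform from a 4x4 homogeneous matrix
#' @param m 4x4 homogeneous matrix with a proper rotation block.
#' @return A [RigidTransform-class].
#' @export
matrixToTransform <- function(m) rigidTransform(m[1:3, 1:3], m[1:3, 4])

#' Draw a random rigid transform
#'
#' Rotation axis uniform on the sphere, angle uniform in
#' `[-maxAngleDeg, maxAngleDeg]`, translation components uniform in
#' `[-maxTranslationMm, maxTranslationMm]`.
#'
#' @param maxAngleDeg maximum |angle| in degrees.
#' @param maxTranslationMm maximum |component| of the translation, mm.
#' @param seed optional integer seed.
#' @return A [RigidTransform-class].
#' @export
randomRigidTransform <- function(maxAngleDeg = 20, maxTranslationMm = 10,
                                 seed = NULL) {
  draw <- function() {
    ax <- rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    ang <- runif(1, -maxAngleDeg, maxAngleDeg) * pi / 180
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
    rigidTransform(R, runif(3, -maxTranslationMm, maxTranslationMm))
  }
  if (is.null(seed)) draw() else withSeed(seed, draw())
}

#' Serialize / deserialize transforms as JSON
#'
#' Transforms are stored as a 4x4 homogeneous matrix (row-major list) with a
#' direction note, so they can be exchanged with other tools.
#'
#' @param transform a [RigidTransform-class].
#' @param path file path.
#' @return `readTransform` returns a [RigidTransform-class];
#'   `writeTransform` its path, invisibly.
#' @export
writeTransform <- function(transform, path) {
  jsonlite::write_json(
    list(direction = "moving_to_fixed",
         matrix = transformToMatrix(transform)),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  matrixToTransform(asMatrix4(obj$matrix))
}

# Accept a 4x4 matrix or a row-major nested list from JSON.
asMatrix4 <- function(m) {
  if (is.matrix(m)) return(m)
  do.call(rbind, lapply(m, unlist))
}
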