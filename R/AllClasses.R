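#' Rigid transform in physical (mm) space
#'
#' A rotation plus translation mapping moving-frame coordinates into the
#' fixed frame: \eqn{y = R x + t}. Rotation is a proper 3x3 orthonormal
#' matrix (determinant +1), translation is in millimetres.
#'
#' @slot rotation 3x3 orthonormal matrix, det = +1.
#' @slot translation numeric length-3 translation in mm.
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (!all(is.finite(R)) || !all(is.finite(object@translation)))
    return("non-finite transform entries")
  if (length(object@translation) != 3L) return("translation must be length 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    return("rotation is not orthonormal")
  if (abs(det(R) - 1) > 1e-6)
    return("rotation determinant must be +1 (no reflection)")
  TRUE
})

#' One synthetic patient: paired MR/CT volumes with ground truth
#'
#' All volumes share one grid. `labelMap` holds the tissue labels the
#' renderers consumed; `boneMask` is the MR-frame bone segmentation
#' (cancellous + cortical + intra-bone lesion), `lesionMask` the lesion
#' segmentation. `ctBoneMask` is the CT-frame bone segmentation, identical
#' to `boneMask` until a misalignment is applied; `trueTransform` then
#' records the rigid map that realigns the CT frame to the MR frame.
#'
#' @slot caseId character identifier.
#' @slot lesionType one of `"osteolytic"`, `"osteoblastic"`, `"mixed"`, or
#'   `"none"` for a lesion-free phantom.
#' @slot labelMap integer tissue-label volume.
#' @slot ct CT volume in Hounsfield units.
#' @slot mrEcho1,mrEcho2 MR magnitude volumes (arbitrary units).
#' @slot boneMask,lesionMask,ctBoneMask logical volumes.
#' @slot spacing voxel spacing in mm (length 3).
#' @slot trueTransform [RigidTransform-class] realigning CT to MR.
#' @slot seed integer seed the case was generated from.
#' @export
setClass("PhantomCase",
  representation(
    caseId = "character", lesionType = "character",
    labelMap = "array", ct = "array",
    mrEcho1 = "array", mrEcho2 = "array",
    boneMask = "array", lesionMask = "array", ctBoneMask = "array",
    spacing = "numeric", trueTransform = "RigidTransform",
    seed = "integer"))

setValidity("PhantomCase", function(object) {
  d <- dim(object@labelMap)
  vols <- list(ct = object@ct, mrEcho1 = object@mrEcho1,
               mrEcho2 = object@mrEcho2, boneMask = object@boneMask,
               lesionMask = object@lesionMask, ctBoneMask = object@ctBoneMask)
  for (nm in names(vols))
    if (!identical(dim(vols[[nm]]), d))
      return(sprintf("volume '%s' does not share the label-map grid", nm))
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be three positive values (mm)")
  if (!any(object@boneMask)) return("bone mask is empty")
  if (!object@lesionType %in% c(.LESION_TYPES, "none"))
    return("unknown lesion type")
  TRUE
})

#' Intensity-normalized volume on the \[-1, 1\] scale
#'
#' Carries the record needed to invert the normalization: for CT the fixed
#' HU range (exactly invertible), for MR the per-volume percentile clip.
#'
#' @slot values volume with all values in \[-1, 1\].
#' @slot source `"mr"` or `"ct"`.
#' @slot record named list of normalization parameters.
#' @slot spacing voxel spacing in mm.
#' @export
setClass("NormalizedVolume",
  representation(values = "array", source = "character",
                 record = "list", spacing = "numeric"))

setValidity("NormalizedVolume", function(object) {
  if (!object@source %in% c("mr", "ct")) return("source must be 'mr' or 'ct'")
  rng <- range(object@values)
  if (rng[1] < -1 - 1e-9 || rng[2] > 1 + 1e-9)
    return("normalized values outside [-1, 1]")
  if (length(object@record) == 0) return("normalization record missing")
  TRUE
})

#' A trained MR-to-CT translation network
#'
#' Weights plus everything needed to reproduce its predictions in HU: the
#' architecture configuration, the training configuration, the
#' normalization conventions, and the per-epoch training/validation loss
#' history. `predictVolume()` is a pure function of the weights and input.
#'
#' @slot weights named list of layer weight matrices and bias vectors.
#' @slot netConfig list from [networkConfig()].
#' @slot trainConfig list from [trainConfig()] (empty for untrained nets).
#' @slot normMeta list: CT HU range and the MR percentile convention.
#' @slot history data.frame with one row per epoch (train/validation loss).
#' @export
setClass("TrainedModel",
  representation(weights = "list", netConfig = "list",
                 trainConfig = "list", normMeta = "list",
                 history = "data.frame"))

setValidity("TrainedModel", function(object) {
  if (length(object@weights) == 0) return("empty weight list")
  if (is.null(object@netConfig$patchSize)) return("netConfig incomplete")
  TRUE
})
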