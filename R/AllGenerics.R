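#' @name accessors
#' @title Accessors for boneSCT objects
#' @description Slot accessors; user code should use these rather than `@`.
#' @param object,x a boneSCT S4 object.
#' @return The slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("caseId", function(object) standardGeneric("caseId"))
#' @rdname accessors
#' @export
setGeneric("lesionType", function(object) standardGeneric("lesionType"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("ctVolume", function(object) standardGeneric("ctVolume"))
#' @rdname accessors
#' @export
setGeneric("mrVolumes", function(object) standardGeneric("mrVolumes"))
#' @rdname accessors
#' @export
setGeneric("boneMask", function(object) standardGeneric("boneMask"))
#' @rdname accessors
#' @export
setGeneric("lesionMask", function(object) standardGeneric("lesionMask"))
#' @rdname accessors
#' @export
setGeneric("labelMap", function(object) standardGeneric("labelMap"))
#' @rdname accessors
#' @export
setGeneric("trueTransform", function(object) standardGeneric("trueTransform"))
#' @rdname accessors
#' @export
setGeneric("normValues", function(object) standardGeneric("normValues"))
#' @rdname accessors
#' @export
setGeneric("normRecord", function(object) standardGeneric("normRecord"))
#' @rdname accessors
#' @export
setGeneric("modelWeights", function(object) standardGeneric("modelWeights"))
#' @rdname accessors
#' @export
setGeneric("trainingHistory",
           function(object) standardGeneric("trainingHistory"))

#' @rdname accessors
#' @export
setMethod("caseId", "PhantomCase", function(object) object@caseId)
#' @rdname accessors
#' @export
setMethod("lesionType", "PhantomCase", function(object) object@lesionType)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "PhantomCase", function(object) object@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "NormalizedVolume", function(object) object@spacing)
#' @rdname accessors
#' @export
setMethod("ctVolume", "PhantomCase", function(object) object@ct)
#' @rdname accessors
#' @export
setMethod("mrVolumes", "PhantomCase",
          function(object) list(echo1 = object@mrEcho1, echo2 = object@mrEcho2))
#' @rdname accessors
#' @export
setMethod("boneMask", "PhantomCase", function(object) object@boneMask)
#' @rdname accessors
#' @export
setMethod("lesionMask", "PhantomCase", function(object) object@lesionMask)
#' @rdname accessors
#' @export
setMethod("labelMap", "PhantomCase", function(object) object@labelMap)
#' @rdname accessors
#' @export
setMethod("trueTransform", "PhantomCase", function(object) object@trueTransform)
#' @rdname accessors
#' @export
setMethod("normValues", "NormalizedVolume", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("normRecord", "NormalizedVolume", function(object) object@record)
#' @rdname accessors
#' @export
setMethod("modelWeights", "TrainedModel", function(object) object@weights)
#' @rdname accessors
#' @export
setMethod("trainingHistory", "TrainedModel", function(object) object@history)

#' @describeIn RigidTransform-class compact display.
#' @param object a `RigidTransform`.
#' @export
setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform (moving -> fixed)\n")
  cat(sprintf("  rotation angle: %.3f deg\n", rotationAngle(object)))
  cat(sprintf("  translation:    [%.2f, %.2f, %.2f] mm\n",
              object@translation[1], object@translation[2],
              object@translation[3]))
})

#' @describeIn PhantomCase-class compact display.
#' @param object a `PhantomCase`.
#' @export
setMethod("show", "PhantomCase", function(object) {
  d <- dim(object@labelMap)
  cat(sprintf("PhantomCase '%s' (%s lesion)\n", object@caseId,
              object@lesionType))
  cat(sprintf("  grid: %d x %d x %d voxels @ [%g, %g, %g] mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  bone voxels: %d, lesion voxels: %d\n",
              sum(object@boneMask), sum(object@lesionMask)))
})

#' @describeIn NormalizedVolume-class compact display.
#' @param object a `NormalizedVolume`.
#' @export
setMethod("show", "NormalizedVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("NormalizedVolume (%s): %d x %d x %d, range [%.3f, %.3f]\n",
              object@source, d[1], d[2], d[3],
              min(object@values), max(object@values)))
})

#' @describeIn TrainedModel-class compact display.
#' @param object a `TrainedModel`.
#' @export
setMethod("show", "TrainedModel", function(object) {
  cfg <- object@netConfig
  cat(sprintf(
    "TrainedModel: %d-level UNet, base %d filters, patch %d^3, %d parameters\n",
    cfg$levels, cfg$baseFilters, cfg$patchSize, parameterCount(object)))
  if (nrow(object@history) > 0)
    cat(sprintf("  trained %d epochs; best validation L1 = %.4f\n",
                nrow(object@history), min(object@history$validationLoss)))
  else cat("  untrained (initialization only)\n")
})
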