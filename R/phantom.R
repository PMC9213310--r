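# Digital MR/CT bone phantom: a stylized long-bone/hemipelvis (tube with a
# flared top) embedded in muscle, fat and water, carrying osteolytic,
# osteoblastic or mixed lesions. All geometry is computed in physical mm so
# anisotropic grids (1 x 1 x 2 mm by default) behave correctly.

#' Tissue properties for phantom rendering
#'
#' CT properties (`huMean`, `huSd`) and MR properties (proton density,
#' relaxation times, fat fraction) for one tissue class.
#'
#' @param name tissue label name.
#' @param huMean,huSd CT mean and noise SD in HU.
#' @param protonDensity relative proton density in \[0, 1\].
#' @param t1,t2Star relaxation times in ms (both > 0).
#' @param fatFraction fat signal fraction in \[0, 1\].
#' @return A named list of class `"tissueProperties"`.
#' @export
tissueProperties <- function(name, huMean, huSd, protonDensity, t1, t2Star,
                             fatFraction) {
  stopifnot(t1 > 0, t2Star > 0,
            protonDensity >= 0, protonDensity <= 1,
            fatFraction >= 0, fatFraction <= 1,
            huSd >= 0)
  structure(list(name = name, huMean = huMean, huSd = huSd,
                 protonDensity = protonDensity, t1 = t1, t2Star = t2Star,
                 fatFraction = fatFraction),
            class = "tissueProperties")
}

#' Default tissue table
#'
#' HU values straddle the 150-HU bone-extraction threshold (cortical 1200,
#' cancellous 300 above it; marrow, muscle, fat, water below). MR
#' parameters are plausible 1.5-T values chosen for realistic T1-weighted
#' gradient-echo contrast: bright fat/marrow, intermediate muscle, near-void
#' cortical bone (very short T2*, low proton density). Lesion entries are
#' placeholders whose HU is finalized per lesion by [phantomSpec()].
#'
#' @return Named list of [tissueProperties()], one per label.
#' @export
defaultTissueTable <- function() {
  list(
    water = tissueProperties("water", 0, 10, 1.00, 3000, 200, 0.00),
    fat = tissueProperties("fat", -100, 20, 0.95, 300, 60, 0.90),
    muscle = tissueProperties("muscle", 40, 15, 0.80, 900, 35, 0.05),
    marrow = tissueProperties("marrow", -50, 20, 0.90, 350, 50, 0.80),
    cancellous = tissueProperties("cancellous", 300, 50, 0.50, 500, 30, 0.40),
    cortical = tissueProperties("cortical", 1200, 50, 0.05, 1000, 2, 0.00),
    lesion_lytic = tissueProperties("lesion_lytic", -100, 30, 0.90, 1000, 60,
                                    0.05),
    lesion_blastic = tissueProperties("lesion_blastic", 700, 50, 0.20, 700,
                                      10, 0.05)
  )
}

#' Dual-echo spoiled gradient-echo acquisition parameters
#'
#' Defaults reproduce a radiofrequency-spoiled T1-weighted dual-echo
#' gradient-echo protocol at 1.5 T: TE 2.1 / 4.2 ms, TR 7 ms, flip 10
#' degrees. The fat-water resonance shift defaults to 220 Hz (about
#' 3.5 ppm at 1.5 T), which places the first echo close to opposed phase
#' and the second close to in phase.
#'
#' @param te1,te2 echo times, ms (0 < te1 < te2 < tr).
#' @param tr repetition time, ms.
#' @param flipAngle degrees, in (0, 90).
#' @param fieldStrength tesla.
#' @param fatWaterShift Hz.
#' @param noiseSd additive Gaussian noise SD as a fraction of the maximum
#'   noise-free signal; 0 disables noise.
#' @return Named list of class `"acquisitionParams"`.
#' @export
acquisitionParams <- function(te1 = 2.1, te2 = 4.2, tr = 7, flipAngle = 10,
                              fieldStrength = 1.5, fatWaterShift = 220,
                              noiseSd = 0.02) {
  if (!(te1 > 0 && te1 < te2 && te2 < tr))
    stop("echo times must satisfy 0 < te1 < te2 < tr")
  if (!(flipAngle > 0 && flipAngle < 90))
    stop("flip angle must lie in (0, 90) degrees")
  stopifnot(noiseSd >= 0)
  structure(list(te1 = te1, te2 = te2, tr = tr, flipAngle = flipAngle,
                 fieldStrength = fieldStrength,
                 fatWaterShift = fatWaterShift, noiseSd = noiseSd),
            class = "acquisitionParams")
}

#' Spoiled gradient-echo steady-state magnitude signal
#'
#' \deqn{S(TE) = PD \sin\alpha \frac{1 - E_1}{1 - \cos\alpha\, E_1}
#'   e^{-TE/T_2^*} \left| (1 - ff) + ff\, e^{i 2\pi \Delta f\, TE} \right|}
#' with \eqn{E_1 = e^{-TR/T_1}}, TE/TR in ms and the fat-water shift
#' \eqn{\Delta f} in Hz. Vectorized over tissue parameters.
#'
#' @param pd proton density.
#' @param t1,t2Star ms.
#' @param fatFraction fat signal fraction.
#' @param te,tr ms; `te < tr` required.
#' @param flipAngle degrees.
#' @param fatWaterShift Hz.
#' @return Magnitude signal (arbitrary units).
#' @export
sgreSignal <- function(pd, t1, t2Star, fatFraction, te, tr, flipAngle,
                       fatWaterShift = 220) {
  if (any(te >= tr)) stop("TE must be smaller than TR")
  a <- flipAngle * pi / 180
  e1 <- exp(-tr / t1)
  phase <- 2 * pi * fatWaterShift * te / 1000  # TE ms -> s
  phasor <- Mod((1 - fatFraction) + fatFraction * exp(1i * phase))
  pd * sin(a) * (1 - e1) / (1 - cos(a) * e1) * exp(-te / t2Star) * phasor
}

#' Specify one metastatic lesion
#'
#' @param lesionType `"osteolytic"`, `"osteoblastic"` or `"mixed"`.
#' @param center voxel index triple (1-based) of the lesion center.
#' @param radiusMm lesion radius in mm (> 0).
#' @param corticalBreach if `TRUE`, a contiguous window of cortical shell
#'   adjacent to the lesion is replaced by lesion tissue.
#' @param huDelta HU offset of lesion tissue relative to cancellous bone:
#'   negative for the lytic component, positive for the blastic component.
#'   For `"mixed"`, a length-2 vector `c(lytic, blastic)`. Defaults:
#'   -400, +400, c(-400, +400).
#' @return Named list of class `"lesionSpec"`.
#' @export
lesionSpec <- function(lesionType, center, radiusMm, corticalBreach = FALSE,
                       huDelta = NULL) {
  lesionType <- match.arg(lesionType, .LESION_TYPES)
  stopifnot(radiusMm > 0, length(center) == 3)
  if (is.null(huDelta))
    huDelta <- switch(lesionType, osteolytic = -400, osteoblastic = 400,
                      mixed = c(-400, 400))
  if (lesionType == "osteolytic" && any(huDelta >= 0))
    stop("osteolytic lesions need huDelta < 0")
  if (lesionType == "osteoblastic" && any(huDelta <= 0))
    stop("osteoblastic lesions need huDelta > 0")
  if (lesionType == "mixed" &&
      !(length(huDelta) == 2 && huDelta[1] < 0 && huDelta[2] > 0))
    stop("mixed lesions need huDelta = c(lytic < 0, blastic > 0)")
  structure(list(lesionType = lesionType, center = as.integer(center),
                 radiusMm = radiusMm, corticalBreach = corticalBreach,
                 huDelta = huDelta),
            class = "lesionSpec")
}

#' Specify a phantom
#'
#' Geometry is a stylized long bone: a cortical tube (flared towards the
#' top, hemipelvis-like) with cancellous interior and central marrow
#' cavity, inside an elliptic muscle body with a subcutaneous fat ring,
#' surrounded by water. Lesion HU values are finalized here as cancellous
#' mean + `huDelta`.
#'
#' @param shape voxel grid, default `c(64, 64, 64)`.
#' @param spacing voxel spacing in mm, default `c(1, 1, 2)`.
#' @param corticalThicknessMm cortical shell thickness.
#' @param boneOuterRadiusMm outer bone radius at the shaft.
#' @param marrowRadiusFrac marrow cavity radius as a fraction of the inner
#'   bone radius.
#' @param boneCenterMm xy position of the bone axis in mm; default volume
#'   center.
#' @param boneAspect ratio of the short to the long cross-section axis of
#'   the bone (long bones are oval, not circular; this also makes the
#'   surface rotationally asymmetric, which real bones are).
#' @param flareFrac fractional radius increase at the flared top (0 = pure
#'   tube). The flare is one-sided (lateral), like a trochanter or iliac
#'   flare, breaking the remaining 180-degree symmetry.
#' @param lesions list of [lesionSpec()] objects.
#' @param tissueTable named list of [tissueProperties()].
#' @param ctNoise draw per-voxel Gaussian HU noise?
#' @param ctBlurSigmaMm Gaussian point-spread sigma (mm) applied to CT to
#'   create partial-volume boundary voxels; 0 disables.
#' @param mrBlurSigmaMm same for the MR magnitudes. The default matches the
#'   CT point-spread so both modalities share one effective resolution, as
#'   they do after resampling a clinical CT onto the MR grid.
#' @param trabecularTexture maximum marrow fraction of the trabecular
#'   texture field (0 disables). Cancellous bone is rendered as a
#'   spatially smooth, seeded mixture of trabecular bone and fatty marrow;
#'   the same field drives the CT attenuation and the MR tissue
#'   parameters, emulating the heterogeneous -50 to 400 HU interior of
#'   real pelvic and femoral bone.
#' @param textureScaleMm correlation length of the texture field, mm.
#' @param seed integer seed; geometry, CT noise and MR noise use
#'   independent streams derived from it, so toggling noise never changes
#'   geometry.
#' @return Named list of class `"phantomSpec"`.
#' @export
phantomSpec <- function(shape = c(64, 64, 64), spacing = c(1, 1, 2),
                        corticalThicknessMm = 3, boneOuterRadiusMm = 16,
                        marrowRadiusFrac = 0.45, boneCenterMm = NULL,
                        boneAspect = 0.75, flareFrac = 0.25,
                        lesions = list(),
                        tissueTable = defaultTissueTable(),
                        ctNoise = TRUE, ctBlurSigmaMm = 0.8,
                        mrBlurSigmaMm = 0.8, trabecularTexture = 0.7,
                        textureScaleMm = 3, seed = 1L) {
  stopifnot(length(shape) == 3, all(shape >= 8),
            length(spacing) == 3, all(spacing > 0),
            corticalThicknessMm > 0, boneOuterRadiusMm > corticalThicknessMm,
            marrowRadiusFrac > 0, marrowRadiusFrac < 1,
            boneAspect > 0, boneAspect <= 1)
  if (is.null(boneCenterMm))
    boneCenterMm <- (shape[1:2] - 1) * spacing[1:2] / 2
  for (les in lesions)
    if (!inherits(les, "lesionSpec")) stop("lesions must be lesionSpec objects")
  # finalize lesion HU relative to cancellous bone
  base <- tissueTable$cancellous$huMean
  for (les in lesions) {
    if (les$lesionType %in% c("osteolytic", "mixed"))
      tissueTable$lesion_lytic$huMean <- base + les$huDelta[1]
    if (les$lesionType == "osteoblastic")
      tissueTable$lesion_blastic$huMean <- base + les$huDelta[1]
    if (les$lesionType == "mixed")
      tissueTable$lesion_blastic$huMean <- base + les$huDelta[2]
  }
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 corticalThicknessMm = corticalThicknessMm,
                 boneOuterRadiusMm = boneOuterRadiusMm,
                 marrowRadiusFrac = marrowRadiusFrac,
                 boneCenterMm = boneCenterMm, boneAspect = boneAspect,
                 flareFrac = flareFrac,
                 lesions = lesions, tissueTable = tissueTable,
                 ctNoise = ctNoise, ctBlurSigmaMm = ctBlurSigmaMm,
                 mrBlurSigmaMm = mrBlurSigmaMm,
                 trabecularTexture = trabecularTexture,
                 textureScaleMm = textureScaleMm, seed = as.integer(seed)),
            class = "phantomSpec")
}

# Physical coordinate arrays (mm) for a grid.
coordArrays <- function(shape, spacing) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  list(x = array((seq_len(nx) - 1) * spacing[1], shape),
       y = array(rep((seq_len(ny) - 1) * spacing[2], each = nx), shape),
       z = array(rep((seq_len(nz) - 1) * spacing[3], each = nx * ny), shape))
}

#' Build the tissue label map of a phantom
#'
#' Deterministic for a given spec. Labels: water 0, fat 1, muscle 2,
#' marrow 3, cancellous 4, cortical 5, lytic lesion 6, blastic lesion 7.
#'
#' @param spec a [phantomSpec()].
#' @return Integer label volume with a `"spacing"` attribute.
#' @export
buildLabelMap <- function(spec) {
  stopifnot(inherits(spec, "phantomSpec"))
  shape <- spec$shape; spacing <- spec$spacing
  co <- coordArrays(shape, spacing)
  ext <- (shape - 1) * spacing
  cx <- ext[1] / 2; cy <- ext[2] / 2

  lab <- array(.LABELS[["water"]], shape)
  # body: elliptic cylinder of muscle with a fat ring
  axMm <- 0.48 * ext[1]; ayMm <- 0.48 * ext[2]
  e <- sqrt(((co$x - cx) / axMm)^2 + ((co$y - cy) / ayMm)^2)
  lab[e <= 1] <- .LABELS[["fat"]]
  lab[e <= 0.85] <- .LABELS[["muscle"]]

  # oval bone tube with a one-sided flare towards the top of the volume
  bx <- spec$boneCenterMm[1]; by <- spec$boneCenterMm[2]
  dx <- co$x - bx; dy <- co$y - by
  rb <- sqrt(dx^2 + (dy / spec$boneAspect)^2)
  zfrac <- pmax(0, (co$z - 0.65 * ext[3]) / (0.35 * ext[3]))
  lateral <- 0.65 + 0.35 * dx / pmax(rb, 1e-9)  # flare biased toward +x
  rOuter <- spec$boneOuterRadiusMm *
    (1 + spec$flareFrac * zfrac^2 * lateral)
  rInner <- rOuter - spec$corticalThicknessMm
  lab[rb <= rOuter] <- .LABELS[["cortical"]]
  lab[rb <= rInner] <- .LABELS[["cancellous"]]
  lab[rb <= spec$marrowRadiusFrac * rInner] <- .LABELS[["marrow"]]

  for (i in seq_along(spec$lesions)) {
    les <- spec$lesions[[i]]
    cMm <- (les$center - 1) * spacing
    d <- sqrt((co$x - cMm[1])^2 + (co$y - cMm[2])^2 + (co$z - cMm[3])^2)
    sphere <- d <= les$radiusMm
    interior <- lab == .LABELS[["marrow"]] | lab == .LABELS[["cancellous"]]
    if (!any(sphere & interior))
      stop(sprintf("lesion %d lies outside the bone interior", i))
    if (les$lesionType == "osteolytic") {
      lab[sphere & interior] <- .LABELS[["lesion_lytic"]]
    } else if (les$lesionType == "osteoblastic") {
      lab[sphere & interior] <- .LABELS[["lesion_blastic"]]
    } else {  # mixed: lytic core, blastic rim
      lab[sphere & interior & d > 0.6 * les$radiusMm] <-
        .LABELS[["lesion_blastic"]]
      lab[interior & d <= 0.6 * les$radiusMm] <- .LABELS[["lesion_lytic"]]
    }
    if (isTRUE(les$corticalBreach)) {
      breachLabel <- if (les$lesionType == "osteoblastic")
        .LABELS[["lesion_blastic"]] else .LABELS[["lesion_lytic"]]
      window <- lab == .LABELS[["cortical"]] &
        d <= les$radiusMm + spec$corticalThicknessMm
      lab[window] <- breachLabel
    }
  }
  storage.mode(lab) <- "integer"
  attr(lab, "spacing") <- spacing
  lab
}

# Separable Gaussian blur with edge-clamped (replicated) boundaries.
gaussianBlur3 <- function(vol, sigmaVox) {
  for (axis in 1:3) {
    s <- sigmaVox[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    w <- stats::dnorm(-r:r, sd = s)
    w <- w / sum(w)
    n <- dim(vol)[axis]
    out <- array(0, dim(vol))
    for (sh in -r:r) {
      idx <- pmin(pmax(seq_len(n) + sh, 1L), n)
      sl <- switch(axis, vol[idx, , , drop = FALSE],
                   vol[, idx, , drop = FALSE], vol[, , idx, drop = FALSE])
      out <- out + w[sh + r + 1] * sl
    }
    vol <- out
  }
  vol
}

# Per-voxel marrow fraction of the trabecular texture inside the
# cancellous compartment: a smoothed, seeded Gaussian field mapped through
# its own CDF to [0, 1] and scaled by the texture strength. Drawn from the
# geometry stream, so toggling CT/MR noise never changes it.
trabecularField <- function(labelMap, spec) {
  if (is.null(spec$trabecularTexture) || spec$trabecularTexture <= 0)
    return(NULL)
  sel <- labelMap == .LABELS[["cancellous"]]
  if (!any(sel)) return(NULL)
  seedGeom <- deriveSeeds(spec$seed, 3)[1]
  field <- withSeed(seedGeom,
                    array(rnorm(length(labelMap)), dim(labelMap)))
  field <- gaussianBlur3(field, spec$textureScaleMm / spec$spacing)
  field <- (field - mean(field)) / stats::sd(field)
  mf <- array(0, dim(labelMap))
  mf[sel] <- stats::pnorm(field[sel]) * spec$trabecularTexture
  mf
}

# Blend a per-voxel property toward marrow by the marrow fraction.
blendProperty <- function(values, mf, marrowValue) {
  if (is.null(mf)) return(values)
  values + mf * (marrowValue - values)
}

# Look up one numeric tissue property per voxel from the label map.
lookupProperty <- function(labelMap, tissueTable, field) {
  labs <- .LABELS[names(tissueTable)]
  tab <- rep(NA_real_, max(.LABELS) + 1)
  tab[labs + 1] <- vapply(tissueTable, function(tp) tp[[field]], numeric(1))
  present <- sort(unique(as.integer(labelMap)))
  unknown <- present[is.na(tab[present + 1])]
  if (length(unknown))
    stop(sprintf("label(s) %s missing from the tissue table",
                 paste(unknown, collapse = ", ")))
  array(tab[as.integer(labelMap) + 1], dim(labelMap))
}

#' Render the CT arm of a phantom
#'
#' Per-voxel HU drawn as `huMean + N(0, huSd)` from the tissue table (with
#' the cancellous compartment blended toward marrow by the trabecular
#' texture field), then blurred with a small Gaussian point-spread kernel
#' so boundary voxels carry partial-volume values. With `ctNoise = FALSE`,
#' `ctBlurSigmaMm = 0` and `trabecularTexture = 0` the rendering is an
#' exact per-label lookup.
#'
#' @param labelMap from [buildLabelMap()].
#' @param spec the [phantomSpec()].
#' @return HU volume with a `"spacing"` attribute.
#' @export
renderCT <- function(labelMap, spec) {
  mf <- trabecularField(labelMap, spec)
  hu <- blendProperty(lookupProperty(labelMap, spec$tissueTable, "huMean"),
                      mf, spec$tissueTable$marrow$huMean)
  if (isTRUE(spec$ctNoise)) {
    huSd <- blendProperty(
      lookupProperty(labelMap, spec$tissueTable, "huSd"),
      mf, spec$tissueTable$marrow$huSd)
    noise <- withSeed(deriveSeeds(spec$seed, 3)[2],
                      array(rnorm(length(hu)), dim(hu)))
    hu <- hu + huSd * noise
  }
  if (spec$ctBlurSigmaMm > 0)
    hu <- gaussianBlur3(hu, spec$ctBlurSigmaMm / spec$spacing)
  attr(hu, "spacing") <- spec$spacing
  hu
}

#' Render the dual-echo MR arm of a phantom
#'
#' Evaluates the spoiled gradient-echo steady-state magnitude
#' ([sgreSignal()]) per voxel at both echo times, then adds Gaussian noise
#' scaled by `acq$noiseSd` times the maximum noise-free signal. Magnitudes
#' are clamped at zero. Both echoes share the grid of the label map.
#'
#' @param labelMap from [buildLabelMap()].
#' @param spec the [phantomSpec()].
#' @param acq an [acquisitionParams()].
#' @return List with `echo1` and `echo2` volumes.
#' @export
renderMR <- function(labelMap, spec, acq = acquisitionParams()) {
  stopifnot(inherits(acq, "acquisitionParams"))
  mf <- trabecularField(labelMap, spec)
  marrow <- spec$tissueTable$marrow
  pd <- blendProperty(
    lookupProperty(labelMap, spec$tissueTable, "protonDensity"),
    mf, marrow$protonDensity)
  t1 <- blendProperty(lookupProperty(labelMap, spec$tissueTable, "t1"),
                      mf, marrow$t1)
  t2s <- blendProperty(lookupProperty(labelMap, spec$tissueTable, "t2Star"),
                       mf, marrow$t2Star)
  ff <- blendProperty(
    lookupProperty(labelMap, spec$tissueTable, "fatFraction"),
    mf, marrow$fatFraction)
  echoes <- lapply(c(acq$te1, acq$te2), function(te) {
    s <- sgreSignal(pd, t1, t2s, ff, te, acq$tr, acq$flipAngle,
                    acq$fatWaterShift)
    array(s, dim(labelMap))
  })
  if (spec$mrBlurSigmaMm > 0)
    echoes <- lapply(echoes, gaussianBlur3, spec$mrBlurSigmaMm / spec$spacing)
  if (acq$noiseSd > 0) {
    smax <- max(vapply(echoes, max, numeric(1)))
    seeds <- deriveSeeds(spec$seed, 3)
    echoes <- withSeed(seeds[3], lapply(echoes, function(e)
      array(pmax(e + rnorm(length(e), 0, acq$noiseSd * smax), 0), dim(e))))
  }
  for (i in 1:2) attr(echoes[[i]], "spacing") <- spec$spacing
  names(echoes) <- c("echo1", "echo2")
  echoes
}

# Masks derivable from the label map: bone = cancellous + cortical +
# intra-bone lesion tissue; lesion = the lesion labels.
masksFromLabelMap <- function(labelMap) {
  bone <- array(as.integer(labelMap) %in% .LABELS[.BONE_LABELS],
                dim(labelMap))
  lesion <- array(as.integer(labelMap) %in% .LABELS[.LESION_LABELS],
                  dim(labelMap))
  list(bone = bone, lesion = lesion)
}

#' Simulate one phantom case
#'
#' Builds the label map, renders CT and both MR echoes, and derives the
#' ground-truth bone and lesion masks. The recorded `trueTransform` is the
#' identity (CT and MR start co-registered); use [applyMisalignment()] to
#' create registration test inputs.
#'
#' @param spec a [phantomSpec()].
#' @param caseId character id.
#' @param acq an [acquisitionParams()].
#' @return A [PhantomCase-class].
#' @examples
#' les <- lesionSpec("osteoblastic", center = c(33, 33, 28), radiusMm = 8)
#' case <- simulateCase(phantomSpec(lesions = list(les), seed = 7), "demo")
#' case
#' @export
simulateCase <- function(spec, caseId = "case", acq = acquisitionParams()) {
  lab <- buildLabelMap(spec)
  ct <- renderCT(lab, spec)
  mr <- renderMR(lab, spec, acq)
  masks <- masksFromLabelMap(lab)
  ltype <- if (length(spec$lesions)) spec$lesions[[1]]$lesionType else "none"
  new("PhantomCase", caseId = caseId, lesionType = ltype,
      labelMap = lab, ct = ct, mrEcho1 = mr$echo1, mrEcho2 = mr$echo2,
      boneMask = masks$bone, lesionMask = masks$lesion,
      ctBoneMask = masks$bone, spacing = spec$spacing,
      trueTransform = rigidTransform(), seed = spec$seed)
}

#' Misalign the CT arm of a case
#'
#' Resamples the CT (and its bone mask) so that realigning it with the MR
#' frame requires `transform`; the transform is recorded as
#' `trueTransform` so a registration result can be checked against it.
#' Images use the given interpolation, masks nearest neighbour. A warning
#' reports the fraction of CT bone voxels pushed outside the field of view.
#'
#' @param case a [PhantomCase-class].
#' @param transform [RigidTransform-class] realigning CT to MR (the
#'   misapplied motion is its inverse).
#' @param interpolation for the CT image: `"linear"`, `"bspline"` or
#'   `"nearest"`.
#' @return A new [PhantomCase-class] with misaligned CT-frame data.
#' @export
applyMisalignment <- function(case, transform, interpolation = "linear") {
  inv <- invertTransform(transform)
  ct <- resampleVolume(case@ct, inv, case@spacing,
                       interpolation = interpolation, background = -1024)
  mask <- resampleVolume(case@ctBoneMask + 0, inv, case@spacing,
                         interpolation = "nearest", background = 0)
  clipped <- 1 - sum(mask > 0.5) / sum(case@ctBoneMask)
  if (clipped > 0.01)
    warning(sprintf("misalignment clipped %.1f%% of the CT bone mask",
                    100 * clipped))
  new("PhantomCase", caseId = case@caseId, lesionType = case@lesionType,
      labelMap = case@labelMap, ct = ct, mrEcho1 = case@mrEcho1,
      mrEcho2 = case@mrEcho2, boneMask = case@boneMask,
      lesionMask = case@lesionMask, ctBoneMask = array(mask > 0.5, dim(mask)),
      spacing = case@spacing, trueTransform = transform, seed = case@seed)
}

#' Simulate a cohort of phantom cases
#'
#' The default cohort reproduces the study composition: nine cases, of
#' which 3 osteolytic, 4 osteoblastic and 2 mixed. When `n` equals the sum
#' of `composition` the exact histogram is used (in seeded random order);
#' otherwise types are drawn with probabilities proportional to
#' `composition`. Anatomy (bone radius, cortical thickness, position,
#' flare) and lesion placement are randomized per case from seeds derived
#' from `seed`, so the cohort is bitwise reproducible.
#'
#' @param n number of cases (>= 2).
#' @param baseSpec a [phantomSpec()] supplying grid, tissue table and
#'   rendering options.
#' @param seed integer cohort seed.
#' @param composition named counts for
#'   `osteolytic` / `osteoblastic` / `mixed`.
#' @param acq an [acquisitionParams()].
#' @return List of [PhantomCase-class] objects; attribute `"seeds"` holds
#'   the per-case seeds.
#' @export
makeCohort <- function(n = 9L, baseSpec = phantomSpec(), seed = 1L,
                       composition = c(osteolytic = 3, osteoblastic = 4,
                                       mixed = 2),
                       acq = acquisitionParams()) {
  stopifnot(n >= 2)
  seeds <- deriveSeeds(seed, n + 1L)
  types <- if (n == sum(composition))
    withSeed(seeds[n + 1L], sample(rep(names(composition), composition)))
  else
    withSeed(seeds[n + 1L],
             sample(names(composition), n, replace = TRUE,
                    prob = composition / sum(composition)))
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- withSeed(seeds[i],
                     randomCaseSpec(baseSpec, types[i], seeds[i]))
    cases[[i]] <- simulateCase(spec, sprintf("case%02d", i), acq)
  }
  attr(cases, "seeds") <- seeds[seq_len(n)]
  cases
}

# Draw a randomized per-case spec: jittered anatomy plus one lesion of the
# requested type placed inside the bone interior. Runs under the caller's
# seeded RNG.
randomCaseSpec <- function(baseSpec, type, caseSeed) {
  ext <- (baseSpec$shape - 1) * baseSpec$spacing
  R <- runif(1, 13, 17)
  ct <- runif(1, 2.5, 3.5)
  centerMm <- (baseSpec$shape[1:2] - 1) * baseSpec$spacing[1:2] / 2 +
    runif(2, -4, 4)
  flare <- runif(1, 0.15, 0.35)
  radius <- runif(1, 6, min(11, R - ct + 3))
  # lesion center: on the bone axis with a small radial offset, mid-shaft
  maxOff <- max(0, R - ct - 4)
  off <- runif(1, 0, maxOff)
  ang <- runif(1, 0, 2 * pi)
  zMm <- runif(1, 0.30, 0.55) * ext[3]
  centerVox <- round(c(centerMm[1] + off * cos(ang),
                       centerMm[2] + off * sin(ang), zMm) /
                       baseSpec$spacing) + 1
  centerVox <- pmin(pmax(centerVox, 2), baseSpec$shape - 1)
  breach <- type %in% c("osteolytic", "mixed") && runif(1) < 0.6
  delta <- runif(1, 350, 450)
  hd <- switch(type, osteolytic = -delta, osteoblastic = delta,
               mixed = c(-delta, runif(1, 350, 450)))
  les <- lesionSpec(type, centerVox, radius, corticalBreach = breach,
                    huDelta = hd)
  phantomSpec(shape = baseSpec$shape, spacing = baseSpec$spacing,
              corticalThicknessMm = ct, boneOuterRadiusMm = R,
              marrowRadiusFrac = baseSpec$marrowRadiusFrac,
              boneCenterMm = centerMm, boneAspect = runif(1, 0.7, 0.85),
              flareFrac = flare,
              lesions = list(les), tissueTable = baseSpec$tissueTable,
              ctNoise = baseSpec$ctNoise,
              ctBlurSigmaMm = baseSpec$ctBlurSigmaMm,
              mrBlurSigmaMm = baseSpec$mrBlurSigmaMm,
              trabecularTexture = baseSpec$trabecularTexture,
              textureScaleMm = baseSpec$textureScaleMm, seed = caseSeed)
}
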