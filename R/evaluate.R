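# sCT-vs-CT evaluation: region-restricted intensity differences, 150-HU
# bone extraction, Dice overlap, directed surface RMSD with a 3-cm lesion
# margin, and cohort summarization (mean and sample SD).

#' Evaluation configuration
#'
#' @param boneThresholdHU HU threshold extracting cancellous + cortical
#'   bone, default 150 (inclusive: `>= 150`).
#' @param lesionMarginMm margin dilating the lesion mask for the surface
#'   distance only, default 30 mm.
#' @param symmetricRMSD if `TRUE`, [surfaceRMSD()] averages both
#'   directions; the default is the directed sCT-surface-to-CT-surface
#'   distance.
#' @return Named list of class `"evalConfig"`.
#' @export
evalConfig <- function(boneThresholdHU = 150, lesionMarginMm = 30,
                       symmetricRMSD = FALSE) {
  stopifnot(is.finite(boneThresholdHU), lesionMarginMm >= 0)
  structure(list(boneThresholdHU = boneThresholdHU,
                 lesionMarginMm = lesionMarginMm,
                 symmetricRMSD = isTRUE(symmetricRMSD)),
            class = "evalConfig")
}

#' Mean absolute difference within a mask
#'
#' @param sct,ct HU volumes on one grid.
#' @param mask nonempty logical volume.
#' @return Mean of `|sCT - CT|` over the mask, HU.
#' @export
madHU <- function(sct, ct, mask) {
  if (!any(mask)) stop("empty evaluation mask")
  mean(abs(sct[mask] - ct[mask]))
}

#' Mean (signed) difference within a mask
#'
#' Sign convention: sCT minus CT, so negative values mean the sCT
#' underestimates the CT intensity.
#'
#' @inheritParams madHU
#' @return Mean of `sCT - CT` over the mask, HU.
#' @export
mdHU <- function(sct, ct, mask) {
  if (!any(mask)) stop("empty evaluation mask")
  mean(sct[mask] - ct[mask])
}

#' Extract bone by HU threshold within a mask
#'
#' @param volumeHU HU volume.
#' @param mask logical region restriction.
#' @param threshold HU threshold (inclusive), default 150.
#' @return Logical volume: `volumeHU >= threshold & mask`. May be empty.
#' @export
extractBone <- function(volumeHU, mask, threshold = 150) {
  array(volumeHU >= threshold & mask, dim(volumeHU))
}

#' Dice similarity coefficient
#'
#' `2 |A n B| / (|A| + |B|)`. Two empty sets agree perfectly on absence:
#' the result is 1, with a warning, so fully lytic lesions with no residual
#' bone in either image do not crash the pipeline.
#'
#' @param a,b logical volumes on one grid.
#' @return DSC in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("dice: shape mismatch")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) {
    warning("both masks empty; returning DSC = 1 (agreement on absence)")
    return(1)
  }
  2 * sum(a & b) / (sa + sb)
}

#' Directed root-mean-square surface distance
#'
#' For every boundary-voxel center of `a` (the sCT-derived bone), the
#' Euclidean distance in mm to the nearest boundary-voxel center of `b`
#' (the CT-derived bone), root-mean-squared. Boundaries are 6-connectivity
#' voxel centers; distances come from an exact anisotropic distance
#' transform of the reference surface. `symmetric = TRUE` returns the RMS
#' over both directions pooled.
#'
#' @param a,b nonempty logical volumes on one grid.
#' @param spacing voxel spacing in mm.
#' @param symmetric pool both directions?
#' @return RMSD in mm.
#' @export
surfaceRMSD <- function(a, b, spacing = c(1, 1, 1), symmetric = FALSE) {
  if (!identical(dim(a), dim(b))) stop("surfaceRMSD: shape mismatch")
  if (!any(a)) stop("surfaceRMSD: empty source (sCT) region")
  if (!any(b)) stop("surfaceRMSD: empty reference (CT) region")
  d <- dim(a)
  bndA <- array(cpp_boundary6(as.logical(a), d), d)
  bndB <- array(cpp_boundary6(as.logical(b), d), d)
  dtB <- cpp_edt(as.logical(bndB), d, spacing)
  sq <- dtB[bndA]^2
  if (symmetric) {
    dtA <- cpp_edt(as.logical(bndA), d, spacing)
    sq <- c(sq, dtA[bndB]^2)
  }
  sqrt(mean(sq))
}

#' Dilate a mask by a physical margin
#'
#' Keeps every voxel whose center lies within Euclidean distance
#' `marginMm` of some voxel center of the original mask, honoring
#' anisotropic spacing. `marginMm = 0` is the identity.
#'
#' @param mask logical volume.
#' @param marginMm margin in mm (>= 0).
#' @param spacing voxel spacing in mm.
#' @return Dilated logical volume.
#' @export
dilateMask <- function(mask, marginMm, spacing = c(1, 1, 1)) {
  stopifnot(marginMm >= 0)
  if (marginMm == 0 || !any(mask)) return(mask)
  d <- dim(mask)
  array(cpp_edt(as.logical(mask), d, spacing) <= marginMm, d)
}

#' Evaluate one case: bone and lesion metric reports
#'
#' Bone region: MAD/MD over the bone mask on raw HU; DSC and surface RMSD
#' between the 150-HU extractions of sCT and CT within the bone mask.
#' Lesion region: MAD/MD over the (undilated) lesion mask; DSC on the
#' extractions within the lesion mask; the surface distance alone uses the
#' lesion mask dilated by the 3-cm margin. A region whose extraction is
#' empty on either side yields `NA` for the affected overlap/surface
#' metric with a warning, never a silent 0.
#'
#' @param sct,ct HU volumes on one grid.
#' @param boneMask,lesionMask logical volumes.
#' @param spacing voxel spacing in mm.
#' @param cfg an [evalConfig()].
#' @param caseId id written into the report rows.
#' @return data.frame with rows `bone` and `lesion` and columns `caseId`,
#'   `region`, `mad`, `md`, `dsc`, `rmsd`.
#' @export
evaluateCase <- function(sct, ct, boneMask, lesionMask,
                         spacing = attr(ct, "spacing"), cfg = evalConfig(),
                         caseId = "case") {
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  thr <- cfg$boneThresholdHU
  oneRegion <- function(region, valueMask, surfMask) {
    a <- extractBone(sct, surfMask, thr)
    b <- extractBone(ct, surfMask, thr)
    dsc <- if (region == "lesion") {
      al <- extractBone(sct, valueMask, thr)
      bl <- extractBone(ct, valueMask, thr)
      dice(al, bl)
    } else dice(a, b)
    rmsd <- if (any(a) && any(b)) surfaceRMSD(a, b, spacing,
                                              cfg$symmetricRMSD)
    else {
      warning(sprintf("empty 150-HU extraction in region '%s'; RMSD is NA",
                      region))
      NA_real_
    }
    data.frame(caseId = caseId, region = region,
               mad = madHU(sct, ct, valueMask),
               md = mdHU(sct, ct, valueMask),
               dsc = dsc, rmsd = rmsd)
  }
  rbind(oneRegion("bone", boneMask, boneMask),
        oneRegion("lesion", lesionMask,
                  dilateMask(lesionMask, cfg$lesionMarginMm, spacing)))
}

#' Summarize metric reports over a cohort
#'
#' Arithmetic mean and sample standard deviation (divisor n - 1) per
#' metric and region. With a single report the SD is `NA` (flagged
#' undefined), not 0.
#'
#' @param reports data.frame as returned by [evaluateCase()] /
#'   [loocv()] (columns `region`, `mad`, `md`, `dsc`, `rmsd`).
#' @return data.frame: one row per region x metric with `mean`, `sd`, `n`.
#' @export
cohortSummary <- function(reports) {
  stopifnot(all(c("region", "mad", "md", "dsc", "rmsd") %in%
                  colnames(reports)))
  metrics <- c("mad", "md", "dsc", "rmsd")
  out <- list()
  for (region in unique(reports$region)) {
    sub <- reports[reports$region == region, , drop = FALSE]
    for (m in metrics) {
      v <- sub[[m]][is.finite(sub[[m]])]
      out[[length(out) + 1L]] <- data.frame(
        region = region, metric = m, mean = mean(v),
        sd = if (length(v) >= 2) sd(v) else NA_real_,
        n = length(v))
    }
  }
  do.call(rbind, out)
}
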