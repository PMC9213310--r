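# Volume and cohort I/O. NIfTI-1 is the single volume format (clinical
# sources would be DICOM; conversion is out of scope and NIfTI is the
# interchange standard for pipelines like this one). Cohorts are a
# directory of per-case NIfTI bundles plus a JSON manifest carrying ids,
# lesion types, seeds and true transforms.

#' Read / write a NIfTI volume
#'
#' Round trips preserve data and spacing. `readVolume` returns the array
#' with its mm spacing; grids of volumes belonging to one case must agree.
#'
#' @param path NIfTI-1 file (`.nii` or `.nii.gz`).
#' @param volume 3D array.
#' @param spacing voxel spacing in mm.
#' @return `readVolume`: list with `data` (array, with `"spacing"`
#'   attribute) and `spacing`. `writeVolume`: the path, invisibly.
#' @export
readVolume <- function(path) {
  im <- RNifti::readNifti(path)
  arr <- as.array(im)
  sp <- RNifti::pixdim(im)[seq_len(min(3L, length(dim(arr))))]
  attr(arr, "spacing") <- sp
  list(data = arr, spacing = sp)
}

#' @rdname readVolume
#' @export
writeVolume <- function(volume, path, spacing = attr(volume, "spacing")) {
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  im <- RNifti::asNifti(array(as.numeric(volume), dim(volume)))
  RNifti::pixdim(im) <- spacing
  RNifti::writeNifti(im, path)
  invisible(path)
}

caseFiles <- c(label_map = "label_map.nii.gz", ct = "ct.nii.gz",
               mr_e1 = "mr_e1.nii.gz", mr_e2 = "mr_e2.nii.gz",
               bone_mask = "bone_mask.nii.gz",
               lesion_mask = "lesion_mask.nii.gz",
               ct_bone_mask = "ct_bone_mask.nii.gz")

#' Write / read a phantom case as a NIfTI bundle
#'
#' @param case a [PhantomCase-class].
#' @param dir directory for the bundle (created if needed).
#' @return `writeCase`: the manifest entry (list), invisibly returned by
#'   path; `readCase`: the [PhantomCase-class].
#' @export
writeCase <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vols <- list(label_map = case@labelMap, ct = case@ct,
               mr_e1 = case@mrEcho1, mr_e2 = case@mrEcho2,
               bone_mask = case@boneMask + 0, lesion_mask = case@lesionMask + 0,
               ct_bone_mask = case@ctBoneMask + 0)
  for (nm in names(vols))
    writeVolume(vols[[nm]], file.path(dir, caseFiles[[nm]]), case@spacing)
  entry <- list(caseId = case@caseId, lesionType = case@lesionType,
                seed = case@seed, spacing = case@spacing,
                trueTransform = transformToMatrix(case@trueTransform))
  jsonlite::write_json(entry, file.path(dir, "case.json"), digits = NA,
                       auto_unbox = TRUE, matrix = "rowmajor")
  invisible(entry)
}

#' @rdname writeCase
#' @export
readCase <- function(dir) {
  entry <- jsonlite::read_json(file.path(dir, "case.json"),
                               simplifyVector = TRUE)
  vols <- lapply(caseFiles, function(f) readVolume(file.path(dir, f)))
  sp <- vols$ct$spacing
  for (nm in names(vols))
    if (max(abs(vols[[nm]]$spacing - sp)) > 1e-6)
      stop(sprintf("grid mismatch between '%s' and '%s' in %s",
                   caseFiles[[nm]], caseFiles[["ct"]], dir))
  asMask <- function(v) array(v$data > 0.5, dim(v$data))
  lab <- vols$label_map$data
  storage.mode(lab) <- "integer"
  new("PhantomCase", caseId = entry$caseId, lesionType = entry$lesionType,
      labelMap = array(lab, dim(lab)), ct = stripAttr(vols$ct$data),
      mrEcho1 = stripAttr(vols$mr_e1$data),
      mrEcho2 = stripAttr(vols$mr_e2$data),
      boneMask = asMask(vols$bone_mask),
      lesionMask = asMask(vols$lesion_mask),
      ctBoneMask = asMask(vols$ct_bone_mask),
      spacing = as.numeric(sp),
      trueTransform = matrixToTransform(asMatrix4(entry$trueTransform)),
      seed = as.integer(entry$seed))
}

stripAttr <- function(x) array(as.numeric(x), dim(x))

#' Write / read a cohort directory
#'
#' One subdirectory per case plus `manifest.json` listing ids, lesion
#' types, seeds and true transforms.
#'
#' @param cases list of [PhantomCase-class] objects.
#' @param dir cohort directory.
#' @return `writeCohort`: `dir`, invisibly; `readCohort`: list of cases.
#' @export
writeCohort <- function(cases, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(cases, function(cs)
    writeCase(cs, file.path(dir, cs@caseId)))
  jsonlite::write_json(entries, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  ids <- vapply(manifest, `[[`, character(1), "caseId")
  if (anyDuplicated(ids)) stop("duplicate case ids in manifest")
  lapply(ids, function(id) readCase(file.path(dir, id)))
}

#' Reference per-case cohort metrics
#'
#' The per-case evaluation metrics (MAD, MD, DSC, RMSD; bone and lesion
#' regions; nine patients with pelvic/femoral metastases) from the
#' clinical feasibility cohort this package models, shipped so the
#' summarization and reporting path is testable independently of training.
#'
#' @return data.frame with columns `caseId`, `region`, `lesionType`,
#'   `mad`, `md`, `dsc`, `rmsd`.
#' @export
referenceCohortMetrics <- function() {
  path <- system.file("extdata", "reference_cohort_metrics.csv",
                      package = "boneSCT")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Render a metric report table
#'
#' Per-case rows with a mean +/- sample-SD footer per region, mirroring
#' the standard sCT evaluation table layout (MAD (HU), MD (HU), DSC (1),
#' RMSD (mm)), plus a machine-readable list.
#'
#' @param reports data.frame of per-case metric rows.
#' @param summary optional precomputed [cohortSummary()]; recomputed if
#'   missing.
#' @return Invisibly, list with `text` (character vector of lines) and
#'   `json` (nested list). The text is also printed.
#' @export
report <- function(reports, summary = NULL) {
  if (is.null(reports) || nrow(reports) == 0) stop("no reports to render")
  if (is.null(summary)) summary <- cohortSummary(reports)
  lines <- character(0)
  for (region in unique(reports$region)) {
    sub <- reports[reports$region == region, , drop = FALSE]
    lines <- c(lines, sprintf("Region: %s", region),
               sprintf("%-10s %9s %9s %7s %9s", "case", "MAD (HU)",
                       "MD (HU)", "DSC (1)", "RMSD (mm)"))
    for (r in seq_len(nrow(sub)))
      lines <- c(lines, sprintf("%-10s %9.0f %9.0f %7.2f %9.2f",
                                sub$caseId[r], sub$mad[r], sub$md[r],
                                sub$dsc[r], sub$rmsd[r]))
    ssub <- summary[summary$region == region, , drop = FALSE]
    fmt <- function(metric, digits) {
      row <- ssub[ssub$metric == metric, ]
      sprintf(paste0("%.", digits, "f ± %.", digits, "f"),
              row$mean, row$sd)
    }
    lines <- c(lines, sprintf("%-10s %9s %9s %7s %9s", "mean ± SD",
                              fmt("mad", 0), fmt("md", 0), fmt("dsc", 2),
                              fmt("rmsd", 2)), "")
  }
  cat(lines, sep = "\n")
  json <- list(summary = split(summary, summary$region),
               cases = reports)
  invisible(list(text = lines, json = json))
}
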