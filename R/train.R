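# Training (L1 loss, Adam), full-volume inference by overlapping patch
# tiling, and the leave-one-out cross-validation harness.

#' Training configuration
#'
#' The loss is fixed to the mean absolute error on normalized intensities
#' and the optimizer to Adam; the learning rate defaults to 1e-4.
#' `epochs`, `batchSize` and `patchesPerVolume` set the desk-scale budget.
#' Patches are drawn 80% bone-intersecting / 20% anywhere by default, since
#' evaluation is restricted to bone.
#'
#' @param learningRate Adam learning rate (> 0 to make progress; 0 is
#'   allowed and leaves weights untouched).
#' @param epochs training epochs (no early stopping; the best-validation
#'   checkpoint is returned).
#' @param batchSize patches per optimizer step.
#' @param patchesPerVolume patches sampled per training volume per epoch.
#' @param boneFraction minimum fraction of bone-intersecting patches.
#' @param augment apply whole-volume flip/rotation augmentation per volume
#'   per epoch?
#' @param seed one seed for everything random in the run (sampling,
#'   augmentation; weight init is seeded in [buildNetwork()]).
#' @return Named list of class `"trainConfig"`.
#' @export
trainConfig <- function(learningRate = 1e-4, epochs = 10L, batchSize = 4L,
                        patchesPerVolume = 32L, boneFraction = 0.8,
                        augment = TRUE, seed = 1L) {
  stopifnot(learningRate >= 0, epochs >= 1, batchSize >= 1,
            patchesPerVolume >= 1, boneFraction >= 0, boneFraction <= 1)
  structure(list(learningRate = learningRate, epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 patchesPerVolume = as.integer(patchesPerVolume),
                 boneFraction = boneFraction, augment = isTRUE(augment),
                 seed = as.integer(seed)),
            class = "trainConfig")
}

#' Normalize the volumes of a case for training/inference
#'
#' @param case a [PhantomCase-class].
#' @param percentile MR clip percentile.
#' @return List of normalized MR echoes, normalized CT, bone mask and
#'   spacing.
#' @export
prepareCase <- function(case, percentile = 95) {
  list(mr1 = normalizeMR(case@mrEcho1, percentile, case@spacing),
       mr2 = normalizeMR(case@mrEcho2, percentile, case@spacing),
       ct = normalizeCT(case@ct, case@spacing),
       boneMask = case@boneMask, spacing = case@spacing)
}

# Augment the raw volumes of a case (images linear, mask nearest; CT
# background -1024 HU, MR 0), then normalize. Augmenting before
# normalization keeps the background at the physical zero of each modality.
augmentedPrep <- function(case, params, percentile = 95) {
  d <- dim(case@ct)
  vols <- augmentVolumes(
    list(mr1 = case@mrEcho1, mr2 = case@mrEcho2,
         ct = case@ct - .CT_HU_MIN,  # shift so out-of-field = 0 maps to air
         bone = case@boneMask + 0),
    params, case@spacing, isMask = c(FALSE, FALSE, FALSE, TRUE))
  list(mr1 = normalizeMR(array(pmax(vols$mr1, 0), d), percentile,
                         case@spacing),
       mr2 = normalizeMR(array(pmax(vols$mr2, 0), d), percentile,
                         case@spacing),
       ct = normalizeCT(vols$ct + .CT_HU_MIN, case@spacing),
       boneMask = array(vols$bone > 0.5, d), spacing = case@spacing)
}

patchLoss <- function(weights, cfg, patch) {
  fw <- netForward(weights, cfg, patch$mr)
  mean(abs(fw$out - patch$ct))
}

#' Train an MR-to-CT translation network
#'
#' Per epoch: every training case is (optionally) augmented as a whole
#' volume, patches are sampled, and Adam minimizes the mean absolute error
#' between predicted and true normalized CT over shuffled mini-batches.
#' The validation case supplies a fixed patch set scored after each epoch;
#' the checkpoint with the best validation loss is returned. Fully seeded.
#'
#' @param model a [TrainedModel-class] from [buildNetwork()] (weights are
#'   the starting point).
#' @param trainingCases nonempty list of [PhantomCase-class] objects.
#' @param validationCase a [PhantomCase-class].
#' @param tc a [trainConfig()].
#' @return A [TrainedModel-class] with training history.
#' @export
train <- function(model, trainingCases, validationCase,
                  tc = trainConfig()) {
  stopifnot(is(model, "TrainedModel"), inherits(tc, "trainConfig"))
  if (length(trainingCases) == 0) stop("empty training set")
  cfg <- model@netConfig
  pct <- model@normMeta$mrPercentile
  size <- cfg$patchSize

  valPrep <- prepareCase(validationCase, pct)
  valSeed <- deriveSeeds(tc$seed, 1)
  valPatches <- extractPatches(valPrep$mr1, valPrep$mr2, valPrep$ct,
                               valPrep$boneMask, size,
                               nPatches = tc$patchesPerVolume,
                               boneFractionMin = tc$boneFraction,
                               seed = valSeed)

  weights <- model@weights
  state <- NULL
  bestW <- weights
  bestVal <- Inf
  hist <- vector("list", tc$epochs)
  nSeedsPerEpoch <- 3L * length(trainingCases) + 1L
  allSeeds <- deriveSeeds(tc$seed + 1L, tc$epochs * nSeedsPerEpoch)

  for (epoch in seq_len(tc$epochs)) {
    seeds <- allSeeds[(epoch - 1) * nSeedsPerEpoch + seq_len(nSeedsPerEpoch)]
    patches <- list()
    for (i in seq_along(trainingCases)) {
      case <- trainingCases[[i]]
      prep <- if (tc$augment)
        augmentedPrep(case, randomAugmentation(seeds[3 * i - 2]), pct)
      else prepareCase(case, pct)
      patches <- c(patches,
                   extractPatches(prep$mr1, prep$mr2, prep$ct, prep$boneMask,
                                  size, nPatches = tc$patchesPerVolume,
                                  boneFractionMin = tc$boneFraction,
                                  seed = seeds[3 * i - 1]))
    }
    patches <- withSeed(seeds[nSeedsPerEpoch],
                        patches[sample.int(length(patches))])
    batchLosses <- numeric(0)
    b0 <- 1
    while (b0 <= length(patches)) {
      batch <- patches[b0:min(b0 + tc$batchSize - 1, length(patches))]
      b0 <- b0 + tc$batchSize
      gSum <- NULL
      lossSum <- 0
      for (patch in batch) {
        fw <- netForward(weights, cfg, patch$mr, cache = TRUE)
        diff <- fw$out - patch$ct
        lossSum <- lossSum + mean(abs(diff))
        gOut <- sign(diff) / length(diff)
        g <- flattenParams(gradAsWeights(netBackward(weights, cfg,
                                                     fw$cache, gOut)))
        gSum <- if (is.null(gSum)) g
        else Map(`+`, gSum, g)
      }
      loss <- lossSum / length(batch)
      if (!is.finite(loss))
        stop(sprintf("non-finite training loss at epoch %d (diverged?)",
                     epoch))
      batchLosses <- c(batchLosses, loss)
      gMean <- lapply(gSum, `/`, length(batch))
      flatW <- flattenParams(weights)
      upd <- adamStep(flatW, gMean, state, tc$learningRate)
      state <- upd$state
      weights <- assignFlat(weights, upd$w)
    }
    valLoss <- mean(vapply(valPatches, function(p)
      patchLoss(weights, cfg, p), numeric(1)))
    hist[[epoch]] <- data.frame(epoch = epoch,
                                trainLoss = mean(batchLosses),
                                validationLoss = valLoss)
    if (valLoss < bestVal) {
      bestVal <- valLoss
      bestW <- weights
    }
  }
  new("TrainedModel", weights = bestW, netConfig = cfg,
      trainConfig = unclass(tc), normMeta = model@normMeta,
      history = do.call(rbind, hist))
}

#' Predict a full sCT volume in HU
#'
#' Normalizes the two MR echoes with the model's convention, tiles the
#' volume into patches with stride patchSize/2 (final origins clamped to
#' the volume edge), averages overlapping predictions with uniform
#' weights -- which preserves constants exactly -- and denormalizes to HU,
#' clipped to the CT range.
#'
#' @param model a [TrainedModel-class].
#' @param mrEcho1,mrEcho2 raw MR magnitude volumes.
#' @return sCT volume in HU within `[-1024, 3071]`.
#' @export
predictVolume <- function(model, mrEcho1, mrEcho2) {
  cfg <- model@netConfig
  size <- cfg$patchSize
  d <- dim(mrEcho1)
  if (any(d < size))
    stop(sprintf("volume %s smaller than one %d^3 patch",
                 paste(d, collapse = "x"), size))
  pct <- model@normMeta$mrPercentile
  m1 <- normalizeMR(mrEcho1, pct)@values
  m2 <- normalizeMR(mrEcho2, pct)@values
  stride <- max(1L, size %/% 2L)
  starts <- lapply(d, function(n)
    unique(c(seq(1L, n - size + 1L, by = stride), n - size + 1L)))
  acc <- array(0, d)
  cnt <- array(0, d)
  for (k in starts[[3]]) for (j in starts[[2]]) for (i in starts[[1]]) {
    ix <- i:(i + size - 1L); jx <- j:(j + size - 1L); kx <- k:(k + size - 1L)
    x <- array(c(m1[ix, jx, kx], m2[ix, jx, kx]), c(size, size, size, 2L))
    pred <- netForward(model@weights, cfg, x)$out
    acc[ix, jx, kx] <- acc[ix, jx, kx] + pred
    cnt[ix, jx, kx] <- cnt[ix, jx, kx] + 1
  }
  hu <- denormalizeCT(acc / cnt)
  array(pmin(pmax(hu, .CT_HU_MIN), .CT_HU_MAX), d)
}

#' Leave-one-out cross-validation over a cohort
#'
#' Fold i: case i is the held-out test set, case (i mod n) + 1 the
#' validation set, the remaining n - 2 cases the training set -- so every
#' case is tested exactly once and never appears in its own fold's
#' training or validation data (asserted structurally). Each fold trains
#' from a fresh seeded initialization, predicts the held-out case and
#' evaluates it.
#'
#' @param cohort list of >= 3 [PhantomCase-class] objects.
#' @param netCfg a [networkConfig()].
#' @param tc a [trainConfig()]; per-fold seeds derive from `tc$seed`.
#' @param evalCfg an [evalConfig()].
#' @param keepModels retain the fold models (memory!)?
#' @param baseline also score each fold's *untrained* model (its seeded
#'   initialization) on the held-out case? Stored per fold as
#'   `baselineBoneDSC`, a learning-sanity reference.
#' @param verbose print one line per fold?
#' @return List: `reports` (18-row data.frame for n = 9: per case x
#'   bone/lesion), `summary` ([cohortSummary()]), `folds` (per-fold ids,
#'   history, optional model and baseline).
#' @export
loocv <- function(cohort, netCfg = networkConfig(), tc = trainConfig(),
                  evalCfg = evalConfig(), keepModels = FALSE,
                  baseline = FALSE, verbose = FALSE) {
  n <- length(cohort)
  stopifnot(n >= 3)
  foldSeeds <- deriveSeeds(tc$seed, 2L * n)
  folds <- vector("list", n)
  reports <- vector("list", n)
  for (i in seq_len(n)) {
    vi <- (i %% n) + 1L
    ti <- setdiff(seq_len(n), c(i, vi))
    stopifnot(!(i %in% ti), vi != i)  # no leakage, structurally
    model0 <- buildNetwork(netCfg, seed = foldSeeds[2 * i - 1])
    tcFold <- tc
    tcFold$seed <- foldSeeds[2 * i]
    test <- cohort[[i]]
    baseDSC <- NA_real_
    if (baseline) {
      sct0 <- predictVolume(model0, test@mrEcho1, test@mrEcho2)
      baseDSC <- dice(extractBone(sct0, test@boneMask,
                                  evalCfg$boneThresholdHU),
                      extractBone(test@ct, test@boneMask,
                                  evalCfg$boneThresholdHU))
    }
    tm <- train(model0, cohort[ti], cohort[[vi]], tcFold)
    sct <- predictVolume(tm, test@mrEcho1, test@mrEcho2)
    rep <- evaluateCase(sct, test@ct, test@boneMask, test@lesionMask,
                        test@spacing, evalCfg, caseId = test@caseId)
    rep$lesionType <- test@lesionType
    reports[[i]] <- rep
    folds[[i]] <- list(testId = test@caseId, validationId = caseId(cohort[[vi]]),
                       trainingIds = vapply(cohort[ti], caseId, character(1)),
                       history = tm@history, baselineBoneDSC = baseDSC,
                       model = if (keepModels) tm else NULL)
    if (verbose)
      message(sprintf("fold %d/%d: test %s, bone MAD %.1f HU, DSC %.3f",
                      i, n, test@caseId, rep$mad[rep$region == "bone"],
                      rep$dsc[rep$region == "bone"]))
  }
  reports <- do.call(rbind, reports)
  list(reports = reports, summary = cohortSummary(reports), folds = folds)
}

#' Save / load a trained model
#'
#' The whole model object (weights, configs, normalization metadata,
#' history) is serialized; reloading reproduces predictions bit for bit.
#'
#' @param model a [TrainedModel-class].
#' @param path file path (`.rds`).
#' @return `loadModel` returns the [TrainedModel-class]; `saveModel` the
#'   path, invisibly.
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  model <- readRDS(path)
  stopifnot(is(model, "TrainedModel"))
  model
}
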