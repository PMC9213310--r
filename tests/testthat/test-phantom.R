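# Phantom generator: geometry, rendering physics, determinism, cohort
# composition.

test_that("lesion-free label map has a closed cortical shell", {
  spec <- phantomSpec(shape = c(48, 48, 32), seed = 3)
  lab <- buildLabelMap(spec)
  interior <- lab == 3L | lab == 4L  # marrow | cancellous
  boneAll <- interior | lab == 5L
  d <- dim(lab)
  shift <- function(m, ax, by) {
    idx <- pmin(pmax(seq_len(d[ax]) + by, 1L), d[ax])
    switch(ax, m[idx, , ], m[, idx, ], m[, , idx])
  }
  # every 6-neighbour of an interior-bone voxel is bone: no leak through
  # the shell
  for (ax in 1:3) for (by in c(-1, 1)) {
    nb <- shift(boneAll, ax, by)
    expect_true(all(nb[interior]))
  }
})

test_that("label map and renderings are deterministic per seed", {
  les <- lesionSpec("osteolytic", c(24, 24, 16), 6)
  spec <- phantomSpec(shape = c(48, 48, 32), lesions = list(les), seed = 9)
  expect_identical(buildLabelMap(spec), buildLabelMap(spec))
  lab <- buildLabelMap(spec)
  expect_identical(renderCT(lab, spec), renderCT(lab, spec))
  mr1 <- renderMR(lab, spec); mr2 <- renderMR(lab, spec)
  expect_identical(mr1, mr2)
  # toggling CT noise must not change geometry (independent streams)
  specNoNoise <- phantomSpec(shape = c(48, 48, 32), lesions = list(les),
                             ctNoise = FALSE, seed = 9)
  expect_identical(buildLabelMap(specNoNoise), lab)
})

test_that("cortical breach removes shell voxels", {
  base <- phantomSpec(shape = c(48, 48, 32), boneOuterRadiusMm = 12,
                      seed = 5)
  nCortFree <- sum(buildLabelMap(base) == 5L)
  les <- lesionSpec("osteolytic", c(24, 32, 16), 7, corticalBreach = TRUE)
  spec <- phantomSpec(shape = c(48, 48, 32), boneOuterRadiusMm = 12,
                      lesions = list(les), seed = 5)
  nCortBreached <- sum(buildLabelMap(spec) == 5L)
  expect_lt(nCortBreached, nCortFree)
  # without breach, an interior lesion leaves the shell untouched
  les2 <- lesionSpec("osteolytic", c(24, 24, 16), 4)
  spec2 <- phantomSpec(shape = c(48, 48, 32), boneOuterRadiusMm = 12,
                       lesions = list(les2), seed = 5)
  expect_equal(sum(buildLabelMap(spec2) == 5L), nCortFree)
})

test_that("a lesion outside the bone is rejected by index", {
  les <- lesionSpec("osteoblastic", c(3, 3, 16), 3)
  spec <- phantomSpec(shape = c(48, 48, 32), lesions = list(les), seed = 2)
  expect_error(buildLabelMap(spec), "lesion 1")
})

test_that("noiseless CT rendering is an exact per-label lookup", {
  les <- lesionSpec("osteoblastic", c(24, 24, 16), 6, huDelta = 400)
  spec <- phantomSpec(shape = c(48, 48, 32), lesions = list(les),
                      ctNoise = FALSE, ctBlurSigmaMm = 0,
                      trabecularTexture = 0, seed = 4)
  lab <- buildLabelMap(spec)
  ct <- renderCT(lab, spec)
  huTab <- vapply(spec$tissueTable, `[[`, numeric(1), "huMean")
  labels <- c(water = 0, fat = 1, muscle = 2, marrow = 3, cancellous = 4,
              cortical = 5, lesion_lytic = 6, lesion_blastic = 7)
  for (nm in names(labels)) {
    sel <- lab == labels[[nm]]
    if (any(sel)) expect_equal(max(abs(ct[sel] - huTab[[nm]])), 0)
  }
  # blastic lesion: +400 on a 300 HU cancellous base -> 700 exactly here
  expect_equal(unique(ct[lab == 7L]), 700)
})

test_that("rendered CT straddles the 150-HU threshold and hits the lesion mean", {
  case <- tinyCase("osteoblastic", seed = 31)
  ct <- ctVolume(case); lab <- labelMap(case)
  expect_gt(mean(ct[lab == 5L]), 800)   # cortical far above 150
  expect_lt(mean(ct[lab == 2L]), 150)   # muscle below
  expect_lt(mean(ct[lab == 3L]), 150)   # marrow below
  # noisy, unblurred lesion-region mean: 300 + 400 within noise tolerance
  les <- lesionSpec("osteoblastic", c(24, 24, 16), 6, huDelta = 400)
  spec <- phantomSpec(shape = c(48, 48, 32), lesions = list(les),
                      ctBlurSigmaMm = 0, seed = 8)
  lab2 <- buildLabelMap(spec)
  ct2 <- renderCT(lab2, spec)
  n <- sum(lab2 == 7L)
  expect_gt(n, 100)
  expect_equal(mean(ct2[lab2 == 7L]), 700, tolerance = 5 * 50 / sqrt(n))
})

test_that("spoiled gradient-echo signal matches the closed form", {
  # independent scalar evaluation of the steady-state expression
  pd <- 0.8; t1 <- 900; t2s <- 35; te <- 2.1; tr <- 7; a <- 10 * pi / 180
  e1 <- exp(-tr / t1)
  expected <- pd * sin(a) * (1 - e1) / (1 - cos(a) * e1) * exp(-te / t2s)
  expect_equal(sgreSignal(pd, t1, t2s, 0, te, tr, 10), expected)
  expect_equal(sgreSignal(0, t1, t2s, 0.3, te, tr, 10), 0)  # PD 0 -> 0

  # fat-water phasor at ff = 0.5 and 220 Hz: TE 2.1 ms is near opposed
  # phase (~166 deg), TE 4.2 ms near in phase
  s1 <- sgreSignal(1, 300, 60, 0.5, 2.1, 7, 10, 220)
  s2 <- sgreSignal(1, 300, 60, 0.5, 4.2, 7, 10, 220)
  expect_lt(s1, s2)
  phasor <- function(te) Mod(0.5 + 0.5 * exp(1i * 2 * pi * 220 * te / 1000))
  expect_equal(sgreSignal(1, 300, 60, 0.5, 2.1, 7, 10, 220) /
                 sgreSignal(1, 300, 60, 0, 2.1, 7, 10, 220), phasor(2.1))
  # signal is monotonically decreasing in TE for water-only voxels
  tes <- seq(0.5, 6.5, by = 0.5)
  sig <- sgreSignal(1, 1000, 40, 0, tes, 7, 10)
  expect_true(all(diff(sig) < 0))
  expect_error(sgreSignal(1, 1000, 40, 0, 8, 7, 10), "TR")
  expect_error(acquisitionParams(te1 = 5, te2 = 4), "te1 < te2")
})

test_that("rendered MR echoes obey the opposed/in-phase ordering", {
  case <- tinyCase("osteolytic", seed = 13, noiseless = TRUE)
  mr <- mrVolumes(case)
  lab <- labelMap(case)
  # marrow (fat fraction 0.8) and fat (0.9): echo 1 below echo 2
  for (l in c(1L, 3L)) {
    expect_lt(mean(mr$echo1[lab == l]), mean(mr$echo2[lab == l]))
  }
  # water background (fat fraction 0): pure T2* decay, echo 1 above echo 2
  expect_gt(mean(mr$echo1[lab == 0L]), mean(mr$echo2[lab == 0L]))
})

test_that("ground-truth masks are consistent with the label map", {
  case <- tinyCase("mixed", seed = 17)
  lab <- labelMap(case)
  expect_identical(boneMask(case),
                   array(lab %in% c(4L, 5L, 6L, 7L), dim(lab)))
  expect_identical(lesionMask(case), array(lab %in% c(6L, 7L), dim(lab)))
  expect_true(all(boneMask(case)[lesionMask(case)]))
  expect_true(any(boneMask(case)))
})

test_that("cohort generation reproduces the study composition and seeds", {
  cohort <- makeCohort(9, phantomSpec(shape = c(48, 48, 32)), seed = 1)
  types <- vapply(cohort, lesionType, character(1))
  counts <- table(types)[c("osteolytic", "osteoblastic", "mixed")]
  expect_equal(unname(counts), c(3L, 4L, 2L), ignore_attr = TRUE)

  again <- makeCohort(9, phantomSpec(shape = c(48, 48, 32)), seed = 1)
  expect_identical(labelMap(cohort[[4]]), labelMap(again[[4]]))
  expect_identical(ctVolume(cohort[[7]]), ctVolume(again[[7]]))
  other <- makeCohort(9, phantomSpec(shape = c(48, 48, 32)), seed = 2)
  expect_false(identical(labelMap(cohort[[1]]), labelMap(other[[1]])))

  two <- makeCohort(2, phantomSpec(shape = c(48, 48, 32)), seed = 5)
  expect_length(two, 2)
  expect_true(all(vapply(two, lesionType, character(1)) %in%
                    c("osteolytic", "osteoblastic", "mixed")))
  expect_error(makeCohort(1, phantomSpec()), "n >= 2")
})

test_that("misalignment resamples the CT frame and records the truth", {
  case <- tinyCase("osteoblastic", seed = 23, noiseless = TRUE)
  idt <- rigidTransform()
  same <- applyMisalignment(case, idt, interpolation = "nearest")
  expect_equal(same@ct, ctVolume(case), ignore_attr = TRUE)
  expect_identical(same@ctBoneMask, case@ctBoneMask)

  # one-voxel integer translation, nearest neighbour: count conserved
  shift <- rigidTransform(translation = c(voxelSpacing(case)[1], 0, 0))
  moved <- applyMisalignment(case, shift, interpolation = "nearest")
  expect_equal(sum(moved@ctBoneMask), sum(case@ctBoneMask))
  expect_identical(trueTransform(moved), shift)
  # the moved CT is the original shifted by one index along x
  expect_equal(moved@ct[1:40, , ], ctVolume(case)[2:41, , ],
               ignore_attr = TRUE)
})
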