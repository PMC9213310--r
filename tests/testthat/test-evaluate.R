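# Metric suite: hand-arithmetic cases, brute-force oracles, and the cohort
# summarization that reproduces the reference table statistics.

test_that("MAD and MD match hand arithmetic and their inequality", {
  ct <- array(0, c(2, 1, 1))
  sct <- array(c(30, -10), c(2, 1, 1))
  mask <- array(TRUE, c(2, 1, 1))
  expect_equal(madHU(sct, ct, mask), 20)
  expect_equal(mdHU(sct, ct, mask), 10)
  expect_equal(madHU(ct, ct, mask), 0)
  expect_equal(mdHU(ct, ct, mask), 0)
  expect_equal(madHU(ct + 50, ct, mask), 50)

  set.seed(4)
  for (i in 1:20) {
    a <- array(rnorm(60, sd = 100), c(5, 4, 3))
    b <- array(rnorm(60, sd = 100), c(5, 4, 3))
    m <- randomMask(c(5, 4, 3), 0.5)
    expect_lte(abs(mdHU(a, b, m)), madHU(a, b, m))
  }
  expect_error(madHU(ct, ct, array(FALSE, c(2, 1, 1))), "empty")
  expect_error(mdHU(ct, ct, array(FALSE, c(2, 1, 1))), "empty")
})

test_that("bone extraction thresholds inclusively within the mask", {
  air <- array(-1000, c(4, 4, 4))
  mask <- array(TRUE, c(4, 4, 4))
  expect_false(any(extractBone(air, mask)))
  expect_false(any(extractBone(air, mask, threshold = Inf)))
  v <- array(c(149.9, 150, 150.1, 0), c(4, 1, 1))
  got <- extractBone(v, array(TRUE, c(4, 1, 1)))
  expect_identical(as.logical(got), c(FALSE, TRUE, TRUE, FALSE))
  # restriction to the mask
  expect_false(any(extractBone(array(1000, c(4, 4, 4)),
                               array(FALSE, c(4, 4, 4)))))
})

test_that("Dice handles identity, disjoint, partial overlap and emptiness", {
  a <- array(FALSE, c(4, 4, 4)); a[1:2, 1:2, 1:2] <- TRUE      # 8 voxels
  b <- array(FALSE, c(4, 4, 4)); b[2:3, 1:2, 1:2] <- TRUE      # 8, overlap 4
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, b), 0.5)
  expect_equal(dice(a, b), dice(b, a))
  disj <- array(FALSE, c(4, 4, 4)); disj[4, 4, 4] <- TRUE
  expect_equal(dice(a, disj), 0)
  empty <- array(FALSE, c(4, 4, 4))
  expect_warning(d0 <- dice(empty, empty), "absence")
  expect_equal(d0, 1)
  expect_error(dice(a, array(FALSE, c(3, 3, 3))), "mismatch")
})

test_that("surface RMSD: exact cases and parallel plates", {
  a <- array(FALSE, c(8, 8, 8)); a[3:6, 3:6, 3:6] <- TRUE
  expect_equal(surfaceRMSD(a, a, c(1, 1, 1)), 0)
  # plates 3 mm apart along x (1 mm spacing, 1-voxel-thick)
  p1 <- array(FALSE, c(8, 6, 6)); p1[2, , ] <- TRUE
  p2 <- array(FALSE, c(8, 6, 6)); p2[5, , ] <- TRUE
  expect_equal(surfaceRMSD(p1, p2, c(1, 1, 1)), 3)
  # anisotropic spacing: same plates along z with 2 mm slices -> 6 mm
  q1 <- array(FALSE, c(6, 6, 8)); q1[, , 2] <- TRUE
  q2 <- array(FALSE, c(6, 6, 8)); q2[, , 5] <- TRUE
  expect_equal(surfaceRMSD(q1, q2, c(1, 1, 2)), 6)
  expect_error(surfaceRMSD(array(FALSE, c(8, 8, 8)), a), "empty")
  expect_error(surfaceRMSD(array(FALSE, c(2, 2, 2)), a), "mismatch")
})

test_that("surface RMSD equals the brute-force all-pairs oracle", {
  set.seed(11)
  for (i in 1:40) {
    dims <- sample(3:10, 3, replace = TRUE)
    sp <- sample(c(1, 1, 2, 0.5), 3, replace = TRUE)
    a <- randomMask(dims, 0.25)
    b <- randomMask(dims, 0.25)
    expect_equal(surfaceRMSD(a, b, sp), bfSurfaceRMSD(a, b, sp),
                 tolerance = 1e-9)
    if (i <= 10) {
      na <- nrow(bfBoundary(a)); nb <- nrow(bfBoundary(b))
      pooled <- sqrt((na * bfSurfaceRMSD(a, b, sp)^2 +
                        nb * bfSurfaceRMSD(b, a, sp)^2) / (na + nb))
      expect_equal(surfaceRMSD(a, b, sp, symmetric = TRUE), pooled,
                   tolerance = 1e-9)
    }
  }
})

test_that("mask dilation honors physical spacing and matches enumeration", {
  m <- array(FALSE, c(13, 13, 13)); m[7, 7, 7] <- TRUE
  expect_identical(dilateMask(m, 0, c(1, 1, 1)), m)
  ball <- dilateMask(m, 5, c(1, 1, 1))
  expect_identical(ball, bfDilate(m, 5, c(1, 1, 1)))
  # anisotropic: extent in voxels along a 2 mm axis is half the 1 mm axes
  ball2 <- dilateMask(m, 5, c(1, 1, 2))
  expect_identical(ball2, bfDilate(m, 5, c(1, 1, 2)))
  expect_equal(sum(ball2[7, 7, ] != 0), 5)   # z: +/- 2 slices
  expect_equal(sum(ball2[, 7, 7] != 0), 11)  # x: +/- 5 voxels
  # monotone in the margin, on random masks
  set.seed(12)
  for (i in 1:10) {
    mm <- randomMask(c(7, 7, 7), 0.1)
    sp <- c(1, 1, 2)
    d1 <- dilateMask(mm, 2, sp); d2 <- dilateMask(mm, 4, sp)
    expect_true(all(d2[d1]))
    expect_identical(d1, bfDilate(mm, 2, sp))
  }
})

test_that("case evaluation: identity and constant-shift phantoms", {
  case <- tinyCase("osteolytic", seed = 21, noiseless = TRUE)
  ct <- ctVolume(case)
  # the fully lytic lesion has no >=150 HU tissue on either side, so the
  # lesion region triggers the documented agreement-on-absence warning
  rep0 <- suppressWarnings(
    evaluateCase(ct, ct, boneMask(case), lesionMask(case),
                 voxelSpacing(case), caseId = "self"))
  bone <- rep0[rep0$region == "bone", ]
  expect_equal(bone$mad, 0)
  expect_equal(bone$md, 0)
  expect_equal(bone$dsc, 1)
  expect_equal(bone$rmsd, 0)

  # +200 HU does not move any noiseless tissue across 150 HU inside bone
  rep1 <- suppressWarnings(
    evaluateCase(ct + 200, ct, boneMask(case), lesionMask(case),
                 voxelSpacing(case)))
  b1 <- rep1[rep1$region == "bone", ]
  expect_equal(b1$mad, 200)
  expect_equal(b1$md, 200)
  expect_equal(b1$dsc, 1)
  # +300 HU lifts the lytic tissue (-100 HU) above threshold: DSC drops by
  # exactly the lesion voxels added to the sCT extraction
  rep2 <- evaluateCase(ct + 300, ct, boneMask(case), lesionMask(case),
                       voxelSpacing(case))
  b2 <- rep2[rep2$region == "bone", ]
  truth <- extractBone(ct, boneMask(case))
  lift <- extractBone(ct + 300, boneMask(case))
  expect_lt(b2$dsc, 1)
  expect_equal(b2$dsc, 2 * sum(truth & lift) / (sum(truth) + sum(lift)))
})

test_that("cohort summarization reproduces the reference statistics", {
  ref <- referenceCohortMetrics()
  cs <- cohortSummary(ref)
  g <- function(region, metric, col)
    cs[cs$region == region & cs$metric == metric, col]
  expect_equal(g("bone", "mad", "mean"), 116.333, tolerance = 1e-3)
  expect_equal(round(g("bone", "mad", "mean")), 116)
  expect_equal(round(g("bone", "mad", "sd")), 26)    # sample (n-1) divisor
  # population divisor would round to 25 -- the printed 26 pins n-1
  madv <- ref$mad[ref$region == "bone"]
  expect_equal(round(sqrt(mean((madv - mean(madv))^2))), 25)
  expect_equal(g("bone", "dsc", "mean"), 0.8533, tolerance = 1e-3)
  expect_equal(g("bone", "rmsd", "mean"), 2.05, tolerance = 1e-9)
  expect_equal(g("lesion", "mad", "mean"), 132.333, tolerance = 1e-3)
  expect_equal(g("lesion", "md", "mean"), -31.111, tolerance = 1e-3)
  expect_equal(g("lesion", "dsc", "mean"), 0.7544, tolerance = 1e-3)
  expect_true(all(cs$n == 9))

  # degenerate summaries
  one <- ref[1, ]
  cs1 <- cohortSummary(one)
  expect_true(all(is.na(cs1$sd)))
  same <- ref[c(1, 1, 1), ]
  expect_true(all(cohortSummary(same)$sd == 0))
})
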