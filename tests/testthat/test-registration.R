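# Surface extraction, ICP rigid recovery, resampling.

test_that("mask surfaces are boundary voxel centers in mm", {
  cube <- array(FALSE, c(5, 5, 5))
  cube[2:4, 2:4, 2:4] <- TRUE
  pts <- maskToSurface(cube, c(1, 1, 1))
  expect_equal(nrow(pts), 26)  # all but the center voxel
  single <- array(FALSE, c(3, 3, 3)); single[2, 2, 2] <- TRUE
  expect_equal(nrow(maskToSurface(single, c(1, 1, 1))), 1)
  # anisotropic spacing scales coordinates per axis
  p1 <- maskToSurface(single, c(1, 1, 1))
  p2 <- maskToSurface(single, c(1, 1, 2))
  expect_equal(p2[1, ], p1[1, ] * c(1, 1, 2))
  expect_error(maskToSurface(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("rigid transform algebra composes, inverts and serializes", {
  t1 <- randomRigidTransform(25, 15, seed = 1)
  t2 <- randomRigidTransform(25, 15, seed = 2)
  p <- matrix(rnorm(30, sd = 20), 10, 3)
  expect_equal(applyTransform(composeTransform(t1, t2), p),
               applyTransform(t1, applyTransform(t2, p)))
  idt <- composeTransform(t1, invertTransform(t1))
  expect_lt(rotationAngle(idt), 1e-10)
  expect_lt(translationMagnitude(idt), 1e-10)
  tmp <- tempfile(fileext = ".json")
  writeTransform(t1, tmp)
  t1b <- readTransform(tmp)
  expect_equal(t1@rotation, t1b@rotation, tolerance = 1e-12)
  expect_equal(t1@translation, t1b@translation, tolerance = 1e-12)
  # reflections are rejected
  expect_error(rigidTransform(diag(c(-1, 1, 1))), "determinant")
})

test_that("ICP is exact on identical clouds and rejects degenerate input", {
  set.seed(8)
  cloud <- matrix(rnorm(300, sd = 30), 100, 3)
  res <- icpRigid(cloud, cloud)
  expect_lt(res$rms, 1e-10)
  expect_lt(rotationAngle(res$transform), 1e-6)
  expect_true(res$converged)
  line <- cbind(seq_len(10), seq_len(10) * 2, seq_len(10) * -1)
  expect_error(icpRigid(line, cloud), "collinear")
  expect_error(icpRigid(cloud[1:2, ], cloud), "3 points")
})

test_that("ICP recovers rigid misalignments of phantom bone surfaces", {
  case <- tinyCase("osteoblastic", seed = 51, noiseless = TRUE)
  fixed <- maskToSurface(boneMask(case), voxelSpacing(case))
  for (s in 1:3) {
    truth <- randomRigidTransform(30, 20, seed = s)
    moving <- applyTransform(invertTransform(truth), fixed)
    res <- icpRigid(moving, fixed, maxPoints = 1500)
    resid <- composeTransform(res$transform, invertTransform(truth))
    expect_lt(rotationAngle(resid), 0.1)
    expect_lt(translationMagnitude(resid), 0.1)
    # logged RMS sequence is non-increasing
    expect_true(all(diff(res$rmsLog) <= 1e-9))
  }
})

test_that("registration residual: closed forms and the optimization contract", {
  plate1 <- cbind(0, rep(seq_len(10), 10), rep(seq_len(10), each = 10))
  plate2 <- plate1; plate2[, 1] <- 3
  idt <- rigidTransform()
  expect_equal(registrationResidual(idt, plate1, plate1), 0)
  expect_equal(registrationResidual(idt, plate1, plate2), 3)
  case <- tinyCase("osteolytic", seed = 52, noiseless = TRUE)
  fixed <- maskToSurface(boneMask(case), voxelSpacing(case))
  truth <- randomRigidTransform(20, 10, seed = 9)
  moving <- applyTransform(invertTransform(truth), fixed)
  pre <- registrationResidual(idt, moving, fixed)
  res <- icpRigid(moving, fixed, maxPoints = 1500)
  expect_lt(registrationResidual(res$transform, moving, fixed), pre)
})

test_that("resampling: identity, integer shifts, rotation inversion", {
  blob <- gaussBlob(24, sigma = 4)
  idt <- rigidTransform()
  expect_equal(resampleVolume(blob, idt, c(1, 1, 1)), blob,
               tolerance = 1e-8, ignore_attr = TRUE)
  # integer-voxel translation with nearest neighbour is a pure index shift
  mask <- array(0, c(16, 16, 16)); mask[6:10, 6:10, 6:10] <- 1
  tr <- rigidTransform(translation = c(2, 0, 0))
  shifted <- resampleVolume(mask, tr, c(1, 1, 1), interpolation = "nearest")
  expect_equal(sum(shifted), sum(mask))
  expect_equal(shifted[8:12, 6:10, 6:10], mask[6:10, 6:10, 6:10],
               ignore_attr = TRUE)
  # rotation then inverse rotation on a smooth blob (cubic B-spline)
  ctr <- rigidTransform(translation = (dim(blob) - 1) / 2)
  rot <- function(a) composeTransform(ctr,
    composeTransform(axisRotation(a, 3), invertTransform(ctr)))
  there <- resampleVolume(blob, rot(25), c(1, 1, 1))
  back <- resampleVolume(there, rot(-25), c(1, 1, 1))
  inner <- 7:18
  expect_lt(max(abs(back[inner, inner, inner] -
                      blob[inner, inner, inner])), 0.01)
})

test_that("case registration realigns a misaligned CT", {
  case <- tinyCase("osteoblastic", seed = 53, noiseless = TRUE)
  # in-plane motion: the bone spans the full z range, so feet-head
  # translation would push slices out of the field of view
  truth <- axisRotation(4, axis = 3L, translation = c(2, 1.5, 0))
  moved <- applyMisalignment(case, truth)
  reg <- registerCase(moved, maxPoints = 1200)
  resid <- composeTransform(reg$transform, invertTransform(truth))
  # voxelized, re-discretized surfaces: accuracy is limited by the ~1 mm
  # grid, not the point-cloud bound that the noiseless-cloud tests check
  expect_lt(rotationAngle(resid), 5)
  expect_lt(translationMagnitude(resid), 3)
  bm <- boneMask(case)
  errAfter <- stats::median(abs(reg$ct[bm] - ctVolume(case)[bm]))
  errBefore <- stats::median(abs(moved@ct[bm] - ctVolume(case)[bm]))
  expect_lt(errAfter, errBefore)
  expect_lt(errAfter, 100)
})
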