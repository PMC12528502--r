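test_that("truncation and per-case min-max normalization", {
  v <- volumeImage(array(c(-2000, -1000, 500, 3000), c(4, 1, 1)))
  out <- truncateNormalize(v)
  expect_equal(c(volData(out)), c(0, 0, 0.5, 1))
  expect_equal(intensityDomain(out), "normalized01")
  expect_equal(normRange(out), c(-1000, 2000))

  expect_error(truncateNormalize(out), "HU-domain")

  r <- volumeImage(rand_vol(c(6, 5, 4), seed = 1, lo = -500, hi = 900))
  rn <- truncateNormalize(r)
  expect_equal(min(volData(rn)), 0)
  expect_equal(max(volData(rn)), 1)
  # inverse mapping restores the clipped HU values
  back <- denormalizeVolume(rn)
  expect_equal(volData(back), pmin(pmax(volData(r), -1000), 2000),
               tolerance = 1e-12)

  const <- volumeImage(array(40, c(3, 3, 3)))
  expect_warning(z <- truncateNormalize(const), "constant")
  expect_true(all(volData(z) == 0))
})

test_that("central crop keeps the centered half-open window", {
  a <- array(seq_len(16 * 16 * 8), c(16, 16, 8))
  cr <- centerCrop(a, c(8, 8, 8))
  expect_identical(cr, a[5:12, 5:12, 1:8])   # start = (16-8)/2 = 4

  big <- array(seq_len(256 * 256 * 4), c(256, 256, 4))
  crb <- centerCrop(big, c(128, 128, 4))
  expect_identical(crb, big[65:192, 65:192, 1:4])  # 0-based [64:192)

  expect_identical(centerCrop(a, dim(a)), a)
  expect_error(centerCrop(a, c(32, 8, 8)), "exceeds")

  hot <- array(0, c(16, 16, 8)); hot[8, 8, 4] <- 1
  expect_equal(sum(centerCrop(hot, c(8, 8, 4))), 1)
})

test_that("central-region mask is exactly the centered core box", {
  m <- centralRegionMask(c(128, 128, 64))
  expect_equal(sum(m), 128 * 64 * 64)       # default core (X, Y/2, Z)
  expect_true(all(m %in% c(0, 1)))

  expect_true(all(centralRegionMask(c(8, 8, 4), c(8, 8, 4)) == 1))

  m2 <- centralRegionMask(c(4, 4, 4), c(2, 2, 2))
  expect_equal(which(m2 == 1, arr.ind = TRUE)[, 1] %in% 2:3, rep(TRUE, 8))
  expect_equal(sum(m2), 8)
  expect_equal(sum(m2[2:3, 2:3, 2:3]), 8)
  expect_error(centralRegionMask(c(4, 4, 4), c(8, 2, 2)), "exceeds")
})

test_that("paired augmentation: identity, inverse shifts, binarity, bounds", {
  sp <- phantomSpec(gridShape = c(32, 32, 16), noiseSigmaHU = 0,
                    cbctOffsetHU = 0)
  case <- generatePlanningCase(sp, seed = 1)
  cbct <- planningVolume(case)
  masks <- planningMasks(case)

  idp <- augmentParams(c(0, 0, 0), 0)
  out <- augmentPair(cbct, masks, idp)
  expect_identical(volData(out$cbct), volData(cbct))
  expect_identical(out$masks@bladder, masks@bladder)

  fwd <- augmentPair(cbct, masks, augmentParams(c(5, 0, 0), 0))
  bck <- augmentPair(fwd$cbct, fwd$masks, augmentParams(c(-5, 0, 0), 0))
  expect_identical(bck$masks@ptv, masks@ptv)
  expect_identical(bck$masks@bladder, masks@bladder)

  rot <- augmentPair(cbct, masks, augmentParams(c(0, 0, 0), 3.5))
  for (nm in c("ptv", "bladder", "rectum", "body"))
    expect_true(all(structureMask(rot$masks, nm) %in% c(0, 1)))

  expect_error(augmentParams(c(6, 0, 0), 0), "5 voxels")
  expect_error(augmentParams(c(0, 0, 0), 5), "4 degrees")

  p1 <- sampleAugmentParams(123)
  p2 <- sampleAugmentParams(123)
  expect_identical(p1, p2)
})

test_that("unified mask: union plus iterated 26-connected dilation", {
  d <- c(16, 16, 16)
  z <- array(0, d)
  ptv <- z; ptv[8, 8, 8] <- 1
  masks <- structureMaskSet(ptv = ptv, bladder = z, rectum = z,
                            body = array(1, d))
  u3 <- buildUnifiedMask(masks, dilationPx = 3)
  expect_equal(sum(u3), 343)                      # 7^3 Chebyshev ball
  expect_identical(unclass(u3)[, , ], oracle_dilate(ptv, 3)[, , ])

  bl <- z; bl[4:6, 4:6, 4:6] <- 1
  re <- z; re[5:8, 5:8, 5:8] <- 1                 # overlaps bladder
  mk <- structureMaskSet(ptv = z, bladder = bl, rectum = re,
                         body = array(1, d))
  u0 <- buildUnifiedMask(mk, dilationPx = 0)
  expect_identical(c(u0), c(pmax(bl, re)))        # union counts voxels once

  expect_error(buildUnifiedMask(structureMaskSet(z, z, z, array(1, d))),
               "empty")
})

test_that("mask multiplication", {
  v <- volumeImage(rand_vol(c(6, 6, 4), seed = 2))
  ones <- array(1, c(6, 6, 4)); zero <- array(0, c(6, 6, 4))
  expect_identical(volData(applyMask(v, ones)), volData(v))
  expect_true(all(volData(applyMask(v, zero)) == 0))
  m <- ones; m[1:3, , ] <- 0
  expect_equal(sum(volData(applyMask(v, m))), sum(volData(v)[m == 1]))
  expect_error(applyMask(v, array(1, c(3, 3, 3))), "shape")
})

test_that("NIfTI round-trip preserves data and spacing", {
  v <- volumeImage(rand_vol(c(12, 10, 8), seed = 3),
                   spacing = c(1.98, 1.98, 3.0))
  path <- tempfile(fileext = ".nii.gz")
  writeVolume(v, path)
  rt <- readVolume(path)
  expect_lt(max(abs(volData(rt) - volData(v))), 1e-4)   # float32 payload
  expect_equal(voxelSpacing(rt), c(1.98, 1.98, 3.0), tolerance = 1e-6)

  p4 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 2))), p4)
  expect_error(readVolume(p4), "3D")
  unlink(c(path, p4))
})
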