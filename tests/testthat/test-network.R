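mkConfig <- function(variant, shape = c(32L, 32L, 16L), base = 4L,
                     levels = 3L)
  modelConfig(variant, inShape3d = shape, baseChannels = base,
              nLevels = levels)

randInputs <- function(shape, seed = 1) {
  set.seed(seed)
  v <- array(runif(prod(shape)), shape)
  list(drrs = renderPair(v, raster = c(shape[1], shape[1])),
       pct = array(runif(prod(shape)), shape))
}

test_that("every variant maps to the 3D input shape, bounded and finite", {
  for (variant in c("drrs_only", "fusion", "fusion_skip", "fusion_skip_res")) {
    cfg <- mkConfig(variant)
    m <- buildModel(cfg, seed = 1)
    inp <- randInputs(c(32L, 32L, 16L))
    out <- predictVolume(m, inp$drrs, inp$pct)
    expect_identical(dim(volData(out)), c(32L, 32L, 16L))
    expect_true(all(is.finite(volData(out))))
    expect_true(all(volData(out) >= 0 & volData(out) <= 1))
    out2 <- predictVolume(m, inp$drrs, inp$pct)
    expect_identical(volData(out), volData(out2))   # deterministic
  }
})

test_that("variant lattice orders the parameter counts", {
  counts <- vapply(c("fusion", "fusion_skip", "fusion_skip_res"),
                   function(v) countParams(buildModel(mkConfig(v), seed = 1)),
                   0)
  expect_lt(counts[["fusion"]], counts[["fusion_skip"]])
  expect_lt(counts[["fusion_skip"]], counts[["fusion_skip_res"]])
})

test_that("encoder blocks halve spatial dims and reject odd inputs", {
  m <- buildModel(mkConfig("fusion_skip_res"), seed = 2)
  x2 <- array(rnorm(32 * 32 * 2), c(32L, 32L, 1L, 2L))
  f2 <- encBlock2dForward(m, 1, x2)
  expect_identical(dim(f2), c(16L, 16L, 1L, 4L))
  x3 <- array(rnorm(32 * 32 * 16), c(32L, 32L, 16L, 1L))
  f3 <- encBlock3dForward(m, 1, x3)
  expect_identical(dim(f3), c(16L, 16L, 8L, 4L))
  expect_true(all(is.finite(f3)))
  expect_error(encBlock2dForward(m, 1, array(0, c(15L, 15L, 1L, 2L))),
               "even")

  # all-zero input stays finite (instance norm epsilon guards the zeros)
  z <- encBlock2dForward(m, 1, array(0, c(32L, 32L, 1L, 2L)))
  expect_true(all(is.finite(z)))
})

test_that("instance norm inside the block removes input scale", {
  m <- buildModel(mkConfig("fusion"), seed = 3)
  # zero the stride-2 conv bias so the pre-norm map scales exactly with x
  m$params[["e2_l1_a_b"]]$value[] <- 0
  x <- array(rnorm(32 * 32 * 2), c(32L, 32L, 1L, 2L))
  f1 <- encBlock2dForward(m, 1, x)
  f2 <- encBlock2dForward(m, 1, 2 * x)
  # equal up to the norm's variance epsilon (1e-5 on unit-scale variances)
  expect_lt(max(abs(f1 - f2)) / max(abs(f1)), 1e-3)
})

test_that("latent fusion conserves element counts and checks shapes", {
  cfg <- mkConfig("fusion_skip_res")   # top 16 channels, depth 2
  m <- buildModel(cfg, seed = 4)
  f2d <- array(rnorm(4 * 4 * 16), c(4L, 4L, 1L, 16L))
  f3d <- array(rnorm(4 * 4 * 2 * 16), c(4L, 4L, 2L, 16L))
  fused <- fuseForward(m, f2d, f3d)
  expect_identical(dim(fused)[1:3], dim(f3d)[1:3])  # 1x1x1 conv keeps dims
  expect_identical(dim(fused)[4], cfg$latentFuseChannels)

  bad2d <- array(rnorm(4 * 4 * 15), c(4L, 4L, 1L, 15L))  # 15 not divisible
  expect_error(fuseForward(m, bad2d, f3d), "4x4x1x15")
  off <- array(rnorm(8 * 8 * 2 * 16), c(8L, 8L, 2L, 16L))
  expect_error(fuseForward(m, f2d, off), "spatial dims differ")
})

test_that("decoder block doubles spatial dims; residual path is exact", {
  m <- buildModel(mkConfig("fusion_skip_res"), seed = 5)
  lat <- array(rnorm(4 * 4 * 2 * 16), c(4L, 4L, 2L, 16L))
  skip <- array(rnorm(8 * 8 * 4 * 8), c(8L, 8L, 4L, 8L))   # level-2 features
  out <- decBlockForward(m, 3, lat, skip)
  expect_identical(dim(out)[1:3], c(8L, 8L, 4L))

  # zero the conv stack: the block must reduce to the projected upsample
  for (suf in c("a_w", "a_b", "b_w", "b_b"))
    m$params[[paste0("d_l3_", suf)]]$value[] <- 0
  pure <- decBlockForward(m, 3, lat, skip)
  up <- OrthoCBCT:::adVal(OrthoCBCT:::.adUpsample2(
    OrthoCBCT:::adConst(lat)))
  cat_in <- array(c(up, skip), c(8L, 8L, 4L, 24L))
  proj <- OrthoCBCT:::conv3d_fwd_cpp(
    cat_in, dim(cat_in),
    m$params[["d_l3_proj_w"]]$value, dim(m$params[["d_l3_proj_w"]]$value),
    m$params[["d_l3_proj_b"]]$value, c(1L, 1L, 1L), c(0L, 0L, 0L))
  expect_lt(max(abs(pure - proj)), 1e-10)

  # non-skip variant accepts an absent skip
  mf <- buildModel(mkConfig("fusion"), seed = 5)
  expect_identical(dim(decBlockForward(mf, 3, lat))[1:3], c(8L, 8L, 4L))
  expect_error(decBlockForward(m, 3, lat), "skip")
})

test_that("configuration guards reject incompatible geometries", {
  expect_error(modelConfig("fusion", inShape3d = c(30, 30, 16),
                           baseChannels = 4, nLevels = 3), "divisible")
  expect_error(modelConfig("fusion", inShape3d = c(32, 64, 16),
                           baseChannels = 4, nLevels = 3), "match")
  m <- buildModel(mkConfig("fusion"), seed = 1)
  inp <- randInputs(c(32L, 32L, 16L))
  wrong <- renderPair(array(runif(16^3), c(16, 16, 16)), raster = c(16, 16))
  expect_error(predictVolume(m, wrong, inp$pct), "raster")
  expect_error(predictVolume(m, inp$drrs, array(0, c(16, 16, 16))), "pCT")
})
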