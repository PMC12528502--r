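fs <- featureExtractorSpec(baseChannels = 4, seed = 7)

test_that("masked MAE agrees with hand-built masks and loops", {
  d <- c(8, 8, 8)
  y <- array(100, d)
  x <- y
  body <- array(0, d); body[, , 1:4] <- 1       # half the voxels
  x[body == 1] <- 110                           # |x-y| = 10 inside
  x[body == 0] <- 1100                          # 1000 outside, ignored
  expect_equal(mMAE(x, y, body), 10)
  expect_equal(mMAE(y, y, body), 0)

  set.seed(40)
  a <- rand_vol(c(6, 6, 6), 41); b <- rand_vol(c(6, 6, 6), 42)
  m <- array(rbinom(216, 1, 0.6), c(6, 6, 6)); m[1] <- 1
  expect_equal(mMAE(a, b, m), oracle_mmae(a, b, m), tolerance = 1e-6)
  expect_error(mMAE(a, b, array(0, c(6, 6, 6))), "empty")
})

test_that("masked SSIM: identity, brute-force window oracle, bounds", {
  set.seed(43)
  d <- c(11, 11, 11)
  y <- array(runif(prod(d), 0, 100), d)
  body <- array(1, d)
  expect_equal(mSSIM(y, y, body), 1.0)

  x <- y + array(rnorm(prod(d), 0, 10), d)
  expect_equal(mSSIM(x, y, body), oracle_mssim(x, y, body),
               tolerance = 1e-5)
  irregular <- array(rbinom(prod(d), 1, 0.4), d); irregular[6, 6, 6] <- 1
  expect_equal(mSSIM(x, y, irregular), oracle_mssim(x, y, irregular),
               tolerance = 1e-5)
  expect_lt(mSSIM(x, y, body), 1)
  expect_error(mSSIM(x[1:5, , ], y[1:5, , ], body[1:5, , ]), "window")
})

test_that("masked PSNR follows the logarithmic definition", {
  d <- c(8, 8, 8)
  y <- array(runif(prod(d)), d); y[1] <- 1      # MAX_y = 1
  body <- array(1, d)
  x <- y + 0.1                                   # masked MSE = 0.01
  expect_equal(mPSNR(x, y, body), 20)
  x4 <- y + 0.2                                  # 4x the MSE
  expect_equal(mPSNR(x, y, body) - mPSNR(x4, y, body), 10 * log10(4),
               tolerance = 1e-10)
  expect_equal(mPSNR(y, y, body), Inf)

  set.seed(44)
  a <- rand_vol(d, 45); b <- rand_vol(d, 46)
  m <- array(rbinom(prod(d), 1, 0.5), d); m[1] <- 1
  expect_equal(mPSNR(a, b, m), oracle_mpsnr(a, b, m), tolerance = 1e-6)
})

test_that("cLPIPS: identity, symmetry, noise monotonicity", {
  set.seed(47)
  d <- c(16, 16, 6)
  y <- array(runif(prod(d)), d)
  expect_equal(cLPIPS(y, y, fs), 0)
  x <- array(runif(prod(d)), d)
  expect_equal(cLPIPS(x, y, fs), cLPIPS(y, x, fs), tolerance = 1e-12)

  vals <- vapply(c(0.01, 0.05, 0.1), function(s) {
    set.seed(48)
    cLPIPS(pmin(pmax(y + array(rnorm(prod(d), 0, s), d), 0), 1), y, fs)
  }, 0)
  expect_true(all(diff(vals) > 0))
  expect_error(cLPIPS(y[1:4, 1:4, ], y[1:4, 1:4, ], fs), "minimum")
})

test_that("masked metrics ignore changes outside the body", {
  set.seed(49)
  d <- c(14, 14, 14)
  y <- array(runif(prod(d), 0, 100), d)
  x <- y + array(rnorm(prod(d), 0, 5), d)
  body <- array(0, d); body[4:11, 4:11, 4:11] <- 1
  x2 <- x; x2[body == 0] <- x2[body == 0] + 500

  expect_identical(mMAE(x, y, body), mMAE(x2, y, body))
  expect_identical(mPSNR(x, y, body), mPSNR(x2, y, body))
  # SSIM windows overlap the boundary; compare on a mask eroded by the
  # window radius, where the local statistics cannot see the change
  eroded <- 1 - oracle_dilate(1 - body, 3)
  expect_equal(mSSIM(x, y, eroded, dataRange = max(y) - min(y)),
               mSSIM(x2, y, eroded, dataRange = max(y) - min(y)),
               tolerance = 1e-12)
})

test_that("growing noise degrades every metric monotonically", {
  set.seed(50)
  d <- c(16, 16, 8)
  y <- array(runif(prod(d), 0, 1), d)
  body <- array(1, d)
  sig <- c(0.02, 0.06, 0.12)
  res <- vapply(sig, function(s) {
    set.seed(51)
    x <- pmin(pmax(y + array(rnorm(prod(d), 0, s), d), 0), 1)
    c(mMAE(x, y, body), mSSIM(x, y, body), mPSNR(x, y, body),
      cLPIPS(x, y, fs))
  }, numeric(4))
  expect_true(all(diff(res[1, ]) > 0))   # mMAE rises
  expect_true(all(diff(res[2, ]) < 0))   # mSSIM falls
  expect_true(all(diff(res[3, ]) < 0))   # mPSNR falls
  expect_true(all(diff(res[4, ]) > 0))   # cLPIPS rises
})

test_that("cohort evaluation: perfect stub, report shape, summary means", {
  cohort <- makeCohort(phantomSpec(gridShape = c(32, 32, 16),
                                   nFractions = 2),
                       3, c(1 / 3, 1 / 3, 1 / 3), seed = 8)
  ev <- evaluateCohort(NULL, cohort, split = "test", featSpec = fs,
                       predictFun = function(drrs, pct, target) target)
  expect_equal(nrow(ev$reports), 2L)     # one row per fraction
  expect_true(all(ev$reports$mmae == 0))
  expect_true(all(ev$reports$mssim == 1))
  expect_true(all(ev$reports$clpips == 0))
  expect_equal(unname(ev$summary["mmae"]), mean(ev$reports$mmae))

  noisy <- evaluateCohort(NULL, cohort, split = "test", featSpec = fs,
                          predictFun = function(drrs, pct, target) {
                            set.seed(1)
                            pmin(pmax(target + array(
                              rnorm(length(target), 0, 0.02),
                              dim(target)), 0), 1)
                          })
  expect_true(all(noisy$reports$mmae > 0))
  expect_true(all(noisy$reports$mssim < 1))
  expect_error(evaluateCohort(NULL, cohort, split = "nope"), "arg")
})

test_that("statistical comparison: Kruskal-Wallis, Dunn, Bonferroni", {
  set.seed(52)
  g <- rnorm(20, 10, 1)
  same <- list(a = g, b = g)
  cmpSame <- compareLosses(same)
  expect_gt(cmpSame@omnibusP, 0.9)
  expect_equal(cmpSame@stars["a", "b"], "n.s.")

  far <- list(a = rnorm(30, 0, 1), b = rnorm(30, 10, 1),
              c = rnorm(30, 20, 1))
  cmpFar <- compareLosses(far)
  expect_lt(cmpFar@omnibusP, 0.001)
  off <- cmpFar@pairwiseP[upper.tri(cmpFar@pairwiseP)]
  expect_true(all(off < 0.001))
  expect_true(all(cmpFar@stars[upper.tri(cmpFar@stars)] == "***"))

  # Bonferroni is exactly min(1, raw * n_pairs)
  npair <- 3
  expect_equal(cmpFar@pairwiseP[upper.tri(cmpFar@pairwiseP)],
               pmin(1, cmpFar@rawP[upper.tri(cmpFar@rawP)] * npair))
  # adjusted never below raw; matrix symmetric (class validity enforces)
  expect_true(validObject(cmpFar))

  expect_error(compareLosses(list(a = rep(1, 5), b = rnorm(5))), "constant")
  expect_error(compareLosses(list(a = rnorm(2), b = rnorm(5))), "fewer")
  # normality screen reports a p-value per group
  expect_equal(length(cmpFar@normalityP), 3L)
})
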