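test_that("Kaiming-uniform initialization is seeded and bounded per fan", {
  cfg <- modelConfig("fusion_skip_res", inShape3d = c(32, 32, 16),
                     baseChannels = 4, nLevels = 3)
  m1 <- buildModel(cfg, seed = 11)
  m2 <- buildModel(cfg, seed = 11)
  for (nm in names(m1$params))
    expect_identical(m1$params[[nm]]$value, m2$params[[nm]]$value)
  m3 <- buildModel(cfg, seed = 12)
  expect_false(identical(m1$params[["out_w"]]$value,
                         m3$params[["out_w"]]$value))

  for (nm in names(m1$params)) {
    p <- m1$params[[nm]]
    bound <- if (grepl("_w$", nm)) sqrt(6 / p$fanIn) else 1 / sqrt(p$fanIn)
    expect_lte(max(abs(p$value)), bound)
    expect_gt(max(abs(p$value)), 0)   # no layer left identically zero
  }
})

test_that("plateau scheduler matches a hand-simulated oracle", {
  cfg <- trainConfig()
  # six flat epochs drop the rate at the sixth step
  s <- plateauScheduler(cfg)
  lrs <- vapply(rep(1, 6), function(l) lrScheduleStep(s, l), 0)
  expect_equal(lrs, c(rep(1e-3, 5), 1e-4))

  # strictly improving losses never decay
  s <- plateauScheduler(cfg)
  lrs <- vapply(seq(1, 0.5, length.out = 10),
                function(l) lrScheduleStep(s, l), 0)
  expect_true(all(lrs == 1e-3))

  # repeated plateaus floor at the minimum rate
  s <- plateauScheduler(cfg)
  lrs <- vapply(rep(2, 40), function(l) lrScheduleStep(s, l), 0)
  expect_equal(lrs[length(lrs)], 1e-6)

  set.seed(31)
  for (rep in 1:10) {
    losses <- cumprod(runif(25, 0.85, 1.1))
    s <- plateauScheduler(cfg)
    got <- vapply(losses, function(l) lrScheduleStep(s, l), 0)
    expect_equal(got, oracle_scheduler(losses))
  }
})

smallCohort <- function(seed = 2, nFractions = 1) {
  makeCohort(phantomSpec(gridShape = c(32, 32, 16),
                         nFractions = nFractions),
             3, c(1 / 3, 1 / 3, 1 / 3), seed = seed)
}

test_that("training history, best checkpoint and determinism", {
  cohort <- smallCohort()
  cfg <- modelConfig("fusion", inShape3d = c(32, 32, 16),
                     baseChannels = 4, nLevels = 3)
  tc <- trainConfig(epochs = 3, seed = 5)
  w <- lossPreset("onlyMAE")   # cheap loss keeps this test quick
  fit1 <- trainModel(buildModel(cfg, 5), cohort, w, tc)
  expect_equal(nrow(fit1$history), 3L)
  expect_equal(fit1$best$epoch,
               fit1$history$epoch[which.min(fit1$history$val_loss)])
  expect_equal(fit1$best$validationLoss, min(fit1$history$val_loss))

  fit2 <- trainModel(buildModel(cfg, 5), cohort, w, tc)
  expect_identical(fit1$history, fit2$history)

  # the reloaded best checkpoint reproduces the recorded validation loss
  restored <- restoreModel(fit1$best)
  core <- centralRegionMask(c(32L, 32L, 16L))
  val <- OrthoCBCT:::.validateEpoch(restored, cohort,
                                    cohortSplit(cohort, "val"), w,
                                    featureExtractorSpec(baseChannels = 4),
                                    core, 32L)
  expect_equal(val$loss, fit1$best$validationLoss, tolerance = 1e-12)
})

test_that("checkpoints survive a text round-trip", {
  cohort <- smallCohort()
  cfg <- modelConfig("fusion", inShape3d = c(32, 32, 16),
                     baseChannels = 4, nLevels = 3)
  fit <- trainModel(buildModel(cfg, 5), cohort, lossPreset("onlyMAE"),
                    trainConfig(epochs = 1, seed = 5))
  path <- tempfile(fileext = ".R")
  saveCheckpoint(fit$best, path)
  ck <- loadCheckpoint(path)
  expect_equal(ck$validationLoss, fit$best$validationLoss)
  m1 <- restoreModel(fit$best); m2 <- restoreModel(ck)
  for (nm in names(m1$params))
    expect_equal(m1$params[[nm]]$value, m2$params[[nm]]$value,
                 tolerance = 1e-12)
  unlink(path)
})

test_that("a poisoned model aborts with the offending component named", {
  cohort <- smallCohort()
  cfg <- modelConfig("fusion", inShape3d = c(32, 32, 16),
                     baseChannels = 4, nLevels = 3)
  m <- buildModel(cfg, 5)
  expect_error({
    m$params[["out_w"]]$value[] <- NaN
    trainModel(m, cohort, lossPreset("onlyMAE"), trainConfig(epochs = 1),
               reinit = FALSE)
  }, "mae")
})

test_that("cohorts without train or val split are rejected", {
  sp <- phantomSpec(gridShape = c(32, 32, 16), nFractions = 1)
  co <- makeCohort(sp, 3, c(1, 0, 0), seed = 1)
  cfg <- modelConfig("fusion", inShape3d = c(32, 32, 16),
                     baseChannels = 4, nLevels = 3)
  expect_error(trainModel(buildModel(cfg, 1), co), "val")
})
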