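spec16 <- phantomSpec(gridShape = c(32, 32, 16), noiseSigmaHU = 0,
                      cbctOffsetHU = 0)

test_that("planning case is deterministic with consistent masks and HU", {
  c1 <- generatePlanningCase(spec16, seed = 1)
  c2 <- generatePlanningCase(spec16, seed = 1)
  expect_identical(volData(planningVolume(c1)), volData(planningVolume(c2)))

  masks <- planningMasks(c1)
  body <- structureMask(masks, "body")
  ptv <- structureMask(masks, "ptv")
  expect_gt(sum(body), 0)
  expect_identical(ptv * body, ptv)  # PTV contained in body

  v <- volData(planningVolume(c1))
  hu <- spec16$tissueHU
  expect_true(all(v[structureMask(masks, "bladder") == 1] == hu[["bladder"]]))
  expect_true(all(v[ptv == 1] == hu[["prostate"]]))
  expect_true(all(v[structureMask(masks, "rectum") == 1] == hu[["rectum"]]))
  expect_true(all(v[body == 0] == hu[["air"]]))
})

test_that("identity anatomy state reproduces the planning volume exactly", {
  case <- generatePlanningCase(spec16, seed = 3)
  fr <- generateFraction(case, anatomyState())
  expect_identical(volData(fr$cbct), volData(planningVolume(case)))
  expect_identical(fr$masks@ptv, planningMasks(case)@ptv)
})

test_that("bladder volume scaling and rectal gas behave analytically", {
  case <- generatePlanningCase(spec16, seed = 3)
  n1 <- sum(structureMask(planningMasks(case), "bladder"))
  fr2 <- generateFraction(case, anatomyState(bladderVolumeScale = 2))
  ratio <- sum(structureMask(fr2$masks, "bladder")) / n1
  expect_gt(ratio, 1.8)   # analytic doubling within 10% discretization
  expect_lt(ratio, 2.2)

  frg <- generateFraction(case, anatomyState(rectalGasFraction = 0.5))
  rect <- structureMask(frg$masks, "rectum")
  expect_gte(sum(volData(frg$cbct)[rect == 1] <= -900), 1)
  # gas occupies about half the rectal tube
  gasFrac <- sum(volData(frg$cbct)[rect == 1] <= -900) / sum(rect)
  expect_gt(gasFrac, 0.35)
  expect_lt(gasFrac, 0.65)
})

test_that("fraction noise is seeded, confined to the body, and clipped", {
  noisy <- phantomSpec(gridShape = c(32, 32, 16), noiseSigmaHU = 20,
                       cbctOffsetHU = 10)
  case <- generatePlanningCase(noisy, seed = 5)
  st <- anatomyState(seed = 42)
  fa <- generateFraction(case, st)
  fb <- generateFraction(case, st)
  expect_identical(volData(fa$cbct), volData(fb$cbct))
  body <- structureMask(fa$masks, "body")
  expect_identical(volData(fa$cbct)[body == 0],
                   volData(planningVolume(case))[body == 0])
  expect_false(identical(volData(fa$cbct)[body == 1],
                         volData(planningVolume(case))[body == 1]))
  expect_true(all(volData(fa$cbct) >= -1000 & volData(fa$cbct) <= 2000))
})

test_that("invalid anatomy states and undersized grids are rejected", {
  expect_error(anatomyState(bladderVolumeScale = 0.1), "0.3")
  expect_error(anatomyState(rectalGasFraction = 1.5), "\\[0, 1\\]")
  expect_error(anatomyState(prostateOffsetMM = c(0, 0, 12)), "10 mm")
  tiny <- phantomSpec(gridShape = c(8, 8, 4))
  expect_error(generatePlanningCase(tiny, seed = 1), "organ")
  # an offset target can leave a very flat body
  flat <- phantomSpec(gridShape = c(64, 16, 32))
  case <- try(generatePlanningCase(flat, seed = 1), silent = TRUE)
  if (!inherits(case, "try-error"))
    expect_error(generateFraction(case, anatomyState(
      prostateOffsetMM = c(0, 10, 0))), "body")
})

test_that("cohorts are split patient-wise and deterministically", {
  sp <- phantomSpec(gridShape = c(32, 32, 16), nFractions = 1)
  co <- makeCohort(sp, 10, c(0.6, 0.2, 0.2), seed = 9)
  expect_equal(unname(table(co$split)[c("train", "val", "test")]),
               c(6L, 2L, 2L), ignore_attr = TRUE)
  ids <- names(co$split)
  expect_equal(length(unique(ids)), 10L)
  expect_setequal(c(cohortSplit(co, "train"), cohortSplit(co, "val"),
                    cohortSplit(co, "test")), ids)
  co2 <- makeCohort(sp, 10, c(0.6, 0.2, 0.2), seed = 9)
  expect_identical(co$manifest, co2$manifest)

  all_train <- makeCohort(sp, 3, c(1, 0, 0), seed = 1)
  expect_equal(length(cohortSplit(all_train, "train")), 3L)
  expect_error(makeCohort(sp, 2, c(0.4, 0.3, 0.3), seed = 1), "3 patients")
  expect_error(makeCohort(sp, 4, c(0.5, 0.3, 0.3), seed = 1), "sum to 1")
})

test_that("cohort NIfTI output round-trips with the manifest on disk", {
  sp <- phantomSpec(gridShape = c(32, 32, 16), nFractions = 2)
  dir <- tempfile("cohort")
  co <- makeCohort(sp, 3, c(1 / 3, 1 / 3, 1 / 3), seed = 2, outDir = dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(length(man$cases), 3L)
  id <- caseId(co$cases[[1]])
  rt <- readVolume(file.path(dir, id, "pct.nii.gz"))
  expect_lt(max(abs(volData(rt) - volData(planningVolume(co$cases[[1]])))),
            1e-4)
  expect_equal(voxelSpacing(rt), c(1.98, 1.98, 3.0), tolerance = 1e-5)
  unlink(dir, recursive = TRUE)
})
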