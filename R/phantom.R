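# Anthropomorphic pelvic phantom cohorts.
#
# Organs are analytic ellipsoids / elliptic cylinders rasterized on the voxel
# grid, so masks and intensities are exactly consistent and voxel counts are
# analytically checkable. Inter-fraction variation re-rasterizes the same
# primitives under a new AnatomyState (bladder volume scale, rectal gas,
# target offset), which makes the identity state reproduce the planning
# volume bit-for-bit.

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Phantom cohort specification
#'
#' Grid, spacing, fraction count and tissue intensity table for the pelvic
#' phantom generator. Default tissue values approximate soft tissue (40 HU),
#' urine-filled bladder (10 HU), rectal wall (25 HU), rectal gas (-950 HU),
#' pelvic bone (700 HU) and air (-1000 HU).
#'
#' @param gridShape voxels per axis (x, y, z); all even.
#' @param spacing voxel spacing in mm.
#' @param nFractions CBCT-like fractions per patient.
#' @param noiseSigmaHU additive Gaussian noise (HU) applied inside the body
#'   of each fraction, modelling the CBCT domain gap.
#' @param cbctOffsetHU global intensity offset (HU) inside the body of each
#'   fraction.
#' @param rectumRadiusMM rectal tube radius in mm.
#' @param tissueHU named HU table for \code{body}, \code{bone},
#'   \code{bladder}, \code{prostate}, \code{rectum}, \code{gas}, \code{air}.
#' @return A validated list of class \code{"phantomSpec"}.
#' @examples
#' spec <- phantomSpec(gridShape = c(32, 32, 16))
#' case <- generatePlanningCase(spec, seed = 1)
#' @export
phantomSpec <- function(gridShape = c(64, 64, 32),
                        spacing = c(1.98, 1.98, 3.0),
                        nFractions = 3L,
                        noiseSigmaHU = 20,
                        cbctOffsetHU = 10,
                        rectumRadiusMM = 8,
                        tissueHU = c(body = 40, bone = 700, bladder = 10,
                                     prostate = 50, rectum = 25, gas = -950,
                                     air = -1000)) {
  stopifnot(length(gridShape) == 3L, all(gridShape %% 2 == 0),
            all(gridShape > 0), length(spacing) == 3L, all(spacing > 0),
            nFractions >= 1L)
  if (any(tissueHU < -1000) || any(tissueHU > 2000))
    stop("tissue HU values must lie within [-1000, 2000]")
  needed <- c("body", "bone", "bladder", "prostate", "rectum", "gas", "air")
  if (!all(needed %in% names(tissueHU)))
    stop("tissueHU must name: ", paste(needed, collapse = ", "))
  structure(list(gridShape = as.integer(gridShape),
                 spacing = as.numeric(spacing),
                 nFractions = as.integer(nFractions),
                 noiseSigmaHU = noiseSigmaHU,
                 cbctOffsetHU = cbctOffsetHU,
                 rectumRadiusMM = rectumRadiusMM,
                 tissueHU = tissueHU),
            class = "phantomSpec")
}

#' Per-fraction anatomy state
#'
#' Parameters of inter-fractional variation: bladder filling (volume scale,
#' applied to the ellipsoid axes as its cube root), rectal gas (fraction of
#' the rectal tube occupied by a gas pocket at gas HU), and a rigid offset of
#' the target.
#'
#' @param bladderVolumeScale in \code{[0.3, 3]}; 1 = planning state.
#' @param rectalGasFraction in \code{[0, 1]}.
#' @param prostateOffsetMM 3-vector, each component within ±10 mm.
#' @param seed integer seed used when the fraction adds noise.
#' @return A list of class \code{"anatomyState"}.
#' @export
anatomyState <- function(bladderVolumeScale = 1, rectalGasFraction = 0,
                         prostateOffsetMM = c(0, 0, 0), seed = 1L) {
  stopifnot(length(prostateOffsetMM) == 3L)
  if (bladderVolumeScale < 0.3 || bladderVolumeScale > 3)
    stop("bladderVolumeScale must lie in [0.3, 3]")
  if (rectalGasFraction < 0 || rectalGasFraction > 1)
    stop("rectalGasFraction must lie in [0, 1]")
  if (any(abs(prostateOffsetMM) > 10))
    stop("prostate offsets are bounded by +/-10 mm")
  structure(list(bladderVolumeScale = bladderVolumeScale,
                 rectalGasFraction = rectalGasFraction,
                 prostateOffsetMM = as.numeric(prostateOffsetMM),
                 seed = as.integer(seed)),
            class = "anatomyState")
}

# Voxel-centre coordinate grids in mm, centred on the volume.
.coordGrids <- function(spec) {
  d <- spec$gridShape; s <- spec$spacing
  list(x = (seq_len(d[1]) - (d[1] + 1) / 2) * s[1],
       y = (seq_len(d[2]) - (d[2] + 1) / 2) * s[2],
       z = (seq_len(d[3]) - (d[3] + 1) / 2) * s[3])
}

.ellipsoidMask <- function(g, centre, radii) {
  d <- c(length(g$x), length(g$y), length(g$z))
  qx <- ((g$x - centre[1]) / radii[1])^2
  qy <- ((g$y - centre[2]) / radii[2])^2
  qz <- ((g$z - centre[3]) / radii[3])^2
  q <- outer(outer(qx, qy, "+"), qz, "+")
  array(as.numeric(q <= 1), dim = d)
}

# Elliptic cylinder along z between zlim (NULL = full extent).
.cylinderMask <- function(g, centre2, radii2, zlim = NULL) {
  d <- c(length(g$x), length(g$y), length(g$z))
  qx <- ((g$x - centre2[1]) / radii2[1])^2
  qy <- ((g$y - centre2[2]) / radii2[2])^2
  q2 <- outer(qx, qy, "+") <= 1
  zin <- if (is.null(zlim)) rep(TRUE, d[3]) else (g$z >= zlim[1] & g$z <= zlim[2])
  array(as.numeric(outer(q2, zin, "&")), dim = d)
}

# Fixed anatomy layout in mm, derived once from the grid extent.
.phantomGeometry <- function(spec, state = anatomyState()) {
  ext <- spec$gridShape * spec$spacing
  ax <- 0.45 * ext[1]; ay <- 0.42 * ext[2]
  bl <- state$bladderVolumeScale^(1 / 3)
  list(
    body = list(centre = c(0, 0), radii = c(ax, ay)),
    boneOuter = list(centre = c(0, 0), radii = 0.95 * c(ax, ay)),
    boneInner = list(centre = c(0, 0), radii = 0.85 * c(ax, ay)),
    bladder = list(centre = c(0, -0.18 * ext[2], 0.10 * ext[3]),
                   radii = bl * c(0.16 * ext[1], 0.13 * ext[2],
                                  0.16 * ext[3])),
    prostate = list(centre = c(0, 0.10 * ext[2], -0.08 * ext[3]) +
                      state$prostateOffsetMM,
                    radii = c(0.09 * ext[1], 0.09 * ext[2], 0.12 * ext[3])),
    rectum = list(centre = c(0, 0.26 * ext[2]),
                  radii = c(spec$rectumRadiusMM, spec$rectumRadiusMM),
                  zlim = c(-0.35, 0.35) * ext[3])
  )
}

# Rasterize the phantom for a given anatomy state; returns the noiseless HU
# volume and its masks.
.rasterizePhantom <- function(spec, state) {
  g <- .coordGrids(spec)
  geo <- .phantomGeometry(spec, state)
  hu <- spec$tissueHU

  for (org in c("body", "bladder", "prostate", "rectum")) {
    radii <- geo[[org]]$radii
    sp <- if (org %in% c("body", "rectum")) spec$spacing[1:2] else spec$spacing
    if (any(radii < sp))
      stop(sprintf("grid too small to contain organ '%s' at minimum radius",
                   org))
  }

  body <- .cylinderMask(g, geo$body$centre, geo$body$radii)
  bone <- pmax(.cylinderMask(g, geo$boneOuter$centre, geo$boneOuter$radii) -
               .cylinderMask(g, geo$boneInner$centre, geo$boneInner$radii), 0)
  bladder <- .ellipsoidMask(g, geo$bladder$centre, geo$bladder$radii)
  prostate <- .ellipsoidMask(g, geo$prostate$centre, geo$prostate$radii)
  rectum <- .cylinderMask(g, geo$rectum$centre, geo$rectum$radii,
                          geo$rectum$zlim)

  if (any(bladder > body))
    stop("scaled bladder exceeds the body contour")
  if (any(prostate > body))
    stop("offset target exceeds the body contour")

  # Gas pocket: central z-segment of the rectal tube covering the stated
  # fraction of its length (hence ~ that fraction of its voxels).
  gas <- array(0, dim = spec$gridShape)
  if (state$rectalGasFraction > 0) {
    half <- state$rectalGasFraction * diff(geo$rectum$zlim) / 2
    mid <- mean(geo$rectum$zlim)
    gas <- .cylinderMask(g, geo$rectum$centre, geo$rectum$radii,
                         c(mid - half, mid + half))
  }

  # Painting order fixes overlap priority; the exported masks are the
  # painted regions (soft-tissue organs win over bone, the target over
  # everything), so mask and intensity stay exactly consistent.
  vol <- array(hu[["air"]], dim = spec$gridShape)
  vol[body == 1] <- hu[["body"]]
  vol[bone == 1] <- hu[["bone"]]
  vol[rectum == 1] <- hu[["rectum"]]
  vol[gas == 1] <- hu[["gas"]]
  vol[bladder == 1] <- hu[["bladder"]]
  vol[prostate == 1] <- hu[["prostate"]]

  bladderM <- bladder * (1 - prostate)
  rectumM <- rectum * (1 - bladder) * (1 - prostate)
  list(volume = vol,
       masks = structureMaskSet(ptv = prostate, bladder = bladderM,
                                rectum = rectumM, body = body))
}

#' Generate the planning anatomy of one phantom patient
#'
#' Rasterizes the reference anatomy (elliptical body, pelvic bone ring,
#' bladder, prostate target and rectal tube) as a noiseless HU volume with
#' exactly matching structure masks. Deterministic given the seed (the
#' planning anatomy itself is seed-independent; the seed is recorded for the
#' fraction generator).
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @param seed integer.
#' @return A \linkS4class{PhantomCase} without fractions.
#' @export
generatePlanningCase <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantomSpec"))
  r <- .rasterizePhantom(spec, anatomyState(seed = seed))
  new("PhantomCase",
      caseId = sprintf("case_%04d", as.integer(seed)),
      pct = volumeImage(r$volume, spacing = spec$spacing, domain = "HU"),
      masks = r$masks,
      fractions = list(),
      spec = unclass(spec))
}

#' Generate one CBCT-like treatment fraction
#'
#' Re-rasterizes the phantom under an \code{\link{anatomyState}} (bladder
#' volume scaled by the cube root per axis, a rectal gas pocket, target
#' offset), then applies the CBCT domain gap: a global intensity offset and
#' additive Gaussian noise, both only inside the body. Masks follow the
#' deformed geometry. With the identity state and zero noise/offset the
#' fraction equals the planning volume exactly.
#'
#' @param case a \linkS4class{PhantomCase}.
#' @param state an \code{\link{anatomyState}}.
#' @return List with \code{cbct} (\linkS4class{VolumeImage}, HU),
#'   \code{masks} (\linkS4class{StructureMaskSet}) and \code{state}.
#' @export
generateFraction <- function(case, state) {
  stopifnot(is(case, "PhantomCase"), inherits(state, "anatomyState"))
  spec <- do.call(phantomSpec, case@spec[c("gridShape", "spacing",
                                           "nFractions", "noiseSigmaHU",
                                           "cbctOffsetHU", "rectumRadiusMM",
                                           "tissueHU")])
  r <- .rasterizePhantom(spec, state)
  vol <- r$volume
  inside <- structureMask(r$masks, "body") == 1
  if (spec$cbctOffsetHU != 0)
    vol[inside] <- vol[inside] + spec$cbctOffsetHU
  if (spec$noiseSigmaHU > 0) {
    noise <- withSeed(state$seed,
                      rnorm(sum(inside), sd = spec$noiseSigmaHU))
    vol[inside] <- vol[inside] + noise
  }
  vol <- pmin(pmax(vol, -1000), 2000)
  list(cbct = volumeImage(vol, spacing = spec$spacing, domain = "HU"),
       masks = r$masks, state = state)
}

# Random anatomy states emulating day-to-day bladder/rectum variation.
.sampleState <- function(seed) {
  withSeed(seed, {
    anatomyState(bladderVolumeScale = runif(1, 0.7, 1.5),
                 rectalGasFraction = if (runif(1) < 0.5) 0 else runif(1, 0.1, 0.5),
                 prostateOffsetMM = runif(3, -5, 5),
                 seed = sample.int(.Machine$integer.max - 1L, 1))
  })
}

#' Generate a phantom cohort on disk
#'
#' Builds \code{nPatients} phantom cases (planning volume + fractions with
#' sampled anatomy states), assigns every patient to exactly one of the
#' train/validation/test splits (patient-wise, so no fraction of one patient
#' crosses splits), writes NIfTI volumes plus a JSON manifest to
#' \code{outDir}, and returns the in-memory cohort.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @param nPatients number of patients.
#' @param splitFractions numeric(3) (train, val, test) summing to 1.
#' @param seed integer; drives patient seeds and anatomy states.
#' @param outDir output directory (created if missing); NULL skips writing.
#' @return List of class \code{"phantomCohort"} with \code{cases},
#'   \code{split} (named character) and \code{manifest}.
#' @export
makeCohort <- function(spec, nPatients, splitFractions = c(0.6, 0.2, 0.2),
                       seed = 1L, outDir = NULL) {
  stopifnot(inherits(spec, "phantomSpec"), nPatients >= 1)
  if (abs(sum(splitFractions) - 1) > 1e-8)
    stop("splitFractions must sum to 1")
  if (all(splitFractions > 0) && nPatients < 3)
    stop("need at least 3 patients when all three splits are nonempty")

  patientSeeds <- withSeed(seed, sample.int(.Machine$integer.max - 1L,
                                            nPatients))
  cases <- vector("list", nPatients)
  for (i in seq_len(nPatients)) {
    case <- generatePlanningCase(spec, seed = patientSeeds[i])
    case@caseId <- sprintf("case_%03d", i)
    frs <- vector("list", spec$nFractions)
    for (k in seq_len(spec$nFractions)) {
      st <- .sampleState(patientSeeds[i] %% 99991L * 100L + k)
      frs[[k]] <- generateFraction(case, st)
    }
    case@fractions <- frs
    cases[[i]] <- case
  }

  cuts <- floor(cumsum(splitFractions) * nPatients + 1e-9)
  splitOf <- rep("train", nPatients)
  if (nPatients >= 1) {
    splitOf[seq_len(nPatients) > cuts[1]] <- "val"
    splitOf[seq_len(nPatients) > cuts[2]] <- "test"
  }
  names(splitOf) <- vapply(cases, caseId, "")

  manifest <- list(seed = seed,
                   gridShape = spec$gridShape,
                   spacing = spec$spacing,
                   nFractions = spec$nFractions,
                   cases = lapply(seq_len(nPatients), function(i)
                     list(case_id = caseId(cases[[i]]),
                          split = unname(splitOf[i]),
                          n_fractions = length(fractions(cases[[i]])))))

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (case in cases) {
      cdir <- file.path(outDir, caseId(case))
      dir.create(cdir, showWarnings = FALSE)
      writeVolume(planningVolume(case), file.path(cdir, "pct.nii.gz"))
      for (nm in c("ptv", "bladder", "rectum", "body"))
        writeVolume(volumeImage(structureMask(planningMasks(case), nm),
                                spacing = spec$spacing),
                    file.path(cdir, sprintf("mask_%s.nii.gz", nm)))
      for (k in seq_along(fractions(case)))
        writeVolume(fractions(case)[[k]]$cbct,
                    file.path(cdir, sprintf("fx_%02d.nii.gz", k)))
    }
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(list(cases = cases, split = splitOf, manifest = manifest,
                 spec = spec, dir = outDir),
            class = "phantomCohort")
}

#' @describeIn makeCohort case ids belonging to one split
#' @param cohort a phantom cohort
#' @param split \code{"train"}, \code{"val"} or \code{"test"}
#' @export
cohortSplit <- function(cohort, split = c("train", "val", "test")) {
  split <- match.arg(split)
  names(cohort$split)[cohort$split == split]
}
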