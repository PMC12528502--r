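# Masked image-quality metrics and the loss-ablation comparison.
#
# mMAE / mSSIM / mPSNR are computed on the HU scale (normalized volumes are
# mapped back through the recorded per-case range) and averaged only over
# voxels inside the body contour; cLPIPS works on the centrally cropped
# normalized volumes. SSIM uses a uniform 7x7x7 window with constants
# c1 = (0.01 L)^2, c2 = (0.03 L)^2 over reflection-padded local moments,
# attributed to the window's centre voxel.

.maskedCheck <- function(x, y, mask) {
  .checkSameShape(x, y)
  .checkSameShape(x, mask)
  if (sum(mask) == 0) stop("body mask is empty")
}

#' Masked mean absolute error
#'
#' @param x,y volumes (synthetic and ground truth), HU scale.
#' @param body binary body mask.
#' @return Mean of \eqn{|x - y|} over body voxels, in HU.
#' @export
mMAE <- function(x, y, body) {
  x <- .arr3(x); y <- .arr3(y)
  .maskedCheck(x, y, body)
  sum(abs(x - y) * body) / sum(body)
}

# Symmetric (edge-including) reflection padding by p voxels per axis.
.padReflect <- function(a, p) {
  d <- dim(a)
  ix <- lapply(d, function(n) c(rev(seq_len(p)), seq_len(n),
                                n - seq_len(p) + 1L))
  a[ix[[1]], ix[[2]], ix[[3]]]
}

# Local box-window mean via the C++ conv kernel (single channel).
.boxMean <- function(a, win) {
  d <- dim(a)
  p <- (win - 1L) %/% 2L
  ap <- .padReflect(a, p)
  dp <- dim(ap)
  k <- array(1 / win^3, dim = c(win, win, win, 1L, 1L))
  y <- conv3d_fwd_cpp(array(ap, dim = c(dp, 1L)), as.integer(c(dp, 1L)),
                      k, as.integer(c(win, win, win, 1L, 1L)), 0,
                      c(1L, 1L, 1L), c(0L, 0L, 0L))
  array(y, dim = d)
}

#' Masked structural similarity (mSSIM)
#'
#' Local SSIM from 7x7x7 windowed means, variances and covariance
#' (population moments, reflection padding), averaged over body voxels.
#' Identical volumes give exactly 1.
#'
#' @param x,y volumes on a common scale.
#' @param body binary body mask.
#' @param dataRange dynamic range L (default: \code{max(y) - min(y)}).
#' @param win odd window size (default 7).
#' @param k1,k2 SSIM constants (0.01, 0.03).
#' @return mSSIM in \code{[0, 1]} (up to small negative local terms).
#' @export
mSSIM <- function(x, y, body, dataRange = NULL, win = 7L,
                  k1 = 0.01, k2 = 0.03) {
  x <- .arr3(x); y <- .arr3(y)
  .maskedCheck(x, y, body)
  if (any(dim(x) < win)) stop("volume smaller than the SSIM window")
  if (is.null(dataRange)) dataRange <- max(y) - min(y)
  if (dataRange <= 0) stop("degenerate dynamic range")
  c1 <- (k1 * dataRange)^2; c2 <- (k2 * dataRange)^2
  mx <- .boxMean(x, win); my <- .boxMean(y, win)
  vx <- .boxMean(x * x, win) - mx^2
  vy <- .boxMean(y * y, win) - my^2
  cxy <- .boxMean(x * y, win) - mx * my
  smap <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  sum(smap * body) / sum(body)
}

#' Masked peak signal-to-noise ratio (dB)
#'
#' \eqn{10 \log_{10}(MAX_y^2 / MSE_{body})} with \eqn{MAX_y} the maximum of
#' the ground truth and the MSE averaged over body voxels. A zero masked MSE
#' returns \code{Inf}.
#'
#' @param x,y volumes (synthetic and ground truth).
#' @param body binary body mask.
#' @return mPSNR in dB.
#' @export
mPSNR <- function(x, y, body) {
  x <- .arr3(x); y <- .arr3(y)
  .maskedCheck(x, y, body)
  mse <- sum((x - y)^2 * body) / sum(body)
  if (mse == 0) return(Inf)
  10 * log10(max(y)^2 / mse)
}

# LPIPS-style distance for one slice pair: features unit-normalized across
# channels at every spatial position, squared differences summed over
# channels, averaged over positions; uniform layer weights.
.lpipsSlice <- function(a, b, spec) {
  adTapeBegin()
  fa <- adBackboneFeatures(adRGB(adConst(a)), spec)
  fb <- adBackboneFeatures(adRGB(adConst(b)), spec)
  eps <- 1e-10
  ds <- vapply(seq_along(fa), function(k) {
    va <- fa[[k]]$value; vb <- fb[[k]]$value
    d <- dim(va)
    ma <- matrix(va, ncol = d[4]); mb <- matrix(vb, ncol = d[4])
    ma <- ma / sqrt(rowSums(ma^2) + eps)
    mb <- mb / sqrt(rowSums(mb^2) + eps)
    mean(rowSums((ma - mb)^2))
  }, 0)
  mean(ds)
}

#' Cropped learned perceptual image patch similarity (cLPIPS)
#'
#' Perceptual patch distance between two centrally cropped volumes,
#' computed axial slice by axial slice on pseudo-RGB inputs with per-layer
#' unit-normalized features, averaged over slices and layers. Symmetric,
#' zero on identical inputs; grows with independent noise.
#'
#' @param x,y cropped volumes in \code{[0, 1]} (arrays or
#'   \linkS4class{VolumeImage}).
#' @param spec a \code{\link{featureExtractorSpec}}.
#' @return Non-negative scalar.
#' @export
cLPIPS <- function(x, y, spec = featureExtractorSpec()) {
  x <- .arr3(x); y <- .arr3(y)
  .checkSameShape(x, y)
  minHW <- 2L^sum(.vggLayout()$pool < max(spec$layerIds))
  if (any(dim(x)[1:2] < minHW))
    stop("raster below the backbone minimum for the requested layers")
  mean(vapply(seq_len(dim(x)[3]),
              function(z) .lpipsSlice(x[, , z], y[, , z], spec), 0))
}

# Extract the central core box (the region the central-region mask keeps).
.coreBox <- function(a, coreShape = NULL) {
  d <- dim(a)
  if (is.null(coreShape)) coreShape <- c(d[1], d[2] %/% 2L, d[3])
  .centerCropArray(a, as.integer(coreShape))
}

#' Evaluate a model over one cohort split
#'
#' For every fraction of every case in the split: preprocess (normalize,
#' core-mask, render DRRs), synthesize the volume, map both volumes back to
#' HU through the ground truth's recorded range, and compute the masked
#' metrics within the fraction's body contour plus cLPIPS on the cropped
#' normalized volumes.
#'
#' @param model a \code{"fusionModel"} (ignored when \code{predictFun} is
#'   given).
#' @param cohort a \code{"phantomCohort"}.
#' @param split \code{"train"}, \code{"val"} or \code{"test"}.
#' @param featSpec a \code{\link{featureExtractorSpec}}.
#' @param predictFun optional stub replacing the network: a function
#'   \code{(drrs, pctIn, target) -> 3D array in [0, 1]} (e.g. a
#'   perfect-prediction stub returning the target).
#' @return List with \code{reports} (one row per fraction: case_id,
#'   fraction, mmae, mssim, mpsnr, clpips) and \code{summary} (mean per
#'   metric).
#' @export
evaluateCohort <- function(model, cohort, split = "test",
                           featSpec = featureExtractorSpec(),
                           predictFun = NULL) {
  ids <- cohortSplit(cohort, split)
  if (length(ids) == 0L) stop("split '", split, "' is empty")
  caseOf <- setNames(cohort$cases, vapply(cohort$cases, caseId, ""))
  if (is.null(predictFun)) {
    stopifnot(inherits(model, "fusionModel"))
    core <- centralRegionMask(model$cfg$inShape3d)
    raster <- model$cfg$inRaster2d
  } else {
    d0 <- dim(volData(planningVolume(caseOf[[ids[1]]])))
    core <- centralRegionMask(d0)
    raster <- d0[1]
  }
  rows <- list()
  for (id in ids) {
    case <- caseOf[[id]]
    if (length(fractions(case)) == 0L)
      stop("case '", id, "' has no fractions")
    for (k in seq_along(fractions(case))) {
      fr <- fractions(case)[[k]]
      if (is.null(fr$masks)) stop("case '", id, "' is missing masks")
      pr <- .preparePair(case, fr, core, raster, augment = NULL)
      sArr <- if (is.null(predictFun)) {
        volData(predictVolume(model,
                              pr$drrs,
                              volumeImage(pr$pctIn, domain = "normalized01")))
      } else predictFun(pr$drrs, pr$pctIn, pr$target)
      rng <- pr$normRange
      sHU <- sArr * (rng[2] - rng[1]) + rng[1]
      tHU <- pr$target * (rng[2] - rng[1]) + rng[1]
      body <- structureMask(pr$masks, "body")
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = id, fraction = k,
        mmae = mMAE(sHU, tHU, body),
        mssim = mSSIM(sHU, tHU, body),
        mpsnr = mPSNR(sHU, tHU, body),
        clpips = cLPIPS(.coreBox(sArr), .coreBox(pr$target), featSpec))
    }
  }
  reports <- do.call(rbind, rows)
  list(reports = reports,
       summary = colMeans(reports[, c("mmae", "mssim", "mpsnr", "clpips")]))
}

# Dunn's pairwise rank test with tie correction; two-sided normal p-values.
.dunnTest <- function(values, groups) {
  N <- length(values)
  r <- rank(values)
  lev <- unique(groups)
  Rbar <- tapply(r, groups, mean)[lev]
  n <- tapply(r, groups, length)[lev]
  ties <- table(values)
  tieC <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tieC
  np <- length(lev)
  z <- p <- matrix(NA_real_, np, np, dimnames = list(lev, lev))
  for (i in seq_len(np - 1)) for (j in (i + 1):np) {
    zij <- (Rbar[i] - Rbar[j]) / sqrt(s2 * (1 / n[i] + 1 / n[j]))
    z[i, j] <- z[j, i] <- zij
    p[i, j] <- p[j, i] <- 2 * pnorm(-abs(zij))
  }
  list(z = z, p = p)
}

.starsOf <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "n.s.")))
}

#' Compare loss configurations statistically
#'
#' The non-parametric pipeline used for the loss-ablation comparison:
#' Shapiro-Wilk normality screen per group, Kruskal-Wallis omnibus test,
#' then Dunn's pairwise test with Bonferroni correction and star coding
#' (*p < 0.05, **p < 0.01, ***p < 0.001, n.s. otherwise).
#'
#' @param metricTables named list of numeric vectors (per-case metric values
#'   per loss configuration); at least 2 groups of at least 3 cases.
#' @return A \linkS4class{ComparisonResult}.
#' @export
compareLosses <- function(metricTables) {
  stopifnot(is.list(metricTables), length(metricTables) >= 2)
  if (is.null(names(metricTables)))
    names(metricTables) <- paste0("group", seq_along(metricTables))
  for (nm in names(metricTables)) {
    v <- metricTables[[nm]]
    if (length(v) < 3) stop("group '", nm, "' has fewer than 3 cases")
    if (length(unique(v)) == 1)
      stop("group '", nm, "' is constant; the rank tests are undefined")
  }
  normP <- vapply(metricTables, function(v) shapiro.test(v)$p.value, 0)
  values <- unlist(metricTables, use.names = FALSE)
  groups <- factor(rep(names(metricTables),
                       vapply(metricTables, length, 0L)),
                   levels = names(metricTables))
  kw <- kruskal.test(values, groups)
  dn <- .dunnTest(values, groups)
  npair <- sum(!is.na(dn$p[upper.tri(dn$p)]))
  adj <- dn$p
  adj[] <- pmin(1, dn$p * npair)
  stars <- adj
  stars[] <- .starsOf(adj)
  diag(adj) <- diag(dn$p) <- NA_real_
  new("ComparisonResult", groups = names(metricTables),
      normalityP = normP, omnibusP = kw$p.value,
      pairwiseP = adj, rawP = dn$p, stars = structure(stars, dim = dim(adj),
                                                      dimnames = dimnames(adj)))
}
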