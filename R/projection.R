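# Parallel-beam DRR rendering.
#
# The ray operator is the mean of voxel values along the ray axis (keeping
# DRR magnitudes comparable across volume sizes); gantry angle 0 = anterior
# source, integrating along y; 270 = left lateral, integrating along x (IEC
# convention for a supine patient). Resizing uses separable linear
# interpolation with half-pixel centres; each image is min-max normalized to
# [0, 1] last, so the network input range is exact.

.projectArray <- function(a, angle) {
  if (!angle %in% c(0, 270))
    stop("only gantry angles 0 and 270 are supported")
  axis <- if (angle == 0) 2L else 1L
  keep <- setdiff(1:3, axis)
  apply(a, keep, mean)
}

.resizeMatrixImg <- function(img, raster) {
  d <- dim(img)
  out <- interpMatrix(raster[1], d[1]) %*% img
  t(interpMatrix(raster[2], d[2]) %*% t(out))
}

.minmax01 <- function(img, warnConstant = TRUE) {
  mn <- min(img); mx <- max(img)
  if (mx == mn) {
    if (warnConstant) warning("constant projection; returning zeros")
    return(img * 0)
  }
  (img - mn) / (mx - mn)
}

#' Parallel projection of a volume at one gantry angle
#'
#' Approximates the line integral by the mean of voxel values along the ray
#' axis: angle 0 (anterior view) integrates along the anterior-posterior
#' axis giving an (x, z) image; angle 270 (left lateral) integrates along
#' the left-right axis giving a (y, z) image. Raw values, no normalization.
#'
#' @param v a \linkS4class{VolumeImage} or 3D array.
#' @param angle 0 or 270.
#' @return A numeric matrix.
#' @examples
#' parallelProject(array(1, c(4, 4, 4)), 0)  # all ones
#' @export
parallelProject <- function(v, angle) {
  a <- if (is(v, "VolumeImage")) volData(v) else v
  stopifnot(length(dim(a)) == 3L)
  .projectArray(a, angle)
}

#' Render the orthogonal DRR pair
#'
#' Projects at 0 and 270 degrees, resizes each image to the raster by
#' separable bilinear interpolation, then min-max normalizes each image
#' independently to [0, 1].
#'
#' @param v a \linkS4class{VolumeImage} or 3D array (HU or normalized; the
#'   projection is domain-agnostic).
#' @param raster integer(2) output raster (default 128 x 128).
#' @param pixelSpacing pixel spacing stamped on the result.
#' @return A \linkS4class{ProjectionPair}.
#' @export
renderPair <- function(v, raster = c(128L, 128L),
                       pixelSpacing = c(1.98, 1.98)) {
  a <- if (is(v, "VolumeImage")) volData(v) else v
  stopifnot(length(dim(a)) == 3L)
  p0 <- .minmax01(.resizeMatrixImg(.projectArray(a, 0), raster))
  p270 <- .minmax01(.resizeMatrixImg(.projectArray(a, 270), raster))
  projectionPair(p0, p270, pixelSpacing)
}

# Differentiable twin of renderPair on an autodiff node holding a 3D array.
# Identical numerics: projection (adMeanAxis), separable resize (adAxisMat on
# a temporary 4D view), then min-max normalization through select nodes, so
# gradients flow through the extremes as well.
adRenderImage <- function(vnode, angle, raster) {
  axis <- if (angle == 0) 2L else 1L
  proj <- adMeanAxis(vnode, axis)                       # 2D matrix node
  d <- dim(proj$value)
  p4 <- adReshape(proj, c(d[1], d[2], 1L, 1L))
  p4 <- adAxisMat(p4, interpMatrix(raster[1], d[1]), 1L)
  p4 <- adAxisMat(p4, interpMatrix(raster[2], d[2]), 2L)
  img <- adReshape(p4, c(raster[1], raster[2]))
  imin <- which.min(img$value)
  imax <- which.max(img$value)
  if (img$value[imax] == img$value[imin])
    return(adTimes(img, 0))
  mn <- adSelect(img, imin)
  rng <- adMinus(adSelect(img, imax), mn)
  adOver(adMinus(img, mn), rng)
}

adRenderPair <- function(vnode, raster) {
  list(img0 = adRenderImage(vnode, 0, raster),
       img270 = adRenderImage(vnode, 270, raster))
}

#' Differentiable DRR rendering
#'
#' Same numerics as \code{\link{renderPair}} but evaluated through the
#' package's autodiff tape, so the gradient of any scalar of the projections
#' with respect to the input voxels is defined (including through the
#' min/max normalization, whose extremes are differentiated as selections).
#' Mainly used inside the DRR-consistency loss; exposed for gradient checks.
#'
#' @param v 3D array.
#' @param raster integer(2).
#' @param lossFn function mapping the two image nodes to a scalar node; the
#'   default is the mean of both images.
#' @return List with \code{pair} (a \linkS4class{ProjectionPair}),
#'   \code{value} (the scalar) and \code{grad} (array like \code{v}).
#' @export
differentiableProject <- function(v, raster = dim(v)[c(1, 3)],
                                  lossFn = NULL) {
  stopifnot(length(dim(v)) == 3L)
  adTapeBegin()
  vn <- adNode(v, track = TRUE)
  pr <- adRenderPair(vn, raster)
  s <- if (is.null(lossFn))
    adTimes(adPlus(adMean(pr$img0), adMean(pr$img270)), 0.5)
  else lossFn(pr$img0, pr$img270)
  adBackward(s)
  list(pair = projectionPair(pr$img0$value, pr$img270$value),
       value = s$value,
       grad = vn$grad %||% array(0, dim(v)))
}
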