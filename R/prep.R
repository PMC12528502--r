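# Phase-2 preprocessing: intensity truncation + per-case min-max
# normalization, central cropping, paired augmentation, unified structure
# mask construction and NIfTI I/O.
#
# Coordinate convention: 1-based voxel indices on axes (x = left-right,
# y = anterior-posterior, z = superior-inferior); crop windows are computed
# with floor division for odd margins.

#' Truncate to [-1000, 2000] HU and min-max normalize per case
#'
#' Clips a HU-domain volume to the CT calibration window \code{[-1000, 2000]}
#' HU, then rescales it to \code{[0, 1]} by its own post-clip minimum and
#' maximum. The (min, max) pair is stored on the result so HU-domain
#' evaluation can invert the mapping (\code{\link{denormalizeVolume}}).
#' A volume that is constant after clipping yields all zeros with a warning.
#'
#' @param v a HU-domain \linkS4class{VolumeImage}.
#' @return A normalized \linkS4class{VolumeImage} with \code{normRange} set.
#' @examples
#' v <- volumeImage(array(c(-2000, -1000, 500, 3000), c(4, 1, 1)))
#' volData(truncateNormalize(v))  # 0, 0, 0.5, 1
#' @export
truncateNormalize <- function(v) {
  stopifnot(is(v, "VolumeImage"))
  if (intensityDomain(v) != "HU")
    stop("truncateNormalize expects a HU-domain volume, got ",
         intensityDomain(v))
  d <- pmin(pmax(volData(v), -1000), 2000)
  mn <- min(d); mx <- max(d)
  if (mx == mn) {
    warning("constant volume after truncation; returning zeros")
    return(volumeImage(array(0, dim(d)), spacing = voxelSpacing(v),
                       domain = "normalized01", normRange = c(mn, mx)))
  }
  volumeImage((d - mn) / (mx - mn), spacing = voxelSpacing(v),
              domain = "normalized01", normRange = c(mn, mx))
}

#' @describeIn truncateNormalize invert the per-case normalization back to HU
#'   using the recorded (min, max) range.
#' @param normRange optionally override the recorded range (e.g. to map a
#'   synthetic volume through its ground truth's range).
#' @export
denormalizeVolume <- function(v, normRange = NULL) {
  stopifnot(is(v, "VolumeImage"))
  if (intensityDomain(v) != "normalized01")
    stop("denormalizeVolume expects a normalized volume")
  r <- if (is.null(normRange)) v@normRange else normRange
  if (anyNA(r)) stop("no normalization range recorded for this volume")
  volumeImage(volData(v) * (r[2] - r[1]) + r[1], spacing = voxelSpacing(v),
              domain = "HU")
}

.centerCropArray <- function(a, target) {
  d <- dim(a)
  stopifnot(length(target) == length(d))
  if (any(target > d))
    stop("crop target exceeds input shape (",
         paste(target, collapse = "x"), " > ", paste(d, collapse = "x"), ")")
  start <- (d - target) %/% 2L
  idx <- lapply(seq_along(d), function(k) start[k] + seq_len(target[k]))
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

#' Central crop of a volume
#'
#' Extracts the centered \code{targetShape} window (floor division for odd
#' margins), e.g. 256x256x64 to 128x128x64 keeps 0-based indices
#' \code{[64, 192)} on the first two axes.
#'
#' @param v a \linkS4class{VolumeImage} (or plain 3D array).
#' @param targetShape integer(3).
#' @return Same type as the input, cropped.
#' @export
centerCrop <- function(v, targetShape) {
  targetShape <- as.integer(targetShape)
  if (is(v, "VolumeImage"))
    volumeImage(.centerCropArray(volData(v), targetShape),
                spacing = voxelSpacing(v), domain = intensityDomain(v),
                normRange = normRange(v))
  else .centerCropArray(v, targetShape)
}

#' Central-region binary mask
#'
#' Ones exactly inside the centered \code{coreShape} box, zeros elsewhere.
#' The default core for a \code{(X, Y, Z)} grid is \code{(X, Y/2, Z)}: the
#' full left-right and superior-inferior extent but only the central half in
#' the anterior-posterior direction, which confines attention to the
#' treatment region and discards e.g. the femoral heads.
#'
#' @param shape integer(3) grid shape.
#' @param coreShape integer(3) core box; default \code{c(X, Y/2, Z)}.
#' @return Binary 3D array.
#' @examples
#' sum(centralRegionMask(c(128, 128, 64)))  # 128*64*64
#' @export
centralRegionMask <- function(shape, coreShape = NULL) {
  shape <- as.integer(shape)
  if (is.null(coreShape)) coreShape <- c(shape[1], shape[2] %/% 2L, shape[3])
  coreShape <- as.integer(coreShape)
  if (any(coreShape > shape)) stop("core shape exceeds grid shape")
  m <- array(0, dim = shape)
  start <- (shape - coreShape) %/% 2L
  idx <- lapply(1:3, function(k) start[k] + seq_len(coreShape[k]))
  m[idx[[1]], idx[[2]], idx[[3]]] <- 1
  m
}

#' Sample augmentation parameters
#'
#' Draws a random integer translation within ±5 voxels per axis and an
#' in-plane (axial) rotation within ±4 degrees, the augmentation ranges used
#' for training.
#'
#' @param seed integer.
#' @param maxTranslate,maxRotate bounds (voxels / degrees).
#' @return A list of class \code{"augmentParams"} with \code{translation}
#'   (integer(3)), \code{rotationDeg} and \code{seed}.
#' @export
sampleAugmentParams <- function(seed, maxTranslate = 5L, maxRotate = 4) {
  withSeed(seed, augmentParams(
    translation = sample(seq(-maxTranslate, maxTranslate), 3, replace = TRUE),
    rotationDeg = runif(1, -maxRotate, maxRotate),
    seed = seed))
}

#' @describeIn sampleAugmentParams explicit constructor with bound checks
#' @param translation integer(3), each within ±5 voxels.
#' @param rotationDeg scalar, within ±4 degrees.
#' @export
augmentParams <- function(translation = c(0L, 0L, 0L), rotationDeg = 0,
                          seed = 0L) {
  translation <- as.integer(round(translation))
  if (length(translation) != 3L || any(abs(translation) > 5L))
    stop("translations are bounded by +/-5 voxels per axis")
  if (abs(rotationDeg) > 4)
    stop("rotations are bounded by +/-4 degrees")
  structure(list(translation = translation, rotationDeg = rotationDeg,
                 seed = as.integer(seed)),
            class = "augmentParams")
}

# Integer translation with constant fill.
.shiftArray <- function(a, t, fill) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    lo <- max(1L, 1L + t[k]); hi <- min(d[k], d[k] + t[k])
    if (lo > hi) return(out)
    dst[[k]] <- lo:hi
    src[[k]] <- (lo - t[k]):(hi - t[k])
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# In-plane (axial) rotation about the volume centre; per-slice resampling.
# interp = "bilinear" (images) or "nearest" (masks).
.rotateAxial <- function(a, deg, fill, interp = "bilinear") {
  if (deg == 0) return(a)
  d <- dim(a)
  th <- deg * pi / 180
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  gx <- matrix(seq_len(d[1]), d[1], d[2]) - cx
  gy <- matrix(rep(seq_len(d[2]), each = d[1]), d[1], d[2]) - cy
  # inverse mapping: source = R(-theta) * target
  sx <- cos(th) * gx + sin(th) * gy + cx
  sy <- -sin(th) * gx + cos(th) * gy + cy
  out <- array(fill, dim = d)
  if (interp == "nearest") {
    ix <- round(sx); iy <- round(sy)
    ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2]
    for (z in seq_len(d[3])) {
      sl <- matrix(fill, d[1], d[2])
      sl[ok] <- a[, , z][cbind(ix[ok], iy[ok])]
      out[, , z] <- sl
    }
  } else {
    x0 <- floor(sx); y0 <- floor(sy)
    fx <- sx - x0; fy <- sy - y0
    ok <- x0 >= 1 & x0 + 1 <= d[1] & y0 >= 1 & y0 + 1 <= d[2]
    w00 <- (1 - fx) * (1 - fy); w10 <- fx * (1 - fy)
    w01 <- (1 - fx) * fy; w11 <- fx * fy
    for (z in seq_len(d[3])) {
      sl <- matrix(fill, d[1], d[2])
      pz <- a[, , z]
      sl[ok] <- w00[ok] * pz[cbind(x0[ok], y0[ok])] +
        w10[ok] * pz[cbind(x0[ok] + 1, y0[ok])] +
        w01[ok] * pz[cbind(x0[ok], y0[ok] + 1)] +
        w11[ok] * pz[cbind(x0[ok] + 1, y0[ok] + 1)]
      out[, , z] <- sl
    }
  }
  out
}

#' Paired augmentation of a CBCT and its structure masks
#'
#' Applies one integer translation and one in-plane (axial) rotation to the
#' volume (bilinear interpolation, fill -1000 HU before normalization / 0
#' after) and identically to every mask (nearest-neighbour, re-binarized), so
#' the augmented anatomy and its delineations stay aligned.
#'
#' @param cbct a \linkS4class{VolumeImage}.
#' @param masks a \linkS4class{StructureMaskSet} aligned to \code{cbct}.
#' @param params an \code{\link{augmentParams}}.
#' @return List with augmented \code{cbct} and \code{masks}.
#' @export
augmentPair <- function(cbct, masks, params) {
  stopifnot(is(cbct, "VolumeImage"), is(masks, "StructureMaskSet"),
            inherits(params, "augmentParams"))
  if (!identical(dim(volData(cbct)), dim(masks@ptv)))
    stop("cbct and masks are not aligned")
  fill <- if (intensityDomain(cbct) == "HU") -1000 else 0
  tr <- params$translation
  vol <- .shiftArray(volData(cbct), tr, fill)
  vol <- .rotateAxial(vol, params$rotationDeg, fill, "bilinear")
  if (intensityDomain(cbct) == "normalized01")
    vol <- pmin(pmax(vol, 0), 1)
  outMasks <- lapply(c("ptv", "bladder", "rectum", "body"), function(nm) {
    m <- .shiftArray(structureMask(masks, nm), tr, 0)
    m <- .rotateAxial(m, params$rotationDeg, 0, "nearest")
    array(as.numeric(m >= 0.5), dim(m))
  })
  list(cbct = volumeImage(vol, spacing = voxelSpacing(cbct),
                          domain = intensityDomain(cbct),
                          normRange = normRange(cbct)),
       masks = structureMaskSet(ptv = outMasks[[1]], bladder = outMasks[[2]],
                                rectum = outMasks[[3]], body = outMasks[[4]]))
}

# One binary dilation step with the 26-connected 3x3x3 element, via shifted
# unions (no padding: the result is clipped to the volume bounds).
.dilate26 <- function(m) {
  d <- dim(m)
  out <- m
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    out <- pmax(out, .shiftArray(m, c(dx, dy, dz), 0))
  }
  out
}

#' Build the unified structure mask
#'
#' Union of the PTV, bladder and rectum masks, dilated by \code{dilationPx}
#' iterations of the 26-connected 3x3x3 structuring element to include edge
#' information around the clinically relevant region. Used only inside the
#' anatomically informed loss.
#'
#' @param masks a \linkS4class{StructureMaskSet}.
#' @param dilationPx non-negative integer (default 3).
#' @return Binary 3D array with attribute \code{dilationPx}.
#' @export
buildUnifiedMask <- function(masks, dilationPx = 3L) {
  stopifnot(is(masks, "StructureMaskSet"), dilationPx >= 0)
  u <- pmax(masks@ptv, masks@bladder, masks@rectum)
  if (sum(u) == 0) stop("all structure masks are empty")
  for (i in seq_len(dilationPx)) u <- .dilate26(u)
  attr(u, "dilationPx") <- as.integer(dilationPx)
  u
}

#' Multiply a volume by a binary mask
#'
#' @param v a \linkS4class{VolumeImage}.
#' @param m a binary array of the same shape.
#' @return The masked \linkS4class{VolumeImage}.
#' @export
applyMask <- function(v, m) {
  stopifnot(is(v, "VolumeImage"))
  if (!identical(dim(volData(v)), dim(m)))
    stop("mask shape does not match volume shape")
  volumeImage(volData(v) * m, spacing = voxelSpacing(v),
              domain = intensityDomain(v), normRange = normRange(v))
}

#' Read / write volumes as NIfTI
#'
#' Thin wrappers over \pkg{RNifti}: spacing travels in the header pixdim,
#' data round-trip within float32 precision. Only 3D payloads are accepted.
#'
#' @param path file path (\code{.nii} or \code{.nii.gz}).
#' @param domain intensity domain to stamp on the volume read.
#' @return \code{readVolume}: a \linkS4class{VolumeImage};
#'   \code{writeVolume}: the path, invisibly.
#' @export
readVolume <- function(path, domain = "HU") {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D NIfTI payload, got ", length(d), "D")
  volumeImage(array(as.numeric(img), d),
              spacing = RNifti::pixdim(img)[1:3], domain = domain)
}

#' @rdname readVolume
#' @param v a \linkS4class{VolumeImage} to write.
#' @export
writeVolume <- function(v, path) {
  stopifnot(is(v, "VolumeImage"))
  img <- RNifti::asNifti(volData(v))
  RNifti::pixdim(img) <- voxelSpacing(v)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}
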