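# The multi-component training loss.
#
# Components (all non-negative, all zero on identical inputs):
#   MAE            voxel mean absolute error,
#   PL             2.5D perceptual loss: feature-space MSE over all axial and
#                  all sagittal slices, averaged over slices and layers,
#   PL_DRR         perceptual loss between the input DRRs and the DRRs
#                  re-rendered from the synthetic volume,
#   PL_structures  perceptual loss after multiplying both volumes by the
#                  dilated unified structure mask.
# The total is the weighted sum alpha*MAE + beta*PL + gamma*PL_DRR +
# omega*PL_structures; the four published ablation settings are pure weight
# configurations (see lossPreset()).

.arr3 <- function(v) if (is(v, "VolumeImage")) volData(v) else v

.checkSameShape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("shape mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
}

#' Voxel mean absolute error
#'
#' @param s,c volumes (\linkS4class{VolumeImage} or arrays) of one shape.
#' @return Scalar mean of \eqn{|s - c|} over all voxels.
#' @export
maeLoss <- function(s, c) {
  a <- .arr3(s); b <- .arr3(c)
  .checkSameShape(a, b)
  mean(abs(a - b))
}

# Mean of a list of scalar nodes.
.adMeanScalars <- function(nodes) {
  acc <- nodes[[1]]
  if (length(nodes) > 1)
    for (k in 2:length(nodes)) acc <- adPlus(acc, nodes[[k]])
  adTimes(acc, 1 / length(nodes))
}

# 2D perceptual loss between two image nodes: feature-space MSE per layer,
# averaged over the selected layers.
.adPerceptual2D <- function(na, nb, spec) {
  fa <- adBackboneFeatures(adRGB(na), spec)
  fb <- adBackboneFeatures(adRGB(nb), spec)
  per <- lapply(seq_along(fa), function(k)
    adMean(adSquare(adMinus(fa[[k]], fb[[k]]))))
  .adMeanScalars(per)
}

# 2.5D perceptual loss between a tracked volume node and a constant volume.
.adPerceptual25D <- function(sNode, cArr, spec) {
  d <- dim(cArr)
  terms <- list()
  for (z in seq_len(d[3]))
    terms[[length(terms) + 1L]] <-
      .adPerceptual2D(adSlice(sNode, 3L, z), adConst(cArr[, , z]), spec)
  for (x in seq_len(d[1]))
    terms[[length(terms) + 1L]] <-
      .adPerceptual2D(adSlice(sNode, 1L, x), adConst(cArr[x, , ]), spec)
  .adMeanScalars(terms)
}

#' 2.5D perceptual loss between two volumes
#'
#' Feeds every axial and every sagittal slice of both volumes (pseudo-RGB
#' triplicated) through the feature backbone and averages the feature-space
#' MSE over slices and selected layers.
#'
#' @param s,c volumes of one shape, values in \code{[0, 1]}.
#' @param spec a \code{\link{featureExtractorSpec}}.
#' @return Scalar loss value.
#' @export
perceptualLoss <- function(s, c, spec = featureExtractorSpec()) {
  a <- .arr3(s); b <- .arr3(c)
  .checkSameShape(a, b)
  adTapeBegin()
  .adPerceptual25D(adConst(a), b, spec)$value
}

# DRR-consistency loss on nodes: render the synthetic volume's DRR pair and
# compare each angle perceptually against the input DRRs; average the angles.
.adPlDrr <- function(sNode, drr0, drr270, spec) {
  raster <- dim(drr0)
  pr <- adRenderPair(sNode, raster)
  .adMeanScalars(list(.adPerceptual2D(pr$img0, adConst(drr0), spec),
                      .adPerceptual2D(pr$img270, adConst(drr270), spec)))
}

#' DRR-consistency perceptual loss
#'
#' Renders the orthogonal DRR pair from the synthetic volume (differentiable
#' path, identical numerics to \code{\link{renderPair}}) and computes the 2D
#' perceptual loss against the input DRRs at both angles, averaged.
#'
#' @param s synthetic volume (\linkS4class{VolumeImage} or 3D array).
#' @param inputDrrs a \linkS4class{ProjectionPair}.
#' @param spec a \code{\link{featureExtractorSpec}}.
#' @return Scalar loss value.
#' @export
plDrr <- function(s, inputDrrs, spec = featureExtractorSpec()) {
  a <- .arr3(s)
  stopifnot(is(inputDrrs, "ProjectionPair"))
  adTapeBegin()
  .adPlDrr(adConst(a), projectionImage(inputDrrs, 0),
           projectionImage(inputDrrs, 270), spec)$value
}

#' Structure-masked perceptual loss
#'
#' Multiplies both volumes by the unified structure mask (excluding all
#' information outside the clinically relevant region) and applies the 2.5D
#' perceptual loss.
#'
#' @param s,c volumes of one shape.
#' @param umask binary unified mask (see \code{\link{buildUnifiedMask}}).
#' @param spec a \code{\link{featureExtractorSpec}}.
#' @return Scalar loss value.
#' @export
plStructures <- function(s, c, umask, spec = featureExtractorSpec()) {
  a <- .arr3(s); b <- .arr3(c)
  .checkSameShape(a, b)
  .checkSameShape(a, umask)
  if (sum(umask) == 0) stop("unified mask is empty")
  perceptualLoss(a * umask, b * umask, spec)
}

#' Anatomically informed total loss
#'
#' The weighted sum of the four components plus the unweighted component
#' breakdown. With \code{gamma = omega = 0} it reduces to the plain
#' MAE + perceptual combination; with weights (1, 0, 0, 0) it equals
#' \code{\link{maeLoss}} exactly.
#'
#' @param s,c synthetic and ground-truth volumes (normalized domain).
#' @param inputDrrs a \linkS4class{ProjectionPair} (the model input DRRs).
#' @param umask binary unified structure mask.
#' @param weights a \linkS4class{LossWeights}.
#' @param spec a \code{\link{featureExtractorSpec}}.
#' @return List with \code{total} and \code{components} (named numeric:
#'   \code{mae}, \code{pl}, \code{pl_drr}, \code{pl_structures}).
#' @export
alfTotal <- function(s, c, inputDrrs, umask, weights = lossPreset("ALF"),
                     spec = featureExtractorSpec()) {
  stopifnot(is(weights, "LossWeights"))
  comp <- c(mae = maeLoss(s, c),
            pl = perceptualLoss(s, c, spec),
            pl_drr = plDrr(s, inputDrrs, spec),
            pl_structures = plStructures(s, c, umask, spec))
  w <- weightVector(weights)
  list(total = sum(w * comp), components = comp)
}

# Training-time loss on an autodiff node: only components with positive
# weight are evaluated (the others are reported as NA in the breakdown).
adAlfLoss <- function(sNode, cArr, drr0, drr270, umask, weights, spec) {
  w <- weightVector(weights)
  terms <- list()
  comp <- c(mae = NA_real_, pl = NA_real_, pl_drr = NA_real_,
            pl_structures = NA_real_)
  if (w[1] > 0) {
    nd <- adMean(adAbs(adMinus(sNode, adConst(cArr))))
    comp["mae"] <- nd$value
    terms <- c(terms, list(adTimes(nd, w[1])))
  }
  if (w[2] > 0) {
    nd <- .adPerceptual25D(sNode, cArr, spec)
    comp["pl"] <- nd$value
    terms <- c(terms, list(adTimes(nd, w[2])))
  }
  if (w[3] > 0) {
    nd <- .adPlDrr(sNode, drr0, drr270, spec)
    comp["pl_drr"] <- nd$value
    terms <- c(terms, list(adTimes(nd, w[3])))
  }
  if (w[4] > 0) {
    if (sum(umask) == 0) stop("unified mask is empty")
    sm <- adTimes(sNode, adConst(umask))
    nd <- .adPerceptual25D(sm, cArr * umask, spec)
    comp["pl_structures"] <- nd$value
    terms <- c(terms, list(adTimes(nd, w[4])))
  }
  acc <- terms[[1]]
  if (length(terms) > 1)
    for (k in 2:length(terms)) acc <- adPlus(acc, terms[[k]])
  list(node = acc, components = comp, weights = w)
}
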