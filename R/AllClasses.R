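#' @import methods
#' @importFrom stats rnorm runif sd setNames p.adjust pnorm shapiro.test
#'   kruskal.test
#' @importFrom utils head
#' @useDynLib OrthoCBCT, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' VolumeImage: a 3D scalar field with voxel spacing
#'
#' Carrier for planning CT (pCT), CBCT and synthetic CBCT volumes, either on
#' the calibrated Hounsfield-unit (HU) scale or min-max normalized to
#' \code{[0, 1]}. When a volume has been normalized, the original intensity
#' range is retained in \code{normRange} so that HU-domain evaluation metrics
#' can invert the normalization per case.
#'
#' @slot data 3D numeric array (x, y, z).
#' @slot spacing numeric(3), voxel spacing in mm.
#' @slot domain \code{"HU"} or \code{"normalized01"}.
#' @slot normRange numeric(2), the (min, max) HU values recorded at
#'   normalization time; \code{c(NA, NA)} for HU-domain volumes.
#' @exportClass VolumeImage
setClass("VolumeImage",
         representation(data = "array", spacing = "numeric",
                        domain = "character", normRange = "numeric"),
         prototype(spacing = c(1.98, 1.98, 3.0), domain = "HU",
                   normRange = c(NA_real_, NA_real_)))

setValidity("VolumeImage", function(object) {
  msg <- NULL
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values (mm)")
  if (!object@domain %in% c("HU", "normalized01"))
    msg <- c(msg, "domain must be 'HU' or 'normalized01'")
  if (object@domain == "normalized01") {
    rng <- range(object@data)
    if (rng[1] < -1e-8 || rng[2] > 1 + 1e-8)
      msg <- c(msg, "normalized01 volumes must lie in [0, 1]")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a VolumeImage
#'
#' @param data 3D numeric array.
#' @param spacing voxel spacing in mm, length 3.
#' @param domain intensity domain, \code{"HU"} (default) or
#'   \code{"normalized01"}.
#' @param normRange recorded (min, max) used for normalization, if any.
#' @return A \linkS4class{VolumeImage}.
#' @examples
#' v <- volumeImage(array(0, c(8, 8, 4)))
#' dim(volData(v))
#' @export
volumeImage <- function(data, spacing = c(1.98, 1.98, 3.0), domain = "HU",
                        normRange = c(NA_real_, NA_real_)) {
  new("VolumeImage", data = data, spacing = as.numeric(spacing),
      domain = domain, normRange = as.numeric(normRange))
}

#' @describeIn volumeImage voxel array accessor
#' @param x a VolumeImage
#' @export
volData <- function(x) x@data

#' @describeIn volumeImage voxel spacing (mm) accessor
#' @export
voxelSpacing <- function(x) x@spacing

#' @describeIn volumeImage intensity-domain accessor
#' @export
intensityDomain <- function(x) x@domain

#' @describeIn volumeImage recorded normalization range accessor
#' @export
normRange <- function(x) x@normRange

setMethod("show", "VolumeImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("VolumeImage %dx%dx%d voxels, spacing %.2fx%.2fx%.2f mm, %s\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3], object@domain))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(object@data), max(object@data)))
})

#' StructureMaskSet: binary radiotherapy structure masks
#'
#' Binary (0/1) masks for the planning target volume (PTV) and organs at risk
#' (bladder, rectum) plus the external body contour, all aligned to one
#' \linkS4class{VolumeImage} grid.
#'
#' @slot ptv,bladder,rectum,body 3D arrays with values in \{0, 1\}.
#' @exportClass StructureMaskSet
setClass("StructureMaskSet",
         representation(ptv = "array", bladder = "array",
                        rectum = "array", body = "array"))

setValidity("StructureMaskSet", function(object) {
  msg <- NULL
  d <- dim(object@ptv)
  for (nm in c("ptv", "bladder", "rectum", "body")) {
    m <- slot(object, nm)
    if (!identical(dim(m), d))
      msg <- c(msg, sprintf("mask '%s' shape differs from ptv", nm))
    if (!all(m %in% c(0, 1)))
      msg <- c(msg, sprintf("mask '%s' is not binary", nm))
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a StructureMaskSet
#'
#' @param ptv,bladder,rectum,body binary 3D arrays of one shape.
#' @return A \linkS4class{StructureMaskSet}.
#' @export
structureMaskSet <- function(ptv, bladder, rectum, body) {
  new("StructureMaskSet", ptv = ptv, bladder = bladder,
      rectum = rectum, body = body)
}

#' @describeIn structureMaskSet extract one mask by name
#' @param x a StructureMaskSet
#' @param name one of \code{"ptv"}, \code{"bladder"}, \code{"rectum"},
#'   \code{"body"}
#' @export
structureMask <- function(x, name) {
  stopifnot(name %in% c("ptv", "bladder", "rectum", "body"))
  slot(x, name)
}

setMethod("show", "StructureMaskSet", function(object) {
  d <- dim(object@ptv)
  cat(sprintf("StructureMaskSet on %dx%dx%d grid\n", d[1], d[2], d[3]))
  for (nm in c("ptv", "bladder", "rectum", "body"))
    cat(sprintf("  %-8s %d voxels\n", nm, sum(slot(object, nm))))
})

#' ProjectionPair: orthogonal 2D projections
#'
#' Two digitally reconstructed radiographs (DRRs) at gantry angles 0 degrees
#' (anterior) and 270 degrees (left lateral), min-max normalized to
#' \code{[0, 1]} on a common raster.
#'
#' @slot img0deg,img270deg numeric matrices sharing one raster.
#' @slot pixelSpacing numeric(2), pixel spacing in mm.
#' @exportClass ProjectionPair
setClass("ProjectionPair",
         representation(img0deg = "matrix", img270deg = "matrix",
                        pixelSpacing = "numeric"),
         prototype(pixelSpacing = c(1.98, 1.98)))

setValidity("ProjectionPair", function(object) {
  msg <- NULL
  if (!identical(dim(object@img0deg), dim(object@img270deg)))
    msg <- c(msg, "both projections must share one raster")
  if (length(object@pixelSpacing) != 2L || any(object@pixelSpacing <= 0))
    msg <- c(msg, "pixelSpacing must be 2 positive values")
  if (is.null(msg)) TRUE else msg
})

#' Construct a ProjectionPair
#' @param img0deg,img270deg projection matrices (anterior / lateral view).
#' @param pixelSpacing pixel spacing in mm.
#' @return A \linkS4class{ProjectionPair}.
#' @export
projectionPair <- function(img0deg, img270deg, pixelSpacing = c(1.98, 1.98)) {
  new("ProjectionPair", img0deg = img0deg, img270deg = img270deg,
      pixelSpacing = as.numeric(pixelSpacing))
}

#' @describeIn projectionPair extract one projection image
#' @param x a ProjectionPair
#' @param angle 0 or 270
#' @export
projectionImage <- function(x, angle) {
  if (angle == 0) x@img0deg
  else if (angle == 270) x@img270deg
  else stop("only gantry angles 0 and 270 are defined")
}

setMethod("show", "ProjectionPair", function(object) {
  d <- dim(object@img0deg)
  cat(sprintf("ProjectionPair %dx%d raster, %.2fx%.2f mm/px\n",
              d[1], d[2], object@pixelSpacing[1], object@pixelSpacing[2]))
})

#' PhantomCase: one simulated patient
#'
#' A planning volume with its structure delineations plus per-fraction
#' CBCT-like volumes (each with the anatomy state that generated it and its
#' own deformed masks).
#'
#' @slot caseId character id.
#' @slot pct the planning \linkS4class{VolumeImage} (HU).
#' @slot masks \linkS4class{StructureMaskSet} on the planning anatomy.
#' @slot fractions list; each element has \code{cbct}, \code{masks},
#'   \code{state}.
#' @slot spec the generating phantom specification (list).
#' @exportClass PhantomCase
setClass("PhantomCase",
         representation(caseId = "character", pct = "VolumeImage",
                        masks = "StructureMaskSet", fractions = "list",
                        spec = "list"))

setValidity("PhantomCase", function(object) {
  msg <- NULL
  d <- dim(object@pct@data)
  if (!identical(dim(object@masks@ptv), d))
    msg <- c(msg, "masks must share the pct grid")
  if (sum(object@masks@body) == 0)
    msg <- c(msg, "body mask is empty")
  if (any(object@masks@ptv > object@masks@body))
    msg <- c(msg, "PTV must be contained in the body")
  for (fr in object@fractions)
    if (!identical(dim(fr$cbct@data), d))
      msg <- c(msg, "all fraction volumes must share the pct grid")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "PhantomCase", function(object) {
  cat(sprintf("PhantomCase '%s': %s grid, %d fraction(s)\n", object@caseId,
              paste(dim(object@pct@data), collapse = "x"),
              length(object@fractions)))
})

#' PhantomCase accessors
#'
#' @param x a \linkS4class{PhantomCase}
#' @return \code{caseId}: the id string; \code{planningVolume}: the planning
#'   \linkS4class{VolumeImage}; \code{planningMasks}: the
#'   \linkS4class{StructureMaskSet}; \code{fractions}: the per-fraction list.
#' @name phantomCaseAccessors
#' @export
caseId <- function(x) x@caseId

#' @rdname phantomCaseAccessors
#' @export
planningVolume <- function(x) x@pct

#' @rdname phantomCaseAccessors
#' @export
planningMasks <- function(x) x@masks

#' @rdname phantomCaseAccessors
#' @export
fractions <- function(x) x@fractions

#' LossWeights: the four weighting factors of the anatomically informed loss
#'
#' Weights of the multi-component training loss
#' \eqn{L = \alpha\,MAE + \beta\,PL + \gamma\,PL_{DRR} + \omega\,PL_{structures}}.
#' The four published ablation configurations are pure settings of these
#' scalars (see \code{\link{lossPreset}}).
#'
#' @slot alpha,beta,gamma,omega non-negative scalars.
#' @exportClass LossWeights
setClass("LossWeights",
         representation(alpha = "numeric", beta = "numeric",
                        gamma = "numeric", omega = "numeric"))

setValidity("LossWeights", function(object) {
  w <- c(object@alpha, object@beta, object@gamma, object@omega)
  if (any(w < 0)) return("loss weights must be non-negative")
  if (all(w == 0)) return("at least one loss weight must be positive")
  TRUE
})

#' Construct LossWeights
#'
#' @param alpha weight of the voxel mean-absolute-error term.
#' @param beta weight of the 2.5D perceptual term.
#' @param gamma weight of the DRR-consistency perceptual term.
#' @param omega weight of the structure-masked perceptual term.
#' @return A \linkS4class{LossWeights}.
#' @examples
#' lossPreset("ALF")
#' @export
lossWeights <- function(alpha = 1, beta = 0.05, gamma = 0.01, omega = 0.04) {
  new("LossWeights", alpha = alpha, beta = beta, gamma = gamma, omega = omega)
}

#' @describeIn lossWeights the four published ablation configurations:
#'   \code{"onlyMAE"} (1,0,0,0), \code{"onlyPL"} (0,1,0,0), \code{"MAE&PL"}
#'   (1,0.02,0,0) and \code{"ALF"} (1,0.05,0.01,0.04).
#' @param name preset name.
#' @export
lossPreset <- function(name = c("ALF", "onlyMAE", "onlyPL", "MAE&PL")) {
  name <- match.arg(name)
  switch(name,
         "onlyMAE" = lossWeights(1, 0, 0, 0),
         "onlyPL"  = lossWeights(0, 1, 0, 0),
         "MAE&PL"  = lossWeights(1, 0.02, 0, 0),
         "ALF"     = lossWeights(1, 0.05, 0.01, 0.04))
}

#' @describeIn lossWeights weights as a named numeric vector
#' @param x a LossWeights object
#' @export
weightVector <- function(x)
  c(alpha = x@alpha, beta = x@beta, gamma = x@gamma, omega = x@omega)

setMethod("show", "LossWeights", function(object) {
  cat(sprintf("LossWeights alpha=%g beta=%g gamma=%g omega=%g\n",
              object@alpha, object@beta, object@gamma, object@omega))
})

#' ComparisonResult: statistical comparison of loss configurations
#'
#' Result of the non-parametric comparison pipeline: Shapiro-Wilk normality
#' screen per group, Kruskal-Wallis omnibus test, then Dunn's pairwise test
#' with Bonferroni correction and the usual star coding.
#'
#' @slot groups group labels.
#' @slot normalityP named numeric, Shapiro-Wilk p per group.
#' @slot omnibusP Kruskal-Wallis p-value.
#' @slot pairwiseP symmetric matrix of Bonferroni-adjusted Dunn p-values.
#' @slot rawP symmetric matrix of unadjusted Dunn p-values.
#' @slot stars character matrix (\code{"***"}, \code{"**"}, \code{"*"},
#'   \code{"n.s."}).
#' @exportClass ComparisonResult
setClass("ComparisonResult",
         representation(groups = "character", normalityP = "numeric",
                        omnibusP = "numeric", pairwiseP = "matrix",
                        rawP = "matrix", stars = "matrix"))

setValidity("ComparisonResult", function(object) {
  msg <- NULL
  if (!isTRUE(all.equal(object@pairwiseP, t(object@pairwiseP))))
    msg <- c(msg, "pairwise p matrix must be symmetric")
  if (isTRUE(any(object@pairwiseP < object@rawP - 1e-12, na.rm = TRUE)))
    msg <- c(msg, "adjusted p must be >= raw p")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "ComparisonResult", function(object) {
  cat("ComparisonResult\n")
  cat(sprintf("  omnibus (Kruskal-Wallis) p = %.4g\n", object@omnibusP))
  cat("  pairwise (Dunn, Bonferroni-adjusted):\n")
  print(signif(object@pairwiseP, 3))
})
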