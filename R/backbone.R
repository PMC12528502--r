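# Perceptual feature backbone.
#
# The perceptual losses and cLPIPS read features at selected layer indices
# of a VGG19-layout CNN (conv/ReLU stacks with 2x2 max pooling at the usual
# positions; layer indices follow the torchvision feature numbering, so ids
# 3, 8, 15, 22 are the ReLU outputs of the second conv in blocks 1-4). The
# default backbone carries deterministic, seeded Kaiming-uniform random
# weights: random-feature perceptual losses are a recognized stand-in for
# pretrained ones, are fully reproducible offline, and every structural
# property of the loss holds for any backbone.

.bbCache <- new.env(parent = emptyenv())

#' Feature extractor specification
#'
#' @param backbone only \code{"seeded_random_cnn"} is available in this
#'   package; requesting \code{"pretrained_vgg19"} raises an error pointing
#'   here (pretrained weights are an external download, not a dependency).
#' @param layerIds strictly increasing feature layer indices (default
#'   3, 8, 15, 22 in the VGG19 feature numbering).
#' @param seed integer seed for the backbone weights.
#' @param baseChannels channels of the first block; later blocks double
#'   (default 4, i.e. schedule 4-8-16-32; the classical VGG19 uses 64).
#' @return A list of class \code{"featureExtractorSpec"}.
#' @export
featureExtractorSpec <- function(backbone = "seeded_random_cnn",
                                 layerIds = c(3L, 8L, 15L, 22L),
                                 seed = 7L, baseChannels = 4L) {
  if (backbone == "pretrained_vgg19")
    stop("pretrained VGG19 weights are not bundled; use the seeded ",
         "random-weight backbone (backbone = 'seeded_random_cnn')")
  if (backbone != "seeded_random_cnn")
    stop("unknown backbone: ", backbone)
  layerIds <- as.integer(layerIds)
  if (any(diff(layerIds) <= 0)) stop("layerIds must be strictly increasing")
  if (max(layerIds) > 26L)
    stop("layer id ", max(layerIds), " beyond backbone depth (26)")
  structure(list(backbone = backbone, layerIds = layerIds,
                 seed = as.integer(seed),
                 baseChannels = as.integer(baseChannels)),
            class = "featureExtractorSpec")
}

# VGG19 feature-stack layout up to index 26: (index, kind, block).
.vggLayout <- function() {
  conv <- c(0, 2, 5, 7, 10, 12, 14, 16, 19, 21, 23, 25)
  pool <- c(4, 9, 18)
  blockOf <- function(i) if (i < 4) 1L else if (i < 9) 2L else if (i < 18) 3L else 4L
  list(conv = conv, pool = pool, blockOf = blockOf)
}

.kaimingUniform <- function(dims, fanIn, gain = sqrt(2)) {
  bound <- gain * sqrt(3 / fanIn)
  array(runif(prod(dims), -bound, bound), dim = dims)
}

# Build (and cache) the backbone weights for a spec.
.backboneWeights <- function(spec) {
  key <- paste0("s", spec$seed, "b", spec$baseChannels)
  if (!is.null(.bbCache[[key]])) return(.bbCache[[key]])
  lay <- .vggLayout()
  chans <- spec$baseChannels * c(1L, 2L, 4L, 8L)
  ws <- withSeed(spec$seed, {
    res <- list()
    cin <- 3L
    for (ci in lay$conv) {
      cout <- chans[lay$blockOf(ci)]
      fanIn <- 3 * 3 * cin
      res[[as.character(ci)]] <-
        list(w = .kaimingUniform(c(3L, 3L, 1L, cin, cout), fanIn),
             b = runif(cout, -1 / sqrt(fanIn), 1 / sqrt(fanIn)))
      cin <- cout
    }
    res
  })
  .bbCache[[key]] <- ws
  ws
}

# Run the backbone on a (H, W, 1, 3) input node; returns the feature nodes
# captured at the spec's layer ids.
adBackboneFeatures <- function(xnode, spec) {
  ws <- .backboneWeights(spec)
  lay <- .vggLayout()
  captured <- vector("list", length(spec$layerIds))
  names(captured) <- as.character(spec$layerIds)
  cur <- xnode
  maxId <- max(spec$layerIds)
  i <- 0L
  while (i <= maxId) {
    if (i %in% lay$conv) {
      wb <- ws[[as.character(i)]]
      cur <- adConv3d(cur, adConst(wb$w), adConst(wb$b),
                      stride = c(1L, 1L, 1L), pad = c(1L, 1L, 0L))
      i <- i + 1L
      cur <- adRelu(cur)                     # relu at index i
      if (as.character(i) %in% names(captured))
        captured[[as.character(i)]] <- cur
      i <- i + 1L
    } else if (i %in% lay$pool) {
      d <- dim(cur$value)
      if (d[1] < 2 || d[2] < 2)
        stop("input raster below backbone minimum for the requested layers")
      cur <- adMaxPool2(cur)
      i <- i + 1L
    } else i <- i + 1L
  }
  captured
}

#' Extract backbone features from a 2D image
#'
#' Triplicates a single-channel image in \code{[0, 1]} to a pseudo-RGB input
#' and captures the feature maps at the specification's layer ids. With the
#' default ids the four maps halve in spatial size at each pooling stage.
#'
#' @param img2d numeric matrix in \code{[0, 1]}.
#' @param spec a \code{\link{featureExtractorSpec}}.
#' @return List of 4D feature arrays (H, W, 1, C), one per layer id.
#' @export
extractFeatures <- function(img2d, spec = featureExtractorSpec()) {
  stopifnot(is.matrix(img2d))
  adTapeBegin()
  feats <- adBackboneFeatures(adRGB(adConst(img2d)), spec)
  lapply(feats, function(f) f$value)
}
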