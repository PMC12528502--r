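# The dual-branch encoder-decoder network family.
#
# One implementation realizes four variants by switching flags:
#   drrs_only        2D encoder only; the decoder is seeded from the
#                    reshaped 2D latent (no 3D encoder, no skips),
#   fusion           adds the 3D planning-CT encoder and the latent fusion,
#   fusion_skip      adds encoder-to-decoder skip concatenations,
#   fusion_skip_res  adds residual connections around the decoder conv
#                    stacks (1x1x1 projection on the identity path when the
#                    channel counts differ).
#
# Encoder blocks: conv(stride 2) -> instance norm -> ReLU -> conv(stride 1);
# channels double per level from baseChannels. The two DRRs enter as two
# input channels of one 2D encoder. The 2D latent is reshaped to the 3D
# latent's spatial dims by splitting its channel axis into (depth, channels),
# concatenated with the 3D latent, and mapped by a 1x1x1 transform conv.
# Decoder blocks upsample trilinearly by 2, optionally concatenate the
# matching encoder skip, then run a stride-1 conv stack; the final 1x1x1
# conv plus sigmoid bounds the output to [0, 1].

.variantFlags <- function(variant) {
  list(use3d = variant != "drrs_only",
       skips = variant %in% c("fusion_skip", "fusion_skip_res"),
       res = variant == "fusion_skip_res")
}

#' Model configuration
#'
#' @param variant one of \code{"drrs_only"}, \code{"fusion"},
#'   \code{"fusion_skip"}, \code{"fusion_skip_res"}.
#' @param inShape3d 3D input (and output) grid, each axis divisible by
#'   \code{2^nLevels}.
#' @param inRaster2d square DRR raster fed to the 2D encoder; its first two
#'   latent dims must match the 3D latent's (x, y) dims, so it defaults to
#'   \code{inShape3d[1]} and must equal \code{inShape3d[1] == inShape3d[2]}.
#' @param baseChannels first-level channel count (doubles per level).
#' @param nLevels encoder/decoder depth.
#' @param latentFuseChannels channels of the fused latent (default: the top
#'   encoder channel count).
#' @return A list of class \code{"modelConfig"}.
#' @export
modelConfig <- function(variant = c("fusion_skip_res", "fusion_skip",
                                    "fusion", "drrs_only"),
                        inShape3d = c(128L, 128L, 64L),
                        inRaster2d = inShape3d[1],
                        baseChannels = 64L, nLevels = 4L,
                        latentFuseChannels = NULL) {
  variant <- match.arg(variant)
  inShape3d <- as.integer(inShape3d)
  stopifnot(length(inShape3d) == 3L, baseChannels >= 1L, nLevels >= 1L)
  if (any(inShape3d %% 2L^nLevels != 0L))
    stop("inShape3d must be divisible by 2^nLevels per axis")
  if (inRaster2d %% 2L^nLevels != 0L)
    stop("inRaster2d must be divisible by 2^nLevels")
  topC <- baseChannels * 2L^(nLevels - 1L)
  depth <- inShape3d[3] %/% 2L^nLevels
  if (topC %% depth != 0L)
    stop(sprintf(paste0("2D latent (%dx%dx%d channels) cannot be reshaped ",
                        "to the 3D latent grid (%dx%dx%d): channel count ",
                        "not divisible by depth %d"),
                 inRaster2d %/% 2L^nLevels, inRaster2d %/% 2L^nLevels, topC,
                 inShape3d[1] %/% 2L^nLevels, inShape3d[2] %/% 2L^nLevels,
                 inShape3d[3] %/% 2L^nLevels, depth))
  if (inRaster2d %/% 2L^nLevels != inShape3d[1] %/% 2L^nLevels ||
      inShape3d[1] != inShape3d[2])
    stop(sprintf(paste0("2D latent spatial dims (%d x %d) must match the 3D ",
                        "latent's first two dims (%d x %d)"),
                 inRaster2d %/% 2L^nLevels, inRaster2d %/% 2L^nLevels,
                 inShape3d[1] %/% 2L^nLevels, inShape3d[2] %/% 2L^nLevels))
  if (is.null(latentFuseChannels)) latentFuseChannels <- topC
  structure(list(variant = variant, inShape3d = inShape3d,
                 inRaster2d = as.integer(inRaster2d),
                 baseChannels = as.integer(baseChannels),
                 nLevels = as.integer(nLevels),
                 latentFuseChannels = as.integer(latentFuseChannels)),
            class = "modelConfig")
}

.makeParam <- function(name, dims, fanIn) {
  p <- new.env(parent = emptyenv())
  p$name <- name
  p$value <- array(0, dim = dims)
  p$grad <- array(0, dim = dims)
  p$fanIn <- fanIn
  p
}

.convParams <- function(params, name, k, cin, cout) {
  fanIn <- prod(k) * cin
  params[[paste0(name, "_w")]] <- .makeParam(paste0(name, "_w"),
                                             c(k, cin, cout), fanIn)
  params[[paste0(name, "_b")]] <- .makeParam(paste0(name, "_b"), cout, fanIn)
  params
}

# Channel schedule of encoder level i (1-based).
.encChannels <- function(cfg, i, inCh) {
  cin <- if (i == 1L) inCh else cfg$baseChannels * 2L^(i - 2L)
  cout <- cfg$baseChannels * 2L^(i - 1L)
  c(cin, cout)
}

# Decoder block l output channels (l = nLevels .. 1, deepest first).
.decOutChannels <- function(cfg, l) {
  if (l >= 2L) cfg$baseChannels * 2L^(l - 2L) else cfg$baseChannels
}

# Decoder block l input channels (before the conv stack, after upsample and
# optional skip concatenation).
.decInChannels <- function(cfg, l, flags) {
  upIn <- if (l == cfg$nLevels) cfg$latentFuseChannels
          else .decOutChannels(cfg, l + 1L)
  skipC <- if (flags$skips && l >= 2L) cfg$baseChannels * 2L^(l - 2L) else 0L
  upIn + skipC
}

#' Build a network model
#'
#' Allocates all parameters for the configured variant and initializes them
#' with the Kaiming-He uniform scheme (see \code{\link{initWeights}}).
#'
#' @param cfg a \code{\link{modelConfig}}.
#' @param seed integer seed for the weight initialization.
#' @return A list of class \code{"fusionModel"} with \code{cfg} and
#'   \code{params}.
#' @examples
#' m <- buildModel(modelConfig("fusion", inShape3d = c(32, 32, 16),
#'                             baseChannels = 4, nLevels = 2), seed = 1)
#' countParams(m)
#' @export
buildModel <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "modelConfig"))
  flags <- .variantFlags(cfg$variant)
  params <- list()
  k2 <- c(3L, 3L, 1L); k3 <- c(3L, 3L, 3L); k1 <- c(1L, 1L, 1L)
  for (i in seq_len(cfg$nLevels)) {
    ch <- .encChannels(cfg, i, 2L)
    params <- .convParams(params, sprintf("e2_l%d_a", i), k2, ch[1], ch[2])
    params <- .convParams(params, sprintf("e2_l%d_b", i), k2, ch[2], ch[2])
  }
  if (flags$use3d) {
    for (i in seq_len(cfg$nLevels)) {
      ch <- .encChannels(cfg, i, 1L)
      params <- .convParams(params, sprintf("e3_l%d_a", i), k3, ch[1], ch[2])
      params <- .convParams(params, sprintf("e3_l%d_b", i), k3, ch[2], ch[2])
    }
  }
  topC <- cfg$baseChannels * 2L^(cfg$nLevels - 1L)
  depth <- cfg$inShape3d[3] %/% 2L^cfg$nLevels
  fuseIn <- topC %/% depth + if (flags$use3d) topC else 0L
  params <- .convParams(params, "fuse", k1, fuseIn, cfg$latentFuseChannels)
  for (l in seq(cfg$nLevels, 1L)) {
    cin <- .decInChannels(cfg, l, flags)
    cout <- .decOutChannels(cfg, l)
    params <- .convParams(params, sprintf("d_l%d_a", l), k3, cin, cout)
    params <- .convParams(params, sprintf("d_l%d_b", l), k3, cout, cout)
    if (flags$res && cin != cout)
      params <- .convParams(params, sprintf("d_l%d_proj", l), k1, cin, cout)
  }
  params <- .convParams(params, "out", k1, cfg$baseChannels, 1L)
  model <- structure(list(cfg = cfg, params = params), class = "fusionModel")
  initWeights(model, seed)
}

#' Total number of trainable parameters
#' @param model a \code{"fusionModel"}.
#' @return Integer parameter count.
#' @export
countParams <- function(model)
  sum(vapply(model$params, function(p) length(p$value), 0))

.pnode <- function(model, name) adParam(model$params[[name]])

# Encoder block: conv(stride 2) -> instance norm -> ReLU -> conv(stride 1).
.adEncBlock <- function(model, prefix, x, k, s2, pad) {
  h <- adConv3d(x, .pnode(model, paste0(prefix, "_a_w")),
                .pnode(model, paste0(prefix, "_a_b")), stride = s2, pad = pad)
  h <- adRelu(adInstNorm(h))
  adConv3d(h, .pnode(model, paste0(prefix, "_b_w")),
           .pnode(model, paste0(prefix, "_b_b")),
           stride = c(1L, 1L, 1L), pad = pad)
}

.adUpsample2 <- function(x) {
  d <- dim(x$value)
  for (ax in 1:3)
    x <- adAxisMat(x, interpMatrix(2L * d[ax], d[ax]), ax)
  x
}

# Full forward pass on the tape; inputs are plain arrays.
.adForward <- function(model, drr0, drr270, pctArr) {
  cfg <- model$cfg
  flags <- .variantFlags(cfg$variant)
  r <- cfg$inRaster2d
  if (!identical(dim(drr0), c(r, r)) || !identical(dim(drr270), c(r, r)))
    stop("DRR raster does not match the model configuration (",
         r, "x", r, ")")
  x2 <- adConst(array(c(drr0, drr270), dim = c(r, r, 1L, 2L)))
  f2 <- x2
  for (i in seq_len(cfg$nLevels))
    f2 <- .adEncBlock(model, sprintf("e2_l%d", i), f2, NULL,
                      c(2L, 2L, 1L), c(1L, 1L, 0L))
  skips <- list()
  if (flags$use3d) {
    if (!identical(dim(pctArr), as.integer(cfg$inShape3d)))
      stop("pCT shape does not match the model configuration (",
           paste(cfg$inShape3d, collapse = "x"), ")")
    f3 <- adConst(array(pctArr, dim = c(dim(pctArr), 1L)))
    for (i in seq_len(cfg$nLevels)) {
      f3 <- .adEncBlock(model, sprintf("e3_l%d", i), f3, NULL,
                        c(2L, 2L, 2L), c(1L, 1L, 1L))
      skips[[i]] <- f3
    }
  }
  # reshape the 2D latent (h, w, 1, C) to (h, w, depth, C/depth)
  d2 <- dim(f2$value)
  depth <- cfg$inShape3d[3] %/% 2L^cfg$nLevels
  lat2 <- adReshape(f2, c(d2[1], d2[2], depth, d2[4] %/% depth))
  lat <- if (flags$use3d) adConcatC(lat2, skips[[cfg$nLevels]]) else lat2
  x <- adConv3d(lat, .pnode(model, "fuse_w"), .pnode(model, "fuse_b"))
  for (l in seq(cfg$nLevels, 1L)) {
    x <- .adUpsample2(x)
    if (flags$skips && l >= 2L) x <- adConcatC(x, skips[[l - 1L]])
    h <- .adEncBlock(model, sprintf("d_l%d", l), x, NULL,
                     c(1L, 1L, 1L), c(1L, 1L, 1L))
    if (flags$res) {
      pj <- sprintf("d_l%d_proj", l)
      idn <- if (!is.null(model$params[[paste0(pj, "_w")]]))
        adConv3d(x, .pnode(model, paste0(pj, "_w")),
                 .pnode(model, paste0(pj, "_b")))
      else x
      x <- adPlus(h, idn)
    } else x <- h
  }
  y <- adSigmoid(adConv3d(x, .pnode(model, "out_w"), .pnode(model, "out_b")))
  adReshape(y, cfg$inShape3d)
}

#' Synthesize a volume from a DRR pair and the planning CT
#'
#' Runs the network forward (no gradient bookkeeping is kept by the caller;
#' the pass is deterministic). The output shape equals the 3D input shape
#' for every variant; the sigmoid output layer bounds it to \code{[0, 1]}.
#'
#' @param model a \code{"fusionModel"}.
#' @param drrs a \linkS4class{ProjectionPair} on the model's raster.
#' @param pct planning volume (\linkS4class{VolumeImage} normalized to
#'   \code{[0, 1]}, or a 3D array). Ignored by the \code{drrs_only} variant
#'   but still required for a uniform call signature.
#' @return The synthetic volume as a normalized \linkS4class{VolumeImage}.
#' @export
predictVolume <- function(model, drrs, pct) {
  stopifnot(inherits(model, "fusionModel"), is(drrs, "ProjectionPair"))
  pctArr <- .arr3(pct)
  adTapeBegin()
  out <- .adForward(model, projectionImage(drrs, 0),
                    projectionImage(drrs, 270), pctArr)
  sp <- if (is(pct, "VolumeImage")) voxelSpacing(pct) else c(1.98, 1.98, 3.0)
  v <- pmin(pmax(out$value, 0), 1)
  adTapeBegin()   # release the graph
  volumeImage(v, spacing = sp, domain = "normalized01")
}

#' Run a single network block (inspection / verification helpers)
#'
#' \code{encBlock2dForward} and \code{encBlock3dForward} run one encoder
#' block (stride-2 conv, instance norm, ReLU, stride-1 conv; spatial dims
#' halve). \code{fuseForward} reshapes a 2D latent, concatenates the 3D
#' latent and applies the 1x1x1 transform conv. \code{decBlockForward} runs
#' one decoder block (trilinear x2 upsample, optional skip concatenation,
#' conv stack, residual addition for the residual variant).
#'
#' @param model a \code{"fusionModel"}.
#' @param level block level (1 = first encoder level / last decoder level).
#' @param x input feature array (H, W, 1, C) for 2D, (X, Y, Z, C) for 3D.
#' @param skip optional skip feature array for \code{decBlockForward}.
#' @return The block's output feature array.
#' @export
encBlock2dForward <- function(model, level, x) {
  d <- dim(x)
  if (any(d[1:2] %% 2L != 0L)) stop("spatial dims must be even")
  adTapeBegin()
  .adEncBlock(model, sprintf("e2_l%d", level), adConst(x), NULL,
              c(2L, 2L, 1L), c(1L, 1L, 0L))$value
}

#' @rdname encBlock2dForward
#' @export
encBlock3dForward <- function(model, level, x) {
  d <- dim(x)
  if (any(d[1:3] %% 2L != 0L)) stop("spatial dims must be even")
  adTapeBegin()
  .adEncBlock(model, sprintf("e3_l%d", level), adConst(x), NULL,
              c(2L, 2L, 2L), c(1L, 1L, 1L))$value
}

#' @rdname encBlock2dForward
#' @param f2d 2D latent array (h, w, 1, C2).
#' @param f3d 3D latent array (h, w, depth, C3) or NULL for drrs_only.
#' @export
fuseForward <- function(model, f2d, f3d = NULL) {
  cfg <- model$cfg
  d2 <- dim(f2d)
  depth <- if (is.null(f3d)) cfg$inShape3d[3] %/% 2L^cfg$nLevels
           else dim(f3d)[3]
  if (d2[4] %% depth != 0L)
    stop(sprintf("cannot reshape 2D latent %s to depth-%d 3D latent %s",
                 paste(d2, collapse = "x"), depth,
                 if (is.null(f3d)) "" else paste(dim(f3d), collapse = "x")))
  if (!is.null(f3d) && !all(d2[1:2] == dim(f3d)[1:2]))
    stop(sprintf("latent spatial dims differ: 2D %s vs 3D %s",
                 paste(d2, collapse = "x"), paste(dim(f3d), collapse = "x")))
  adTapeBegin()
  lat2 <- adReshape(adConst(f2d), c(d2[1], d2[2], depth, d2[4] %/% depth))
  lat <- if (is.null(f3d)) lat2 else adConcatC(lat2, adConst(f3d))
  adConv3d(lat, .pnode(model, "fuse_w"), .pnode(model, "fuse_b"))$value
}

#' @rdname encBlock2dForward
#' @export
decBlockForward <- function(model, level, x, skip = NULL) {
  flags <- .variantFlags(model$cfg$variant)
  adTapeBegin()
  xn <- .adUpsample2(adConst(x))
  if (!is.null(skip)) {
    if (!all(dim(xn$value)[1:3] == dim(skip)[1:3]))
      stop("skip feature shape does not match the upsampled input")
    xn <- adConcatC(xn, adConst(skip))
  } else if (flags$skips && level >= 2L)
    stop("this variant expects a skip input at level ", level)
  h <- .adEncBlock(model, sprintf("d_l%d", level), xn, NULL,
                   c(1L, 1L, 1L), c(1L, 1L, 1L))
  if (flags$res) {
    pj <- sprintf("d_l%d_proj", level)
    idn <- if (!is.null(model$params[[paste0(pj, "_w")]]))
      adConv3d(xn, .pnode(model, paste0(pj, "_w")),
               .pnode(model, paste0(pj, "_b")))
    else xn
    adPlus(h, idn)$value
  } else h$value
}
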