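# Reverse-mode automatic differentiation on a global tape.
#
# Nodes are environments holding $value (numeric array), $grad, $parents and
# $back (a function mapping the node's gradient to per-parent gradients).
# Batch size is one throughout, so feature maps are plain 4D arrays
# (X, Y, Z, C); 2D maps travel as (H, W, 1, C). Everything here is internal;
# the network, loss and projection modules are the public surface.

# The tape is a linked chain: every node keeps a pointer to the node created
# just before it, so reverse-creation order (a valid reverse topological
# order, since parents are always created first) is walked without any
# growing container.
.ad <- new.env(parent = emptyenv())
.ad$last <- NULL

adTapeBegin <- function() {
  .ad$last <- NULL
  invisible(NULL)
}

adNode <- function(value, parents = NULL, back = NULL, track = NA) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$parents <- parents
  n$back <- back
  n$param <- NULL
  if (is.na(track)) {
    track <- FALSE
    if (!is.null(parents))
      for (p in parents) if (isTRUE(p$track)) { track <- TRUE; break }
  }
  n$track <- track
  n$prev <- .ad$last
  .ad$last <- n
  n
}

isNode <- function(x) is.environment(x) && !is.null(x$value)

asNode <- function(x) {
  if (isNode(x)) x else adNode(x, track = FALSE)
}

adVal <- function(x) if (isNode(x)) x$value else x

# Leaf node for a trainable parameter environment (with $value, $grad).
adParam <- function(p) {
  n <- adNode(p$value, track = TRUE)
  n$param <- p
  n
}

adConst <- function(x) adNode(x, track = FALSE)

.addGrad <- function(node, g) {
  if (!isTRUE(node$track)) return(invisible(NULL))
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

# Backpropagate from a scalar node by walking the creation chain backwards;
# afterwards parameter gradients are accumulated into each leaf's $param$grad.
adBackward <- function(loss) {
  stopifnot(isNode(loss), length(loss$value) == 1L)
  loss$grad <- 1
  n <- loss
  while (!is.null(n)) {
    if (!is.null(n$grad)) {
      if (!is.null(n$param))
        n$param$grad <- n$param$grad + n$grad
      if (!is.null(n$back)) {
        gs <- n$back(n$grad, n)
        for (j in seq_along(n$parents)) {
          if (!is.null(gs[[j]])) .addGrad(n$parents[[j]], gs[[j]])
        }
      }
    }
    n <- n$prev
  }
  invisible(NULL)
}

.isScalar <- function(v) length(v) == 1L

.sumTo <- function(g, v) if (.isScalar(v)) sum(g) else g

## ---- elementwise arithmetic (with scalar broadcasting) ----

adPlus <- function(a, b) {
  a <- asNode(a); b <- asNode(b)
  adNode(a$value + b$value, parents = list(a, b),
         back = function(g, n)
           list(.sumTo(g, n$parents[[1]]$value),
                .sumTo(g, n$parents[[2]]$value)))
}

adMinus <- function(a, b) {
  a <- asNode(a); b <- asNode(b)
  adNode(a$value - b$value, parents = list(a, b),
         back = function(g, n)
           list(.sumTo(g, n$parents[[1]]$value),
                -.sumTo(g, n$parents[[2]]$value)))
}

adTimes <- function(a, b) {
  a <- asNode(a); b <- asNode(b)
  adNode(a$value * b$value, parents = list(a, b),
         back = function(g, n) {
           av <- n$parents[[1]]$value; bv <- n$parents[[2]]$value
           list(.sumTo(g * bv, av), .sumTo(g * av, bv))
         })
}

adOver <- function(a, b) {
  a <- asNode(a); b <- asNode(b)
  adNode(a$value / b$value, parents = list(a, b),
         back = function(g, n) {
           av <- n$parents[[1]]$value; bv <- n$parents[[2]]$value
           list(.sumTo(g / bv, av), .sumTo(-g * av / (bv * bv), bv))
         })
}

adAbs <- function(x) {
  x <- asNode(x)
  adNode(abs(x$value), parents = list(x),
         back = function(g, n) list(g * sign(n$parents[[1]]$value)))
}

adSquare <- function(x) {
  x <- asNode(x)
  adNode(x$value^2, parents = list(x),
         back = function(g, n) list(2 * g * n$parents[[1]]$value))
}

adMean <- function(x) {
  x <- asNode(x)
  nn <- length(x$value)
  adNode(mean(x$value), parents = list(x),
         back = function(g, n) {
           v <- n$parents[[1]]$value
           gr <- array(as.numeric(g) / length(v), dim = dim(v) %||% length(v))
           list(gr)
         })
  }

adSum <- function(x) {
  x <- asNode(x)
  adNode(sum(x$value), parents = list(x),
         back = function(g, n) {
           v <- n$parents[[1]]$value
           list(array(as.numeric(g), dim = dim(v) %||% length(v)))
         })
}

# Scalar element selection (used for differentiable min/max normalization).
adSelect <- function(x, i) {
  x <- asNode(x)
  adNode(x$value[i], parents = list(x),
         back = function(g, n) {
           v <- n$parents[[1]]$value
           gr <- array(0, dim = dim(v) %||% length(v))
           gr[i] <- g
           list(gr)
         })
}

## ---- activations and normalization ----

adRelu <- function(x) {
  x <- asNode(x)
  adNode(pmax(x$value, 0), parents = list(x),
         back = function(g, n) list(g * (n$parents[[1]]$value > 0)))
}

adSigmoid <- function(x) {
  x <- asNode(x)
  y <- 1 / (1 + exp(-x$value))
  n <- adNode(y, parents = list(x),
              back = function(g, n) list(g * n$aux * (1 - n$aux)))
  n$aux <- y
  n
}

# Instance normalization: per-channel standardization over spatial dims of a
# (d1,d2,d3,C) map; no learned affine (matching the reference formulation).
adInstNorm <- function(x, eps = 1e-5) {
  x <- asNode(x)
  v <- x$value
  d <- dim(v)
  m <- prod(d[1:3])
  mat <- matrix(v, nrow = m)                     # spatial x channels
  mu <- colMeans(mat)
  ctr <- sweep(mat, 2, mu)
  sd2 <- colMeans(ctr^2) + eps
  sdv <- sqrt(sd2)
  xhat <- sweep(ctr, 2, sdv, "/")
  n <- adNode(array(xhat, dim = d), parents = list(x),
              back = function(g, n) {
                d <- dim(n$parents[[1]]$value)
                m <- prod(d[1:3])
                gm <- matrix(g, nrow = m)
                xh <- n$aux$xhat
                t1 <- sweep(gm, 2, colMeans(gm))
                t2 <- sweep(xh, 2, colMeans(gm * xh), "*")
                gx <- sweep(t1 - t2, 2, n$aux$sdv, "/")
                list(array(gx, dim = d))
              })
  n$aux <- list(xhat = xhat, sdv = sdv)
  n
}

## ---- convolution / pooling ----

adConv3d <- function(x, w, b, stride = c(1L, 1L, 1L), pad = c(0L, 0L, 0L)) {
  x <- asNode(x); w <- asNode(w); b <- asNode(b)
  xd <- dim(x$value); wd <- dim(w$value)
  stopifnot(length(xd) == 4L, length(wd) == 5L, xd[4] == wd[4])
  y <- conv3d_fwd_cpp(x$value, as.integer(xd), w$value, as.integer(wd),
                      b$value, as.integer(stride), as.integer(pad))
  n <- adNode(y, parents = list(x, w, b),
              back = function(g, n) {
                px <- n$parents[[1]]; pw <- n$parents[[2]]
                xd <- dim(px$value); wd <- dim(pw$value)
                yd <- dim(n$value)
                gx <- NULL
                if (isTRUE(px$track))
                  gx <- conv3d_bwd_x_cpp(g, as.integer(yd), pw$value,
                                         as.integer(wd), as.integer(xd),
                                         n$aux$stride, n$aux$pad)
                if (isTRUE(pw$track)) {
                  gwb <- conv3d_bwd_w_cpp(px$value, as.integer(xd), g,
                                          as.integer(yd), as.integer(wd),
                                          n$aux$stride, n$aux$pad)
                  list(gx, gwb$gw, gwb$gb)
                } else list(gx, NULL, NULL)
              })
  n$aux <- list(stride = as.integer(stride), pad = as.integer(pad))
  n
}

adMaxPool2 <- function(x) {
  x <- asNode(x)
  xd <- dim(x$value)
  r <- maxpool2_fwd_cpp(x$value, as.integer(xd))
  n <- adNode(r$y, parents = list(x),
              back = function(g, n)
                list(maxpool2_bwd_cpp(g, n$aux$argmax,
                                      as.integer(dim(n$parents[[1]]$value)))))
  n$aux <- list(argmax = r$argmax)
  n
}

## ---- shape ops ----

adReshape <- function(x, dims) {
  x <- asNode(x)
  adNode(array(x$value, dim = dims), parents = list(x),
         back = function(g, n) {
           v <- n$parents[[1]]$value
           list(array(g, dim = dim(v) %||% length(v)))
         })
}

adConcatC <- function(a, b) {
  a <- asNode(a); b <- asNode(b)
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(length(da) == 4L, all(da[1:3] == db[1:3]))
  y <- array(c(a$value, b$value), dim = c(da[1:3], da[4] + db[4]))
  adNode(y, parents = list(a, b),
         back = function(g, n) {
           da <- dim(n$parents[[1]]$value)
           ka <- prod(da)
           list(array(g[seq_len(ka)], dim = da),
                array(g[-seq_len(ka)], dim = dim(n$parents[[2]]$value)))
         })
}

# Apply a matrix M (n_out x n_axis) along one of the first three axes of a
# 4D array; linear, so the backward pass is the transpose. Carries bilinear
# or trilinear interpolation when M holds interpolation weights.
.axisApply <- function(v, M, axis) {
  d <- dim(v)
  perm <- c(axis, setdiff(seq_len(4L), axis))
  vp <- aperm(v, perm)
  mat <- matrix(vp, nrow = d[axis])
  out <- M %*% mat
  dout <- d; dout[axis] <- nrow(M)
  vo <- array(out, dim = dout[perm])
  aperm(vo, order(perm))
}

adAxisMat <- function(x, M, axis) {
  x <- asNode(x)
  n <- adNode(.axisApply(x$value, M, axis), parents = list(x),
              back = function(g, n)
                list(.axisApply(g, t(n$aux$M), n$aux$axis)))
  n$aux <- list(M = M, axis = axis)
  n
}

# Mean along one axis of a plain 3D array node (the parallel projection).
adMeanAxis <- function(x, axis) {
  x <- asNode(x)
  d <- dim(x$value)
  stopifnot(length(d) == 3L)
  keep <- setdiff(1:3, axis)
  y <- apply(x$value, keep, mean)
  n <- adNode(y, parents = list(x),
              back = function(g, n) {
                d <- dim(n$parents[[1]]$value)
                ax <- n$aux$axis
                keep <- setdiff(1:3, ax)
                ge <- array(0, dim = d)
                gfull <- array(rep(g, times = d[ax]), dim = c(d[keep], d[ax]))
                ge <- aperm(gfull, order(c(keep, ax))) / d[ax]
                list(ge)
              })
  n$aux <- list(axis = axis)
  n
}

# Extract one 2D slice from a 3D array node.
adSlice <- function(x, axis, index) {
  x <- asNode(x)
  d <- dim(x$value)
  y <- switch(axis,
              x$value[index, , ],
              x$value[, index, ],
              x$value[, , index])
  n <- adNode(y, parents = list(x),
              back = function(g, n) {
                d <- dim(n$parents[[1]]$value)
                gr <- array(0, dim = d)
                switch(n$aux$axis,
                       gr[n$aux$index, , ] <- g,
                       gr[, n$aux$index, ] <- g,
                       gr[, , n$aux$index] <- g)
                list(gr)
              })
  n$aux <- list(axis = axis, index = index)
  n
}

# (H, W) matrix node -> (H, W, 1, 3) pseudo-RGB map (channel triplication).
adRGB <- function(x) {
  x <- asNode(x)
  d <- dim(x$value)
  y <- array(rep(x$value, 3L), dim = c(d[1], d[2], 1L, 3L))
  adNode(y, parents = list(x),
         back = function(g, n) {
           d <- dim(n$parents[[1]]$value)
           gm <- g[, , 1L, 1L] + g[, , 1L, 2L] + g[, , 1L, 3L]
           list(matrix(gm, d[1], d[2]))
         })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Linear interpolation matrix mapping n_in samples to n_out (half-pixel
# centre convention, the one used for image resizing without corner
# alignment); identity when n_out == n_in.
interpMatrix <- function(n_out, n_in) {
  M <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * n_in / n_out - 0.5
    i0 <- floor(src)
    t <- src - i0
    j0 <- min(max(i0, 0), n_in - 1)
    j1 <- min(max(i0 + 1, 0), n_in - 1)
    M[i, j0 + 1] <- M[i, j0 + 1] + (1 - t)
    M[i, j1 + 1] <- M[i, j1 + 1] + t
  }
  M
}
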