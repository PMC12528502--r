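# Independent brute-force oracles used to freeze expected values.

# Masked MAE by explicit loop.
oracle_mmae <- function(x, y, body) {
  acc <- 0; n <- 0
  for (i in which(body == 1)) { acc <- acc + abs(x[i] - y[i]); n <- n + 1 }
  acc / n
}

oracle_mpsnr <- function(x, y, body) {
  idx <- which(body == 1)
  mse <- mean((x[idx] - y[idx])^2)
  if (mse == 0) return(Inf)
  10 * log10(max(y)^2 / mse)
}

# Symmetric reflection padding, matching the package's boundary policy.
oracle_pad <- function(a, p) {
  d <- dim(a)
  ix <- lapply(d, function(n) c(rev(seq_len(p)), seq_len(n),
                                n - seq_len(p) + 1L))
  a[ix[[1]], ix[[2]], ix[[3]]]
}

# Masked SSIM by direct per-voxel window extraction (population moments).
oracle_mssim <- function(x, y, body, dataRange = max(y) - min(y),
                         win = 7L, k1 = 0.01, k2 = 0.03) {
  p <- (win - 1L) %/% 2L
  xp <- oracle_pad(x, p); yp <- oracle_pad(y, p)
  c1 <- (k1 * dataRange)^2; c2 <- (k2 * dataRange)^2
  d <- dim(x)
  vals <- c()
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (body[i, j, k] != 1) next
    wx <- xp[i:(i + 2 * p), j:(j + 2 * p), k:(k + 2 * p)]
    wy <- yp[i:(i + 2 * p), j:(j + 2 * p), k:(k + 2 * p)]
    mx <- mean(wx); my <- mean(wy)
    vx <- mean(wx^2) - mx^2; vy <- mean(wy^2) - my^2
    cxy <- mean(wx * wy) - mx * my
    vals <- c(vals, ((2 * mx * my + c1) * (2 * cxy + c2)) /
                ((mx^2 + my^2 + c1) * (vx + vy + c2)))
  }
  mean(vals)
}

# Binary dilation as a Chebyshev-ball reachability check: r iterations of
# the 26-connected cube reach exactly max-norm distance r.
oracle_dilate <- function(m, r) {
  d <- dim(m)
  out <- array(0, d)
  on <- which(m == 1, arr.ind = TRUE)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    dist <- pmax(abs(on[, 1] - i), pmax(abs(on[, 2] - j), abs(on[, 3] - k)))
    if (any(dist <= r)) out[i, j, k] <- 1
  }
  out
}

# Hand-simulated plateau scheduler (relative threshold, reduce when the
# count of consecutive non-improving epochs reaches the patience).
oracle_scheduler <- function(losses, lr0 = 1e-3, factor = 10, patience = 5,
                             threshold = 1e-4, lrMin = 1e-6) {
  lr <- lr0; best <- Inf; bad <- 0
  out <- numeric(length(losses))
  for (i in seq_along(losses)) {
    if (losses[i] < best * (1 - threshold)) { best <- losses[i]; bad <- 0 }
    else {
      bad <- bad + 1
      if (bad >= patience) { lr <- max(lr / factor, lrMin); bad <- 0 }
    }
    out[i] <- lr
  }
  out
}

# Small random HU volume.
rand_vol <- function(d, seed, lo = -200, hi = 400) {
  set.seed(seed)
  array(runif(prod(d), lo, hi), dim = d)
}
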